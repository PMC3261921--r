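#' Options bundle for f-I based estimation
#'
#' Shared measurement settings for threshold/inverse-gain estimation and
#' sensitivity sweeps.
#'
#' @param F_low,F_high bracket frequencies of the linear fit window, Hz.
#' @param n_points currents per f-I fit.
#' @param n_isi ISIs averaged per rate measurement.
#' @param dt integration step, ms.
#' @param settle settling period, ms.
#' @param t_max longest simulation per rate measurement, ms.
#' @param threshold_t_max probe window for the threshold scan, ms.
#' @param I_bracket initial current bracket for the first bisection, uA/cm^2.
#' @param probe_high current of the no-discharge admissibility probe
#'   (category "high_threshold"), uA/cm^2.
#' @param probe_low current of the spontaneous-discharge probe (category
#'   "spontaneous", the unrealistically negative threshold), uA/cm^2.
#' @param ap_band admissible AP-duration band, ms.
#' @param gain_factor admissible gain range relative to baseline.
#' @export
fi_options <- function(F_low = 5, F_high = 60, n_points = 30L, n_isi = 30L,
                       dt = 0.01, settle = 200, t_max = 12000,
                       threshold_t_max = 4000, I_bracket = c(-2, 3),
                       probe_high = 5, probe_low = -5,
                       ap_band = c(1.8 * 0.75, 1.8 * 1.25),
                       gain_factor = 2.5) {
  as.list(environment())
}

.closure_for <- function(membrane, x, noise, opts) {
  rate_closure(membrane, x, noise, dt = opts$dt, n_isi = opts$n_isi,
               settle = opts$settle, t_max = opts$t_max)
}

.fit_for <- function(membrane, x, noise, opts, I_bracket = NULL, threshold = TRUE) {
  rf <- .closure_for(membrane, x, noise, opts)
  fit_fi(rf, F_low = opts$F_low, F_high = opts$F_high, n_points = opts$n_points,
         I_bracket = if (is.null(I_bracket)) opts$I_bracket else I_bracket,
         threshold = threshold, threshold_t_max = opts$threshold_t_max)
}

#' Admissibility of a model instance at one gmax
#'
#' Applies the exclusion categories that delimit the physiological range of
#' the X conductance: (1) no discharge at a large probe current
#' (`high_threshold`); (2) spontaneous discharge at a large negative probe
#' current, i.e. an unrealistically negative threshold (`spontaneous`);
#' (3, 4) gain outside `1/2.5 .. 2.5` times the baseline gain (`low_gain`,
#' `high_gain`, bounds inclusive); (5) frequency saturation inside the fit
#' window (`saturation`); (6, 7) AP duration outside 1.8 ms +/- 25%
#' (`short_AP`, `long_AP`).
#'
#' @param membrane,x,noise model parameters at the gmax under test.
#' @param baseline baseline `fi_curve` (gmax = 0); precomputed.
#' @param opts an [fi_options()].
#' @param fi optional precomputed `fi_curve` for this gmax (skips refitting).
#' @param I_bracket current bracket hint for the fit.
#' @param run_probes run the category 1/2 current probes (disable only for
#'   fixture-driven testing of the fit-based categories).
#' @return list with `category` (one of pass, high_threshold, spontaneous,
#'   low_gain, high_gain, saturation, short_AP, long_AP), `detail` (the
#'   measured value that triggered it) and `fi` (the fit, when reached).
#' @export
admissibility_check <- function(membrane, x, noise, baseline, opts = fi_options(),
                                fi = NULL, I_bracket = NULL, run_probes = TRUE) {
  verdict <- function(category, detail, fi = NULL)
    list(category = category, detail = detail, fi = fi)
  if (run_probes) {
    rf_probe <- rate_closure(membrane, x, noise, dt = opts$dt, n_isi = opts$n_isi,
                             settle = opts$settle, t_max = opts$threshold_t_max)
    f_hi <- rf_probe(opts$probe_high)
    if (f_hi == 0) return(verdict("high_threshold", f_hi))
    f_lo <- rf_probe(opts$probe_low)
    if (f_lo > 0) return(verdict("spontaneous", f_lo))
  }
  if (is.null(fi)) {
    fi <- tryCatch(.fit_for(membrane, x, noise, opts, I_bracket, threshold = TRUE),
                   error = function(e) e)
    if (inherits(fi, "error")) return(verdict("saturation", conditionMessage(fi)))
  }
  gain0 <- baseline$gain
  if (fi$gain < gain0 / opts$gain_factor) return(verdict("low_gain", fi$gain, fi))
  if (fi$gain > gain0 * opts$gain_factor) return(verdict("high_gain", fi$gain, fi))
  # saturation: local slope in the upper third of the window collapses
  # relative to the lower third
  k <- length(fi$currents)
  third <- max(3L, floor(k / 3))
  lo_fit <- model_I_regression(fi$currents[1:third], fi$frequencies[1:third])
  hi_fit <- model_I_regression(fi$currents[(k - third + 1):k],
                               fi$frequencies[(k - third + 1):k])
  if (lo_fit$slope > 0 && hi_fit$slope < 0.25 * lo_fit$slope)
    return(verdict("saturation", hi_fit$slope / lo_fit$slope, fi))
  if (!is.na(fi$ap_duration)) {
    if (fi$ap_duration < opts$ap_band[1L]) return(verdict("short_AP", fi$ap_duration, fi))
    if (fi$ap_duration > opts$ap_band[2L]) return(verdict("long_AP", fi$ap_duration, fi))
  }
  verdict("pass", NA_real_, fi)
}

#' Admissible geometric gmax progression with per-gmax excitability fits
#'
#' Builds the geometric sequence `g1 * ratio^j` and climbs it while each
#' member passes [admissibility_check()], fitting the f-I curve at each
#' member. `g1` is first validated (and halved if needed, up to
#' `max_downscale` times) so that it leaves the threshold and inverse gain
#' unchanged within 0.5% of baseline — the conductance must start about three
#' orders of magnitude below its effective range.
#'
#' @param template an [x_conductance()]; its `gmax` field is ignored.
#' @param membrane,noise model parameters.
#' @param g1 starting conductance, mS/cm^2 (default `g_L / 1000`).
#' @param ratio geometric ratio (> 1).
#' @param max_steps cap on progression length.
#' @param max_downscale times `g1` may be halved to satisfy the no-effect
#'   precondition.
#' @param opts an [fi_options()].
#' @param baseline optional precomputed baseline `fi_curve`.
#' @return list with `gmax` (admissible progression), `fits` (list of
#'   `fi_curve`), `baseline`, `fail_category` (category that stopped the
#'   climb, or NA), `g1`.
#' @export
gmax_progression <- function(template, membrane = membrane_params(),
                             noise = noise_params(), g1 = NULL, ratio = sqrt(2),
                             max_steps = 40L, max_downscale = 6L,
                             opts = fi_options(), baseline = NULL) {
  stopifnot(ratio > 1)
  if (is.null(g1)) g1 <- membrane$g_L / 1000
  if (g1 <= 0) stop("invalid-parameter: g1 must be > 0")
  if (is.null(baseline))
    baseline <- .fit_for(membrane, x_modify(template, gmax = 0), noise, opts)
  ref_I <- max(abs(baseline$I_theta), baseline$I_high - baseline$I_low, na.rm = TRUE)
  bracket0 <- c(baseline$I_low - 0.5 * (baseline$I_high - baseline$I_low),
                baseline$I_high)
  # No-effect precondition at g1, measured on the baseline's own current
  # grid with the same noise realization (common random numbers): the
  # difference then reflects only the conductance, not sampling jitter.
  res <- baseline$threshold_resolution
  if (!is.finite(res)) res <- (baseline$I_high - baseline$I_low) / 100
  th_scan <- seq(baseline$I_theta - 25 * res, baseline$I_theta + 25 * res,
                 by = res)
  ok <- FALSE
  for (d in seq_len(max_downscale + 1L)) {
    rf1 <- .closure_for(membrane, x_modify(template, gmax = g1), noise, opts)
    f1 <- tryCatch(vapply(baseline$currents, rf1, numeric(1)),
                   error = function(e) NULL)
    if (!is.null(f1)) {
      E1 <- 1 / model_I_regression(baseline$currents, f1)$slope
      th1 <- tryCatch(
        as.numeric(find_current_threshold(
          attr(rf1, "rebuild")(opts$threshold_t_max), th_scan,
          resolution = res)),
        error = function(e) NA_real_)
      tol_I <- max(0.005 * ref_I, 1.5 * res)
      if (is.finite(th1) &&
          abs(th1 - baseline$I_theta) < tol_I &&
          abs(E1 - baseline$E) < 0.005 * baseline$E) { ok <- TRUE; break }
    }
    g1 <- g1 / 2
  }
  if (!ok)
    stop("degenerate-start: g1 modifies threshold or inverse gain even after downscaling")
  fit1 <- .fit_for(membrane, x_modify(template, gmax = g1), noise, opts, bracket0)
  v1 <- admissibility_check(membrane, x_modify(template, gmax = g1), noise,
                            baseline, opts, fi = fit1)
  if (v1$category != "pass")
    stop("degenerate-start: g1 fails admissibility (", v1$category, ")")
  gs <- g1
  fits <- list(fit1)
  fail <- NA_character_
  prev <- fit1
  for (j in seq_len(max_steps - 1L)) {
    g <- g1 * ratio^j
    span <- prev$I_high - prev$I_low
    bracket <- c(prev$I_low - 1.5 * span, prev$I_high + 0.75 * span)
    v <- admissibility_check(membrane, x_modify(template, gmax = g), noise,
                             baseline, opts, I_bracket = bracket)
    if (v$category != "pass") { fail <- v$category; break }
    gs <- c(gs, g)
    fits <- c(fits, list(v$fi))
    prev <- v$fi
  }
  list(gmax = gs, fits = fits, baseline = baseline, fail_category = fail, g1 = g1)
}

#' Threshold and inverse-gain sensitivities of an X-conductance template
#'
#' The threshold sensitivity `S_theta` and inverse-gain sensitivity `S_E` are
#' the model-I regression slopes of the current threshold and of the inverse
#' gain against gmax, over the admissible geometric progression. Both are
#' constants of the template kinetics, independent of the amount of
#' conductance.
#'
#' @inheritParams gmax_progression
#' @param min_points minimum admissible progression length (error of class
#'   `ipsense_insufficient_range` below it).
#' @return An object of class `sensitivity_estimate`: `S_theta` (uA/cm^2 per
#'   mS/cm^2), `S_E` (uA/cm^2 per Hz per mS/cm^2), `gmax` (progression),
#'   `fit_theta`, `fit_E` (regressions), `r2_theta`, `r2_E`, `linear` flag
#'   (both r^2 > 0.99), `baseline`, `fail_category`.
#' @export
estimate_sensitivities <- function(template, membrane = membrane_params(),
                                   noise = noise_params(), g1 = NULL,
                                   ratio = sqrt(2), max_steps = 40L,
                                   opts = fi_options(), baseline = NULL,
                                   min_points = 3L) {
  prog <- gmax_progression(template, membrane, noise, g1 = g1, ratio = ratio,
                           max_steps = max_steps, opts = opts, baseline = baseline)
  if (length(prog$gmax) < min_points) {
    cond <- structure(class = c("ipsense_insufficient_range", "error", "condition"),
                      list(message = sprintf(
                        "insufficient-range: only %d admissible gmax values (need >= %d); stopped by %s",
                        length(prog$gmax), min_points, prog$fail_category),
                        call = sys.call(-1)))
    stop(cond)
  }
  I_th <- vapply(prog$fits, function(f) f$I_theta, numeric(1))
  Es <- vapply(prog$fits, function(f) f$E, numeric(1))
  ok <- is.finite(I_th) & is.finite(Es)
  if (sum(ok) < min_points) {
    cond <- structure(class = c("ipsense_insufficient_range", "error", "condition"),
                      list(message = sprintf(
                        "insufficient-range: only %d usable gmax values (need >= %d)",
                        sum(ok), min_points), call = sys.call(-1)))
    stop(cond)
  }
  prog$gmax <- prog$gmax[ok]; I_th <- I_th[ok]; Es <- Es[ok]
  fit_theta <- model_I_regression(prog$gmax, I_th)
  fit_E <- model_I_regression(prog$gmax, Es)
  structure(list(S_theta = fit_theta$slope, S_E = fit_E$slope,
                 gmax = prog$gmax, I_theta = I_th, E = Es,
                 fit_theta = fit_theta, fit_E = fit_E,
                 r2_theta = fit_theta$r^2, r2_E = fit_E$r^2,
                 linear = fit_theta$r^2 > 0.99 && fit_E$r^2 > 0.99,
                 baseline = prog$baseline, fail_category = prog$fail_category,
                 g1 = prog$g1, ratio = ratio),
            class = "sensitivity_estimate")
}

#' @export
print.sensitivity_estimate <- function(x, ...) {
  cat(sprintf("<sensitivity_estimate> S_theta = %.4g (r2 = %.4f), S_E = %.4g (r2 = %.4f), %d gmax in [%.3g, %.3g]\n",
              x$S_theta, x$r2_theta, x$S_E, x$r2_E, length(x$gmax),
              min(x$gmax), max(x$gmax)))
  invisible(x)
}

#' Rectangular (V_half, k) grid specification
#'
#' @param V_half_range,k_range ranges, mV. Defaults cover the physiological
#'   window of most sodium, calcium and potassium conductances.
#' @param V_half_res,k_res grid resolutions, mV.
#' @export
grid_spec <- function(V_half_range = c(-80, -20), k_range = c(1, 15),
                      V_half_res = 2, k_res = 1) {
  list(V_half = seq(V_half_range[1L], V_half_range[2L], by = V_half_res),
       k = seq(k_range[1L], k_range[2L], by = k_res))
}

#' Numerical sensitivity map over the (V_half, k) plane
#'
#' Estimates `S_theta` and `S_E` at every node of the grid for the given
#' template (all cells share p, tau, E_X and inactivation; only the
#' activation Boltzmann varies). Per-node failures are recorded in the
#' `fail_category` column, not fatal. With `cache_dir`, completed nodes are
#' written to disk as JSON and reused on re-run (checkpoint-resume).
#'
#' @param grid a [grid_spec()].
#' @param template an [x_conductance()] template.
#' @param membrane,noise model parameters (the noise seed is shared across
#'   nodes).
#' @param ratio geometric progression ratio for the per-node estimate.
#' @param opts an [fi_options()].
#' @param cache_dir optional directory for per-node checkpoints.
#' @param verbose log per-node progress.
#' @return An object of class `sensitivity_map`: data.frame with columns
#'   V_half, k, S_theta, S_E, r2_theta, r2_E, n_gmax, fail_category, plus
#'   metadata attributes (`template`, `ap_model`, `seed`).
#' @export
compute_map <- function(grid, template, membrane = membrane_params(),
                        noise = noise_params(), ratio = 4,
                        opts = fi_options(), cache_dir = NULL, verbose = FALSE) {
  cells <- expand.grid(V_half = grid$V_half, k = grid$k,
                       KEEP.OUT.ATTRS = FALSE)
  rows <- vector("list", nrow(cells))
  if (!is.null(cache_dir) && !dir.exists(cache_dir))
    dir.create(cache_dir, recursive = TRUE)
  # the gmax = 0 baseline is template-independent: fit it once for all nodes
  baseline <- .fit_for(membrane, x_modify(template, gmax = 0), noise, opts)
  for (i in seq_len(nrow(cells))) {
    vh <- cells$V_half[i]; kk <- cells$k[i]
    cache_file <- if (!is.null(cache_dir))
      file.path(cache_dir, sprintf("node_%+.3f_%.3f.json", vh, kk)) else NULL
    if (!is.null(cache_file) && file.exists(cache_file)) {
      rows[[i]] <- as.data.frame(jsonlite::read_json(cache_file, simplifyVector = TRUE))
      next
    }
    xt <- x_modify(template, V_half = vh, k = kk)
    est <- tryCatch(estimate_sensitivities(xt, membrane, noise, ratio = ratio,
                                           opts = opts, baseline = baseline),
                    error = function(e) e)
    row <- if (inherits(est, "error")) {
      data.frame(V_half = vh, k = kk, S_theta = NA_real_, S_E = NA_real_,
                 r2_theta = NA_real_, r2_E = NA_real_, n_gmax = 0L,
                 fail_category = .err_category(est))
    } else {
      data.frame(V_half = vh, k = kk, S_theta = est$S_theta, S_E = est$S_E,
                 r2_theta = est$r2_theta, r2_E = est$r2_E,
                 n_gmax = length(est$gmax),
                 fail_category = if (is.na(est$fail_category)) "none" else est$fail_category)
    }
    if (!is.null(cache_file))
      jsonlite::write_json(row, cache_file, auto_unbox = TRUE, digits = NA)
    rows[[i]] <- row
    if (verbose)
      message(sprintf("map node %d/%d (V_half = %g, k = %g): S_theta = %.3g, S_E = %.3g",
                      i, nrow(cells), vh, kk, row$S_theta, row$S_E))
  }
  out <- do.call(rbind, rows)
  structure(out, class = c("sensitivity_map", "data.frame"),
            template = template, ap_model = membrane$ap_model,
            seed = if (is.null(noise)) NA_integer_ else noise$seed,
            grid = grid)
}

.err_category <- function(e) {
  m <- conditionMessage(e)
  if (grepl("insufficient-range", m)) "insufficient_range"
  else if (grepl("degenerate-start", m)) "degenerate_start"
  else if (grepl("no-spiking", m)) "high_threshold"
  else paste0("error: ", substr(m, 1, 60))
}
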