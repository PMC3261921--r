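#' High-threshold calcium current and intracellular calcium parameters
#'
#' The loop's activity sensor: an L-type-like calcium current
#' \eqn{I_{CaL} = g_{CaL} m^2 (V - E_{Ca})} whose influx charges a thin
#' intracellular shell beneath the soma surface, with first-order buffering
#' back to the basal concentration. The surface-to-volume factor of the shell
#' converts current density to concentration rate:
#' \deqn{d[Ca]/dt = -\frac{S/V}{2F} I_{CaL} - ([Ca] - Ca_b)/\tau_{Ca}.}
#'
#' @param g_CaL maximal conductance, mS/cm^2.
#' @param activation a [gate_kinetics()] for the m gate (squared).
#' @param E_Ca reversal potential, mV.
#' @param Ca_b basal intracellular concentration, uM.
#' @param tau_Ca buffering time constant, ms.
#' @param soma_radius spherical soma radius, um.
#' @param shell_thickness shell thickness, um (must be < radius).
#' @return An object of class `calcium_params`; field `ca_conv` is the
#'   conversion factor in uM/ms per uA/cm^2.
#' @export
calcium_params <- function(g_CaL = 0.02,
                           activation = gate_kinetics(-20, 6, tau = 1.5),
                           E_Ca = 150, Ca_b = 0.1, tau_Ca = 100,
                           soma_radius = 10, shell_thickness = 1) {
  if (shell_thickness >= soma_radius)
    stop("invalid-parameter: shell thickness must be < soma radius")
  if (g_CaL < 0 || Ca_b < 0 || tau_Ca <= 0)
    stop("invalid-parameter: conductance/concentration must be >= 0, tau_Ca > 0")
  r <- soma_radius; d <- shell_thickness
  sv <- 3 * r^2 / (r^3 - (r - d)^3)          # shell surface/volume, 1/um
  # uA/cm^2 -> mol m^-2 s^-1 via 1e-2/(2F); x S/V (um^-1 -> m^-1: 1e6) gives
  # mol m^-3 s^-1 = mM/s, and 1 mM/s = 1 uM/ms
  ca_conv <- 1e-2 / (2 * 96485) * 1e6 * sv
  structure(list(g_CaL = g_CaL, activation = activation, E_Ca = E_Ca,
                 Ca_b = Ca_b, tau_Ca = tau_Ca, soma_radius = soma_radius,
                 shell_thickness = shell_thickness, ca_conv = ca_conv,
                 F = 96485),
            class = "calcium_params")
}

#' Kinase/phosphatase (aKP) cycle parameters
#'
#' Calcium-activated kinase and phosphatase with Hill-type activation set the
#' phosphorylated (functional) fraction of the X-channel population. The
#' kinase is the more calcium-sensitive enzyme (K_K < K_P) but saturates at a
#' lower maximal rate (v_K < v_P), so the stationary fraction is high when
#' the neuron is silent and falls with sustained activity — the homeostatic
#' sign convention. The cycle time constant 1/(R_K + R_P) is large at basal
#' calcium (slow plasticity at low activity) and shrinks with calcium (rapid
#' homeostasis under hyper-activity).
#'
#' @param v_K,v_P maximal kinase/phosphatase rates, 1/ms.
#' @param K_K,K_P half-activation calcium concentrations, uM.
#' @param n_H Hill number of the enzymatic activations.
#' @param g_sup superior physiological value of the X conductance, mS/cm^2;
#'   the effective maximal conductance is `g_sup * f_phi`.
#' @return An object of class `akp_params`.
#' @export
akp_params <- function(v_K = 1.4e-4, v_P = 2.9e-3, K_K = 0.15, K_P = 1.2,
                       n_H = 3, g_sup = 0.05) {
  vals <- c(v_K, v_P, K_K, K_P, n_H, g_sup)
  if (any(!is.finite(vals)) || any(vals[1:5] <= 0) || g_sup < 0)
    stop("invalid-parameter: aKP rates, constants and Hill number must be > 0, g_sup >= 0")
  structure(list(v_K = v_K, v_P = v_P, K_K = K_K, K_P = K_P, n_H = n_H,
                 g_sup = g_sup),
            class = "akp_params")
}

#' aKP cycle dynamics
#'
#' First-order kinetics of the phosphorylated fraction,
#' \deqn{df_\phi/dt = R_K(Ca)(1 - f_\phi) - R_P(Ca) f_\phi,}
#' with Hill-type macroscopic rates
#' \eqn{R_K = v_K Ca^{n}/(Ca^{n} + K_K^{n})} (and likewise for the
#' phosphatase), closed-form stationary fraction
#' \eqn{f^*(Ca) = R_K/(R_K + R_P)} and time constant
#' \eqn{\tau(Ca) = 1/(R_K + R_P)}.
#'
#' @param Ca calcium concentration, uM (vectorized).
#' @param f_phi current phosphorylated fraction in `[0, 1]`.
#' @param akp an [akp_params()].
#' @return list with `dfdt` (1/ms), `f_star`, `tau` (ms), `R_K`, `R_P`.
#' @export
akp_dynamics <- function(Ca, f_phi, akp) {
  stopifnot(all(Ca >= 0))
  cn <- Ca^akp$n_H
  R_K <- akp$v_K * cn / (cn + akp$K_K^akp$n_H)
  R_P <- akp$v_P * cn / (cn + akp$K_P^akp$n_H)
  list(dfdt = R_K * (1 - f_phi) - R_P * f_phi,
       f_star = ifelse(R_K + R_P > 0, R_K / (R_K + R_P), NA_real_),
       tau = ifelse(R_K + R_P > 0, 1 / (R_K + R_P), Inf),
       R_K = R_K, R_P = R_P)
}

.loop_pars <- function(cal, akp, fphi0, Ca0 = NULL) {
  act <- cal$activation
  list(gCaL = cal$g_CaL, VhCa = act$V_half, kCa = act$k,
       tauCaAct = if (act$instantaneous) 0.1 else act$tau,
       ECa = cal$E_Ca, caConv = cal$ca_conv, Cab = cal$Ca_b,
       tauCa = cal$tau_Ca, vK = akp$v_K, vP = akp$v_P, KK = akp$K_K,
       KP = akp$K_P, nH = akp$n_H, gsup = akp$g_sup,
       fphi0 = fphi0, Ca0 = if (is.null(Ca0)) cal$Ca_b else Ca0)
}

# steady frequency with the stationarity criterion: relative change of the
# 1 s-binned rate < tol over the last `frac` of the run
.steady_frequency <- function(spike_times, t_end, frac = 0.2, tol = 0.02,
                              bin = 1000) {
  t0 <- (1 - frac) * t_end
  win <- spike_times[spike_times >= t0]
  f_last <- 1000 * length(win) / (t_end - t0)
  if (f_last == 0) return(list(f = 0, stationary = TRUE))
  half <- (t0 + t_end) / 2
  f1 <- 1000 * sum(win < half) / (half - t0)
  f2 <- 1000 * sum(win >= half) / (t_end - half)
  stat <- f1 > 0 && abs(f2 - f1) / f1 < tol
  list(f = f_last, stationary = stat)
}

#' Simulate the homeostatic IP loop (conductance-based engine)
#'
#' Co-integrates the membrane (with the high-threshold Ca current), the
#' shell calcium concentration and the aKP cycle, with the X maximal
#' conductance slaved to the phosphorylated fraction
#' (`gmax = g_sup * f_phi`). No injected current and no synaptic drive: the
#' neuron is initially silent and the loop decides whether a spontaneous
#' discharge emerges.
#'
#' @param membrane a [membrane_params()].
#' @param template an [x_conductance()] template (gmax ignored).
#' @param cal a [calcium_params()].
#' @param akp an [akp_params()].
#' @param duration simulated time, ms.
#' @param dt integration step, ms.
#' @param fphi0 initial phosphorylated fraction.
#' @param record_every trace decimation.
#' @return An object of class `loop_trajectory`: `t`, `V`, `Ca`, `f_phi`,
#'   `gmax` series, `spike_times`, `steady_frequency` (Hz, 0 if silent;
#'   reported from the last 20% of the run), `stationary` flag, `fired`.
#' @export
simulate_loop_hh <- function(membrane, template, cal = calcium_params(),
                             akp = akp_params(), duration = 120000, dt = 0.01,
                             fphi0 = 0, record_every = 1000L) {
  lp <- .loop_pars(cal, akp, fphi0)
  out <- .sim_raw(membrane, x_modify(template, gmax = 0), I = 0, noise = NULL,
                  dt = dt, t_max = duration, settle = 0,
                  record_every = as.integer(record_every), loop = lp)
  sf <- .steady_frequency(out$spike_times, out$t_end)
  structure(list(t = out$t, V = out$V, Ca = out$Ca, f_phi = out$fphi,
                 gmax = out$gmax_eff, spike_times = out$spike_times,
                 steady_frequency = sf$f, stationary = sf$stationary,
                 fired = length(out$spike_times) > 0, engine = "hh",
                 duration = duration),
            class = "loop_trajectory")
}

#' @export
print.loop_trajectory <- function(x, ...) {
  cat(sprintf("<loop_trajectory:%s> %s; steady f = %.2f Hz%s; f_phi end = %.3f\n",
              x$engine, if (x$fired) sprintf("%d spikes", length(x$spike_times)) else "silent",
              x$steady_frequency, if (x$stationary) "" else " (not stationary)",
              tail(x$f_phi, 1)))
  invisible(x)
}

#' Fit the calcium-frequency relation of the conductance-based model
#'
#' Simulates the model (with the Ca current, fixed `gmax = 0`, aKP frozen)
#' at currents spanning the given frequencies and regresses the steady
#' calcium concentration on the firing rate. The relation is close to linear;
#' its slope feeds the rate-based loop engine.
#'
#' @param membrane,template,cal model parameters.
#' @param currents injected currents to probe, uA/cm^2.
#' @param t_probe duration per probe, ms.
#' @param dt integration step, ms.
#' @return list with `slope` (uM per Hz), `intercept`, `fit`
#'   (a `regression_result`), and the probe table `data`.
#' @export
fit_ca_frequency <- function(membrane, template, cal = calcium_params(),
                             currents = seq(0.4, 3, length.out = 8),
                             t_probe = 3000, dt = 0.01) {
  akp0 <- akp_params(g_sup = 0)
  rows <- lapply(currents, function(I) {
    lp <- .loop_pars(cal, akp0, fphi0 = 0)
    out <- .sim_raw(membrane, x_modify(template, gmax = 0), I = I,
                    noise = NULL, dt = dt, t_max = t_probe, settle = 0,
                    record_every = 100L, loop = lp)
    n2 <- length(out$Ca)
    keep <- seq(ceiling(n2 / 2), n2)   # steady half
    sp <- out$spike_times[out$spike_times > t_probe / 2]
    data.frame(I = I, f = 1000 * length(sp) / (t_probe / 2),
               Ca = mean(out$Ca[keep]))
  })
  d <- do.call(rbind, rows)
  fit <- model_I_regression(d$f, d$Ca)
  list(slope = fit$slope, intercept = fit$intercept, fit = fit, data = d)
}

#' Simulate the homeostatic IP loop (rate-based engine)
#'
#' Replaces the conductance-based equations by the linear rate description:
#' \eqn{f = H(I - I_\theta)(I - I_\theta)/E_0} with the threshold slaved to
#' the plastic conductance through the threshold sensitivity,
#' \eqn{I_\theta(t) = I_{\theta,0} + S_\theta\, g_{sup} f_\phi(t)}, calcium
#' linearized as \eqn{[Ca] = Ca_b + c\, f}, and the aKP cycle driving
#' `f_phi`. Much cheaper than the conductance-based engine and used to
#' predict its outcome.
#'
#' @param S_theta threshold sensitivity of the template, uA/cm^2 per mS/cm^2.
#' @param I_theta0 baseline current threshold (gmax = 0, no noise), uA/cm^2.
#' @param E0 baseline inverse gain, uA/cm^2 per Hz.
#' @param akp an [akp_params()].
#' @param ca_slope calcium-frequency slope `c`, uM per Hz
#'   (from [fit_ca_frequency()]).
#' @param Ca_b basal calcium, uM.
#' @param I injected current, uA/cm^2.
#' @param duration simulated time, ms.
#' @param dt integration step, ms (the loop variables evolve on second
#'   timescales; 5 ms is ample).
#' @param fphi0 initial phosphorylated fraction.
#' @return A `loop_trajectory` (V series absent; `f` series instead).
#' @export
simulate_loop_rate <- function(S_theta, I_theta0, E0, akp = akp_params(),
                               ca_slope = 0.02, Ca_b = 0.1, I = 0,
                               duration = 120000, dt = 5, fphi0 = 0) {
  n <- floor(duration / dt)
  keep <- max(1L, floor(n / 2000))
  ts <- fs <- cas <- fps <- numeric(0)
  fphi <- fphi0
  f <- 0; Ca <- Ca_b
  for (i in seq_len(n)) {
    I_th <- I_theta0 + S_theta * akp$g_sup * fphi
    f <- if (I > I_th) (I - I_th) / E0 else 0
    Ca <- Ca_b + ca_slope * f
    # RK4 on f_phi with Ca held over the step (Ca tracks f quasi-statically)
    k1 <- akp_dynamics(Ca, fphi, akp)$dfdt
    k2 <- akp_dynamics(Ca, fphi + 0.5 * dt * k1, akp)$dfdt
    k3 <- akp_dynamics(Ca, fphi + 0.5 * dt * k2, akp)$dfdt
    k4 <- akp_dynamics(Ca, fphi + dt * k3, akp)$dfdt
    fphi <- fphi + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    fphi <- min(1, max(0, fphi))
    if (i %% keep == 0L) {
      ts <- c(ts, i * dt); fs <- c(fs, f); cas <- c(cas, Ca); fps <- c(fps, fphi)
    }
  }
  m <- length(fs)
  last <- fs[ts >= 0.8 * duration]
  f_steady <- if (length(last)) mean(last) else f
  stat <- length(last) > 1 &&
    (f_steady == 0 || abs(last[length(last)] - last[1]) / max(f_steady, 1e-9) < 0.02)
  structure(list(t = ts, f = fs, Ca = cas, f_phi = fps,
                 gmax = akp$g_sup * fps, spike_times = numeric(0),
                 steady_frequency = if (f_steady > 0) f_steady else 0,
                 stationary = stat, fired = any(fs > 0), engine = "rate",
                 duration = duration),
            class = "loop_trajectory")
}

#' Map of spontaneous discharge emerging from the IP loop
#'
#' Runs the loop at every node of the (V_half, k) grid and reports the
#' steady spontaneous frequency (0 for silent), alongside the a-priori
#' analytic border criterion
#' \eqn{I_{\theta,0} + S_\theta(V_{1/2}, k)\, g_{sup} \le 0}
#' (threshold IAF theory: the maximal possible threshold modification allows
#' firing at I = 0).
#'
#' @param grid a [grid_spec()].
#' @param membrane,template,cal,akp loop parameters.
#' @param engine `"hh"` (conductance-based) or `"rate"`.
#' @param duration horizon per node, ms.
#' @param iaf an [iaf_params()] for the analytic border (and the rate
#'   engine's S_theta).
#' @param I_theta0,E0 baseline threshold and inverse gain for the rate
#'   engine (noise-free); estimated once from the model if NULL.
#' @param ca_slope calcium-frequency slope for the rate engine; fitted once
#'   from the model if NULL.
#' @param dt integration step of the hh engine, ms.
#' @return data.frame with V_half, k, steady_frequency, fired,
#'   predicted_fire (analytic criterion); attribute `engine`.
#' @export
spontaneous_map <- function(grid, membrane, template, cal = calcium_params(),
                            akp = akp_params(), engine = c("hh", "rate"),
                            duration = 120000, iaf = NULL,
                            I_theta0 = NULL, E0 = NULL, ca_slope = NULL,
                            dt = 0.01) {
  engine <- match.arg(engine)
  if (is.null(iaf)) iaf <- estimate_iaf_params(membrane, template)
  if (is.null(I_theta0) || is.null(E0)) {
    rf <- rate_closure(membrane, x_modify(template, gmax = 0), NULL, t_max = 6000)
    if (is.null(I_theta0))
      I_theta0 <- as.numeric(find_current_threshold(rf, seq(0, 4, 0.25),
                                                    resolution = 0.005))
    if (is.null(E0)) {
      fi <- fit_fi(rf, n_points = 10L, I_bracket = c(I_theta0, I_theta0 + 3),
                   threshold = FALSE)
      E0 <- fi$E
    }
  }
  if (engine == "rate" && is.null(ca_slope))
    ca_slope <- fit_ca_frequency(membrane, template, cal)$slope
  cells <- expand.grid(V_half = grid$V_half, k = grid$k, KEEP.OUT.ATTRS = FALSE)
  cells$steady_frequency <- NA_real_
  cells$fired <- NA
  cells$predicted_fire <- NA
  for (i in seq_len(nrow(cells))) {
    xt <- x_modify(template, V_half = cells$V_half[i], k = cells$k[i])
    s_th <- s_theta_analytic(xt, iaf)
    cells$predicted_fire[i] <- (I_theta0 + s_th * akp$g_sup) <= 0
    tr <- if (engine == "hh") {
      simulate_loop_hh(membrane, xt, cal, akp, duration = duration, dt = dt)
    } else {
      simulate_loop_rate(s_th, I_theta0, E0, akp, ca_slope = ca_slope,
                         Ca_b = cal$Ca_b, duration = duration)
    }
    cells$steady_frequency[i] <- tr$steady_frequency
    cells$fired[i] <- tr$fired
  }
  structure(cells, engine = engine, I_theta0 = I_theta0, E0 = E0,
            class = c("spontaneous_map", "data.frame"))
}
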