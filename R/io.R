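#' Derive a component seed from the master seed
#'
#' Stable hash of (seed, component name): adding a component never perturbs
#' the streams of the others. Result is a positive integer below 2^31.
#'
#' @param master master seed (integer).
#' @param component component name (character).
#' @export
derive_seed <- function(master, component) {
  h <- as.double(master) %% 2147483647
  for (cc in utf8ToInt(component)) h <- (h * 31 + cc) %% 2147483647
  as.integer(h + 1)
}

.scenario_defaults <- function() {
  list(
    membrane = list(capacitance = 1, g_L = 0.05, E_L = -70, ap_model = "golomb_rs"),
    x = list(gmax = 0, p = 1, V_half = -45, k = 5, tau = 5, E_X = 50,
             inactivation = NULL),
    noise = list(enabled = TRUE,
                 e = list(n_trains = 100, n_sync = 3, rate = 2,
                          g_unit = 0.0128, tau_syn = 2, E_syn = 0),
                 i = list(n_trains = 50, n_sync = 3, rate = 5,
                          g_unit = 0.0020, tau_syn = 10, E_syn = -80)),
    integration = list(dt = 0.01, settle = 200, t_max = 12000),
    analysis = list(F_low = 5, F_high = 60, n_points = 30, n_isi = 30,
                    probe_high = 5, probe_low = -5),
    seed = 1,
    provenance = "")
}

.merge_scenario <- function(defaults, user, path = "") {
  for (nm in names(user)) {
    if (!nm %in% names(defaults))
      stop("scenario parse error at ", paste0(path, nm), ": unknown key")
    if (is.list(defaults[[nm]]) && !is.null(defaults[[nm]]) && is.list(user[[nm]])) {
      defaults[[nm]] <- .merge_scenario(defaults[[nm]], user[[nm]],
                                        paste0(path, nm, "$"))
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

#' Load a scenario configuration file
#'
#' One JSON document per scenario (membrane, X conductance, noise,
#' integration and analysis settings, seed). Missing keys are filled with
#' the documented defaults; unknown keys are rejected with the offending key
#' path; invariants are validated by constructing the parameter objects.
#'
#' @param path path to a JSON scenario file.
#' @return An object of class `scenario`: the resolved configuration plus
#'   constructed `membrane_params`, `x_conductance` and `noise_params`.
#' @export
load_scenario <- function(path) {
  if (!file.exists(path)) stop("scenario file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- .merge_scenario(.scenario_defaults(), raw)
  scenario_from_config(cfg)
}

#' Build a scenario from a configuration list
#'
#' @param cfg configuration list in the scenario schema.
#' @return An object of class `scenario`.
#' @export
scenario_from_config <- function(cfg) {
  mem <- membrane_params(cfg$membrane$capacitance, cfg$membrane$g_L,
                         cfg$membrane$E_L, cfg$membrane$ap_model)
  inact <- NULL
  xi <- cfg$x$inactivation
  if (!is.null(xi) && length(xi))
    inact <- gate_kinetics(xi$V_half, xi$k, xi$tau, "inactivation")
  act <- gate_kinetics(cfg$x$V_half, cfg$x$k,
                       if (identical(cfg$x$tau, "instantaneous"))
                         "instantaneous" else cfg$x$tau,
                       "activation")
  x <- x_conductance(cfg$x$gmax, cfg$x$p, act, inact, cfg$x$E_X)
  noise <- NULL
  if (isTRUE(cfg$noise$enabled))
    noise <- noise_params(e = as.list(cfg$noise$e), i = as.list(cfg$noise$i),
                          seed = derive_seed(cfg$seed, "noise"))
  structure(list(config = cfg, membrane = mem, x = x, noise = noise,
                 seed = cfg$seed),
            class = "scenario")
}

#' Write a scenario back to JSON
#'
#' Round-trips losslessly through [load_scenario()].
#' @param scenario a `scenario`.
#' @param path output path.
#' @export
write_scenario <- function(scenario, path) {
  jsonlite::write_json(scenario$config, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

.sidecar <- function(path, meta) {
  side <- paste0(tools::file_path_sans_ext(path), ".json")
  meta$software <- paste0("ipsense ", as.character(utils::packageVersion("ipsense")))
  jsonlite::write_json(meta, side, auto_unbox = TRUE, digits = NA, null = "null")
  side
}

#' Write a trace to CSV (with JSON metadata sidecar)
#'
#' Columns: t, V, then every recorded gating/loop series; full precision.
#' @param trace an `hh_trace` or `loop_trajectory`.
#' @param path output CSV path.
#' @param meta extra metadata stored in the sidecar.
#' @return the CSV path, invisibly.
#' @export
write_trace <- function(trace, path, meta = list()) {
  cols <- c("t", "V", "f", "x", "h", "n", "y", "ge", "gi", "Ca", "f_phi",
            "fphi", "gmax_eff", "gmax")
  d <- trace[intersect(cols, names(trace))]
  d <- d[vapply(d, function(v) length(v) == length(trace$t), logical(1))]
  utils::write.csv(as.data.frame(d), path, row.names = FALSE, quote = FALSE)
  meta$n_spikes <- length(trace$spike_times)
  meta$columns <- names(d)
  .sidecar(path, meta)
  invisible(path)
}

#' Write spike times to a single-column CSV
#' @param trace an `hh_trace`.
#' @param path output path.
#' @export
write_spikes <- function(trace, path) {
  utils::write.csv(data.frame(spike_time_ms = trace$spike_times), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a sensitivity/theory/spontaneous map to CSV (with sidecar)
#'
#' Fixed column order as computed; JSON sidecar with metadata and seed.
#' @param map a `sensitivity_map`, `theory_map` or `spontaneous_map`.
#' @param path output CSV path.
#' @param meta extra metadata.
#' @export
write_map <- function(map, path, meta = list()) {
  utils::write.csv(as.data.frame(map), path, row.names = FALSE, quote = FALSE)
  meta$class <- class(map)[1L]
  for (a in c("theory", "engine", "ap_model", "seed"))
    if (!is.null(attr(map, a))) meta[[a]] <- attr(map, a)
  .sidecar(path, meta)
  invisible(path)
}
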