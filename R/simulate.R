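#' @useDynLib ipsense, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats coef lm pt uniroot integrate approx var cor sd
#' @importFrom utils head tail modifyList
NULL

# Assemble the parameter list consumed by the compiled integrator.
.sim_pars <- function(membrane, x, I, noise, dt, t_max, settle, stop_spikes,
                      record_every, V0, loop = NULL) {
  act <- x$activation
  has_in <- !is.null(x$inactivation)
  xl <- list(gmax = x$gmax, p = as.numeric(x$p),
             Vhx = act$V_half, kx = act$k,
             inst = isTRUE(act$instantaneous), taux = if (act$instantaneous) 1 else act$tau,
             has_inact = has_in,
             Vhy = if (has_in) x$inactivation$V_half else 0,
             ky = if (has_in) -x$inactivation$k else -7,
             tauy = if (has_in) x$inactivation$tau else 1,
             EX = x$E_X)
  use_noise <- !is.null(noise)
  nz <- NULL
  if (use_noise) {
    # superposition of the per-train Poisson processes: one stream per
    # population with total event rate n_trains * rate (events/ms), each event
    # adding g_unit * n_sync to the population conductance
    nz <- list(rateE = noise$e$n_trains * noise$e$rate / 1000,
               jumpE = noise$e$g_unit * noise$e$n_sync,
               tauE = noise$e$tau_syn, Ee = noise$e$E_syn,
               rateI = noise$i$n_trains * noise$i$rate / 1000,
               jumpI = noise$i$g_unit * noise$i$n_sync,
               tauI = noise$i$tau_syn, Ei = noise$i$E_syn,
               seed = as.numeric(noise$seed))
  }
  use_loop <- !is.null(loop)
  list(dt = dt, t_max = t_max, settle = settle, stop_spikes = as.integer(stop_spikes),
       I = I, C = membrane$capacitance, gL = membrane$g_L, EL = membrane$E_L,
       ap = membrane$ap, x = xl, use_noise = use_noise,
       noise = if (use_noise) nz else NULL,
       use_loop = use_loop, loop = loop,
       record_every = as.integer(record_every),
       V0 = if (is.null(V0)) membrane$E_L else V0)
}

.sim_raw <- function(membrane, x, I = 0, noise = NULL, dt = 0.01, t_max = 1000,
                     settle = 0, stop_spikes = 0L, record_every = 0L, V0 = NULL,
                     loop = NULL) {
  p <- .sim_pars(membrane, x, I, noise, dt, t_max, settle, stop_spikes,
                 record_every, V0, loop)
  out <- .hh_simulate_cpp(p)
  if (isTRUE(out$blown_up))
    stop(sprintf("integration blow-up: non-finite state at t = %.3f ms", out$blow_time))
  out
}

#' Simulate the conductance-based neuron model
#'
#' Fixed-step 4th-order Runge-Kutta integration of the single-compartment
#' model (leak + AP currents + X conductance), with optional stochastic
#' background synaptic drive. Gating variables start at their steady-state
#' values for the initial voltage.
#'
#' @param membrane a [membrane_params()].
#' @param x an [x_conductance()].
#' @param I injected current, uA/cm^2.
#' @param noise a [noise_params()] or `NULL` for the noise-free model.
#' @param dt integration step, ms.
#' @param t_max wall duration of the simulation, ms.
#' @param settle settling period discarded from spike-count stopping, ms.
#' @param stop_spikes if > 0, stop after this many spikes past the settling
#'   period; an error of class `ipsense_timeout` is raised if `t_max` is
#'   reached first.
#' @param record_every store every n-th sample of the state trajectory
#'   (0 disables trace recording; spikes are always recorded).
#' @param V0 initial voltage (defaults to `E_L`).
#' @return An object of class `hh_trace` with fields `t`, `V`, gating series,
#'   `spike_times` (ms), `ap_durations` (ms, measured at the -20 mV level) and
#'   the call parameters.
#' @export
simulate_neuron <- function(membrane, x, I = 0, noise = NULL, dt = 0.01,
                            t_max = 1000, settle = 0, stop_spikes = 0L,
                            record_every = 1L, V0 = NULL) {
  out <- .sim_raw(membrane, x, I, noise, dt, t_max, settle,
                  stop_spikes, record_every, V0)
  if (stop_spikes > 0) {
    n_meas <- sum(out$spike_times > settle)
    if (n_meas < stop_spikes) {
      cond <- structure(class = c("ipsense_timeout", "error", "condition"),
                        list(message = sprintf(
                          "timeout: %d spikes requested after settle, %d obtained within t_max = %g ms",
                          stop_spikes, n_meas, t_max), call = sys.call(-1)))
      stop(cond)
    }
  }
  structure(c(out, list(dt = dt, I = I, membrane = membrane, x = x,
                        noisy = !is.null(noise))),
            class = "hh_trace")
}

#' @export
print.hh_trace <- function(x, ...) {
  cat("<hh_trace>", sprintf("%d spikes, t_end = %.1f ms, I = %g uA/cm^2%s\n",
      length(x$spike_times), x$t_end, x$I, if (x$noisy) ", noisy" else ""))
  invisible(x)
}

#' Detect spikes in a raw voltage series
#'
#' One event per upward crossing of `threshold` with a refractory guard; the
#' action-potential duration is the time spent above `duration_level` around
#' each detected spike.
#'
#' @param V voltage series, mV, uniformly sampled.
#' @param dt sampling step, ms.
#' @param threshold detection level, mV.
#' @param refractory minimum inter-event interval, ms.
#' @param duration_level voltage level at which AP duration is measured, mV.
#' @return list with `spike_times` (ms, strictly increasing) and `ap_durations`.
#' @export
detect_spikes <- function(V, dt, threshold = 0, refractory = 2,
                          duration_level = -20) {
  stopifnot(is.numeric(V), dt > 0)
  n <- length(V)
  if (n < 2L) return(list(spike_times = numeric(0), ap_durations = numeric(0)))
  up <- which(V[-n] < threshold & V[-1] >= threshold)
  spikes <- numeric(0)
  last <- -Inf
  for (i in up) {
    ti <- i * dt
    if (ti - last > refractory && V[i + 1] > V[i]) { # dV/dt > 0 at crossing
      spikes <- c(spikes, ti); last <- ti
    }
  }
  dur <- numeric(0)
  if (length(spikes)) {
    du <- which(V[-n] < duration_level & V[-1] >= duration_level) * dt
    dd <- which(V[-n] >= duration_level & V[-1] < duration_level) * dt
    for (s in spikes) {
      a <- du[du <= s]; b <- dd[dd >= s]
      if (length(a) && length(b)) dur <- c(dur, b[1] - a[length(a)])
    }
  }
  list(spike_times = spikes, ap_durations = dur)
}

#' Resting potential of the model
#'
#' Integrates the noise-free model at `I = 0` and returns the final voltage
#' (errors if the model fires spontaneously).
#' @param membrane,x model parameters.
#' @param t_max settling horizon, ms.
#' @inheritParams simulate_neuron
#' @export
resting_potential <- function(membrane, x, dt = 0.01, t_max = 1000) {
  out <- .sim_raw(membrane, x, I = 0, noise = NULL, dt = dt, t_max = t_max)
  if (length(out$spike_times) > 0)
    stop("model fires spontaneously at I = 0; no resting potential")
  out$V_end
}
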