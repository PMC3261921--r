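#' Integrate-and-fire reduction parameters
#'
#' Reduced description of the neuron used by the analytic sensitivity
#' theories: the membrane charges from the resting/reset potential `V_r`
#' toward the phenomenological spike threshold `V_s`; the spike is
#' effectively initiated at the effective AP-threshold potential `V_theta`
#' (`V_r < V_theta <= V_s`).
#'
#' @param V_r resting/reset potential, mV.
#' @param V_s phenomenological spike-threshold potential, mV.
#' @param V_theta effective AP-threshold potential, mV.
#' @param membrane a [membrane_params()] supplying g_L, E_L, capacitance.
#' @param V_ap spike plateau potential used to compute the end-of-spike
#'   activation, mV.
#' @param T_spike spike duration used for the same purpose, ms.
#' @return An object of class `iaf_params`.
#' @export
iaf_params <- function(V_r = -70, V_s = -40, V_theta = -50,
                       membrane = membrane_params(), V_ap = 30, T_spike = 1.8) {
  if (!(V_r < V_theta && V_theta <= V_s))
    stop("invalid-parameter: require V_r < V_theta <= V_s")
  structure(list(V_r = V_r, V_s = V_s, V_theta = V_theta,
                 g_L = membrane$g_L, E_L = membrane$E_L,
                 C = membrane$capacitance, V_ap = V_ap, T_spike = T_spike),
            class = "iaf_params")
}

#' Effective AP-threshold potential from a simulated trace
#'
#' Estimates `V_theta` from the voltage trajectory of a repetitively firing
#' model. Criterion `"dvdt"` (default): potential at which dV/dt first
#' exceeds `dvdt_crit` on the AP upstroke. Criterion `"phase_min"`: potential
#' at the minimum of dV/dt along the inter-spike trajectory (the slowest
#' point before the regenerative take-off). Also returns an estimate of the
#' phenomenological spike threshold `V_s` (potential at which dV/dt first
#' exceeds `dvdt_vs`). Averaged over spikes.
#'
#' @param trace an `hh_trace` recorded with `record_every = 1`.
#' @param criterion threshold criterion.
#' @param dvdt_crit dV/dt criterion for V_theta, mV/ms.
#' @param dvdt_vs dV/dt criterion for V_s, mV/ms.
#' @return list with `V_theta`, `V_s`, `n_spikes`, `criterion`.
#' @export
effective_threshold <- function(trace, criterion = c("dvdt", "phase_min"),
                                dvdt_crit = 10, dvdt_vs = 50) {
  criterion <- match.arg(criterion)
  V <- trace$V; dt <- trace$dt
  if (is.null(V) || length(V) < 10L)
    stop("effective_threshold needs a recorded voltage trace")
  sp <- trace$spike_times
  sp <- sp[sp > 0]
  if (length(sp) < 2L) stop("no-threshold: model does not fire repetitively")
  dvdt <- c(diff(V) / dt, 0)
  idx_sp <- pmin(length(V), as.integer(round(sp / dt)) + 1L)
  vth <- vs <- numeric(0)
  for (j in seq_len(length(idx_sp))) {
    i1 <- if (j == 1L) 1L else idx_sp[j - 1L]
    i2 <- idx_sp[j]
    if (i2 - i1 < 10L) next
    # start the search at the AHP minimum following the previous spike
    seg <- i1:i2
    i_min <- seg[which.min(V[seg])]
    seg <- i_min:i2
    if (criterion == "dvdt") {
      cand <- seg[dvdt[seg] >= dvdt_crit & V[seg] < 0]
      if (length(cand)) vth <- c(vth, V[cand[1L]])
    } else {
      sub <- seg[V[seg] < -20]
      if (length(sub) > 2L) vth <- c(vth, V[sub[which.min(dvdt[sub])]])
    }
    cand_s <- seg[dvdt[seg] >= dvdt_vs & V[seg] < 0]
    if (length(cand_s)) vs <- c(vs, V[cand_s[1L]])
  }
  if (!length(vth)) stop("no-threshold: criterion never met on any upstroke")
  list(V_theta = mean(vth), V_s = if (length(vs)) mean(vs) else NA_real_,
       n_spikes = length(vth), criterion = criterion)
}

#' Steady-state current-voltage relation of the model
#'
#' Holding current required to clamp the model at `V` with all gates at
#' steady state: \eqn{I_{hold}(V) = g_L (V - E_L) + I_{Na,\infty} + I_{Kdr,\infty} + I_{X,\infty}}.
#' Its local maximum below spike take-off is the saddle-node knee that sets
#' the noise-free rheobase; the corresponding potential is the effective
#' AP-threshold `V_theta`. The following local minimum marks the potential
#' beyond which the spike is autonomous, used as the phenomenological spike
#' threshold `V_s`.
#'
#' @param membrane a [membrane_params()].
#' @param x an [x_conductance()] (its gmax contributes to the relation).
#' @param V voltages at which to evaluate, mV.
#' @return numeric vector of holding currents, uA/cm^2.
#' @export
steady_iv <- function(membrane, x, V) {
  ap <- membrane$ap
  b <- function(v, th, sg) 1 / (1 + exp(-(v - th) / sg))
  xs <- boltzmann_steady_state(V, x$activation)^x$p
  if (!is.null(x$inactivation))
    xs <- xs * boltzmann_steady_state(V, x$inactivation)
  membrane$g_L * (V - membrane$E_L) +
    ap$gNa * b(V, ap$thm, ap$sgm)^3 * b(V, ap$thh, ap$sgh) * (V - ap$VNa) +
    ap$gK * b(V, ap$thn, ap$sgn)^4 * (V - ap$VK) +
    x$gmax * xs * (V - x$E_X)
}

#' Threshold potentials from the steady I-V relation
#'
#' @inheritParams steady_iv
#' @param V_range search window, mV.
#' @param dV search resolution, mV.
#' @return list with `V_theta` (local maximum of the relation), `V_s` (local
#'   minimum), `I_knee` (rheobase of the relation).
#' @export
iv_thresholds <- function(membrane, x, V_range = c(-75, -25), dV = 0.01) {
  V <- seq(V_range[1L], V_range[2L], by = dV)
  I <- steady_iv(membrane, x, V)
  # first interior local maximum (the saddle-node knee)
  dI <- diff(I)
  up <- which(dI[-length(dI)] > 0 & dI[-1] <= 0) + 1L
  if (!length(up)) stop("no-threshold: steady I-V relation has no interior maximum")
  i_max <- up[1L]
  dn <- which(dI[-length(dI)] < 0 & dI[-1] >= 0) + 1L
  dn <- dn[dn > i_max]
  list(V_theta = V[i_max], I_knee = I[i_max],
       V_s = if (length(dn)) V[dn[1L]] else NA_real_)
}

#' Estimate IAF parameters from the conductance-based model
#'
#' Simulates the noise-free model at a probe current and averages the
#' effective threshold over spikes and over a weak-conductance probe range of
#' the template (the estimate must not depend on the starting gmax).
#'
#' @param membrane a [membrane_params()].
#' @param template an [x_conductance()] template.
#' @param I probe current eliciting repetitive firing (trace criteria only),
#'   uA/cm^2.
#' @param g_probe gmax probe values averaged over, mS/cm^2.
#' @param criterion `"iv"` (default): `V_theta` and `V_s` are the local
#'   maximum and minimum of the steady I-V relation ([iv_thresholds()]), the
#'   potentials that govern the saddle-node rheobase. `"dvdt"`/`"phase_min"`:
#'   trace-based criteria via [effective_threshold()] (the dV/dt criterion
#'   locates the upstroke inflection, several mV above the I-V knee; both are
#'   exposed, the criterion used is recorded).
#' @param dt integration step, ms.
#' @return An [iaf_params()] with attribute `criterion`.
#' @export
estimate_iaf_params <- function(membrane, template, I = 1,
                                g_probe = c(0, membrane$g_L / 1000),
                                criterion = c("iv", "dvdt", "phase_min"),
                                dt = 0.01) {
  criterion <- match.arg(criterion)
  vth <- vs <- numeric(0)
  for (g in g_probe) {
    xg <- x_modify(template, gmax = g)
    if (criterion == "iv") {
      est <- iv_thresholds(membrane, xg)
      vth <- c(vth, est$V_theta); vs <- c(vs, est$V_s)
    } else {
      tr <- simulate_neuron(membrane, xg, I = I, dt = dt, t_max = 2000,
                            settle = 500, record_every = 1L)
      est <- effective_threshold(tr, criterion)
      vth <- c(vth, est$V_theta); vs <- c(vs, est$V_s)
    }
  }
  vr <- resting_potential(membrane, x_modify(template, gmax = 0), dt = dt)
  out <- iaf_params(V_r = vr, V_s = mean(vs, na.rm = TRUE), V_theta = mean(vth),
                    membrane = membrane)
  attr(out, "criterion") <- criterion
  out
}

#' Analytic threshold sensitivity (threshold IAF theory)
#'
#' Under instantaneous activation, the current threshold of the reduced
#' model is the steady current at `V_theta`, so the threshold sensitivity is
#' \deqn{S_\theta = x_\infty(V_\theta)^p (V_\theta - E_X)}
#' (multiplied by the steady-state inactivation at `V_theta` when the
#' template inactivates). It depends on the activation kinetics only through
#' the steady activation at the effective AP threshold.
#'
#' @param x an [x_conductance()] template.
#' @param iaf an [iaf_params()].
#' @return `S_theta`, uA/cm^2 per mS/cm^2 (dimensionally mV).
#' @export
s_theta_analytic <- function(x, iaf) {
  xin <- boltzmann_steady_state(iaf$V_theta, x$activation)
  yin <- if (is.null(x$inactivation)) 1 else
    boltzmann_steady_state(iaf$V_theta, x$inactivation)
  xin^x$p * yin * (iaf$V_theta - x$E_X)
}

#' Iso-threshold-sensitivity lines in the (V_half, k) plane
#'
#' Conductances sharing the steady activation level `c` at `V_theta` share
#' the same threshold sensitivity and lie on the straight line
#' \deqn{V_{1/2} = V_\theta - k \, \ln\!\big(c^{1/p} / (1 - c^{1/p})\big),}
#' all passing through the central point O = (V_theta, 0).
#'
#' @param levels activation levels, each in (0, 1).
#' @param V_theta effective AP-threshold potential, mV.
#' @param p activation power.
#' @return data.frame with columns `level`, `intercept` (V_half at k = 0,
#'   always `V_theta`), `slope` (dV_half/dk).
#' @export
iso_sensitivity_lines <- function(levels, V_theta, p = 1L) {
  if (any(levels <= 0 | levels >= 1))
    stop("invalid-parameter: iso-sensitivity levels must lie in (0, 1)")
  cp <- levels^(1 / p)
  data.frame(level = levels, intercept = V_theta, slope = -log(cp / (1 - cp)))
}

#' Auxiliary threshold currents for clamped activation levels
#'
#' The current at which the membrane, with the X activation clamped at level
#' `a`, reaches `V_theta` at steady state. Solved by bisection on the steady
#' current-voltage relation (relative tolerance 1e-6). Returns the four
#' currents used by the inverse-gain theories: activation 0, 1, and the
#' steady levels at `V_r` and `V_s`.
#'
#' @param x an [x_conductance()] template with the gmax at which to evaluate.
#' @param iaf an [iaf_params()].
#' @return named numeric vector `I0`, `I1`, `I_xr`, `I_xs`.
#' @export
activation_threshold_currents <- function(x, iaf) {
  lv <- c(I0 = 0, I1 = 1,
          I_xr = boltzmann_steady_state(iaf$V_r, x$activation),
          I_xs = boltzmann_steady_state(iaf$V_s, x$activation))
  vapply(lv, function(a) {
    gx <- x$gmax * a^x$p
    target <- function(I) {
      # steady V of dV/dt = 0 with clamped gate, by bisection in V
      lo <- -120; hi <- 60
      for (it in 1:80) {
        mid <- (lo + hi) / 2
        dv <- I - iaf$g_L * (mid - iaf$E_L) - gx * (mid - x$E_X)
        if (dv > 0) lo <- mid else hi <- mid
      }
      (lo + hi) / 2 - iaf$V_theta
    }
    # bisection on I
    Ilo <- -50; Ihi <- 50
    for (it in 1:60) {
      mid <- (Ilo + Ihi) / 2
      if (target(mid) < 0) Ilo <- mid else Ihi <- mid
      if ((Ihi - Ilo) <= 1e-6 * max(1, abs(Ilo))) break
    }
    (Ilo + Ihi) / 2
  }, numeric(1))
}

# End-of-spike activation level: buildup from the entry level toward the
# steady activation at the spike plateau over the spike duration. The entry
# level is the pre-spike buildup level x_inf(V_s) when the buildup mechanism
# is engaged (pre/post-spike theory) and the resting level otherwise
# (post-spike theory in isolation).
.x_end_of_spike <- function(x, iaf, from = c("buildup", "rest")) {
  from <- match.arg(from)
  x_entry <- boltzmann_steady_state(
    if (from == "buildup") iaf$V_s else iaf$V_r, x$activation)
  if (x$activation$instantaneous)
    return(boltzmann_steady_state(iaf$V_r, x$activation))
  xap <- boltzmann_steady_state(iaf$V_ap, x$activation)
  x_entry + (xap - x_entry) * (1 - exp(-iaf$T_spike / x$activation$tau))
}

# Integrator mode and initial activation per theory:
# threshold -> quasi-steady gate (instantaneous activation hypothesis)
# pre       -> coupled first-order gate from the resting activation: the
#              buildup mechanism in isolation, no spike-driven elevation
# post      -> exponential relaxation from the spike-driven level, the spike
#              entered from the resting activation (relaxation in isolation)
# prepost   -> exponential relaxation from the self-consistent end-of-spike
#              level: the pre-spike buildup (to x_inf(V_s)) is carried
#              through the spike and relaxes during the initial ISI period
.theory_setup <- function(theory, x, iaf) {
  x_rest <- boltzmann_steady_state(iaf$V_r, x$activation)
  switch(theory,
         threshold = list(mode = 0L, x0 = x_rest, x_rest = x_rest),
         pre = list(mode = 2L, x0 = x_rest, x_rest = x_rest),
         post = list(mode = 1L, x0 = .x_end_of_spike(x, iaf, "rest"),
                     x_rest = x_rest),
         prepost = list(mode = 1L, x0 = .x_end_of_spike(x, iaf, "buildup"),
                        x_rest = x_rest),
         stop("unknown theory: ", theory))
}

#' Analytic single-ISI trajectory of the reduced model
#'
#' Integrates the reduced membrane equation from `V_r` to `V_s` under the
#' activation hypothesis of the chosen theory: `"threshold"`/`"pre"` use the
#' quasi-steady activation `x_inf(V)` (buildup before the spike), `"post"`
#' relaxes the activation exponentially from its end-of-spike level, and
#' `"prepost"` switches from relaxation to quasi-steady when the two meet
#' (the end of the initial period, returned as `t_switch`).
#'
#' @param theory one of "threshold", "pre", "post", "prepost".
#' @param x an [x_conductance()] with the gmax at which to evaluate.
#' @param iaf an [iaf_params()].
#' @param I injected current, uA/cm^2; must exceed the theory's threshold.
#' @param dt integration step, ms.
#' @param t_max ISI horizon, ms.
#' @param record return the trajectory arrays.
#' @return list with `T` (ISI, ms), `f` (= 1000/T, Hz), `t_switch`, and if
#'   `record` the `t`, `V`, `x` series. Error of class `ipsense_no_spike`
#'   if `V_s` is not reached within `t_max`.
#' @export
iaf_trajectory <- function(theory, x, iaf, I, dt = 0.01, t_max = 2000,
                           record = TRUE) {
  su <- .theory_setup(theory, x, iaf)
  inst <- x$activation$instantaneous
  taux <- if (inst) 1e-6 else x$activation$tau
  out <- .iaf_isi_cpp(I, x$gmax, as.numeric(x$p),
                      x$activation$V_half, x$activation$k, x$E_X, taux,
                      iaf$C, iaf$g_L, iaf$E_L, iaf$V_r, iaf$V_s,
                      su$x0, su$x_rest,
                      if (inst) 0L else su$mode, dt, t_max, record)
  if (!isTRUE(out$reached)) {
    cond <- structure(class = c("ipsense_no_spike", "error", "condition"),
                      list(message = sprintf(
                        "no-spike: I = %g below the %s-theory threshold (V_s not reached in %g ms)",
                        I, theory, t_max), call = sys.call(-1)))
    stop(cond)
  }
  list(T = out$T, f = 1000 / out$T, t_switch = out$t_switch,
       t = out$t, V = out$V, x = out$x)
}

# f(I) of the reduced model under a theory; 0 if V_s is not reached
.iaf_rate <- function(theory, x, iaf, I, dt = 0.005, t_max = 2000) {
  su <- .theory_setup(theory, x, iaf)
  inst <- x$activation$instantaneous
  taux <- if (inst) 1e-6 else x$activation$tau
  out <- .iaf_isi_cpp(I, x$gmax, as.numeric(x$p),
                      x$activation$V_half, x$activation$k, x$E_X, taux,
                      iaf$C, iaf$g_L, iaf$E_L, iaf$V_r, iaf$V_s,
                      su$x0, su$x_rest,
                      if (inst) 0L else su$mode, dt, t_max, FALSE)
  if (!isTRUE(out$reached)) 0 else 1000 / out$T
}

#' f-I relation of a reduced IAF theory
#'
#' Frequency is the inverse of the ISI duration (the spike-duration
#' correction 1/(T + T_spike) is neglected; the error is minute below
#' ~100 Hz). The inverse gain is measured exactly as in the simulation
#' pipeline: from the currents bracketing the `F_low`..`F_high` window.
#'
#' @inheritParams iaf_trajectory
#' @param F_low,F_high frequency window, Hz.
#' @param method `"chord"`: E from the two bracket currents; `"ols"`:
#'   regression slope over `n_points` uniform currents in the window,
#'   mirroring the simulation pipeline.
#' @param n_points currents for the OLS method.
#' @return list with `I_low`, `I_high`, `E` (uA/cm^2 per Hz), `gain`.
#' @export
iaf_fi <- function(theory, x, iaf, F_low = 5, F_high = 60, dt = 0.005,
                   method = c("chord", "ols"), n_points = 15L) {
  method <- match.arg(method)
  rate <- function(I) .iaf_rate(theory, x, iaf, I, dt = dt)
  lo <- iaf$g_L * (iaf$V_theta - iaf$E_L) - 2
  hi <- lo + 8
  I_low <- .current_for_rate(rate, F_low, lo, hi, tol = 1e-7)
  I_high <- .current_for_rate(rate, F_high, I_low, I_low + 4, tol = 1e-7)
  if (method == "chord") {
    E <- (I_high - I_low) / (F_high - F_low)
  } else {
    Is <- seq(I_low, I_high, length.out = n_points)
    fs <- vapply(Is, rate, numeric(1))
    E <- 1 / model_I_regression(Is, fs)$slope
  }
  list(I_low = I_low, I_high = I_high, E = E, gain = 1 / E)
}

#' Analytic inverse-gain sensitivity (pre-, post- and pre/post-spike theories)
#'
#' Deterministic inverse-gain sensitivity of the reduced model under the
#' chosen activation hypothesis: slope of the theory's inverse gain in gmax,
#' evaluated in the linear (weak-conductance) regime.
#'
#' @param x an [x_conductance()] template (gmax ignored).
#' @param iaf an [iaf_params()].
#' @param theory one of "pre", "post", "prepost".
#' @param g_eval conductance at which the slope is evaluated, mS/cm^2
#'   (default g_L / 10).
#' @param F_low,F_high frequency window, Hz.
#' @param method,n_points passed to [iaf_fi()].
#' @return `S_E`, uA/cm^2 per Hz per mS/cm^2.
#' @export
s_E_analytic <- function(x, iaf, theory = c("prepost", "pre", "post"),
                         g_eval = iaf$g_L / 10, F_low = 5, F_high = 60,
                         method = "chord", n_points = 15L) {
  theory <- match.arg(theory)
  if (!(iaf$V_r < iaf$V_theta)) stop("invalid-parameter: require V_r < V_theta")
  E0 <- iaf_fi(theory, x_modify(x, gmax = 0), iaf, F_low, F_high,
               method = method, n_points = n_points)$E
  E1 <- iaf_fi(theory, x_modify(x, gmax = g_eval), iaf, F_low, F_high,
               method = method, n_points = n_points)$E
  (E1 - E0) / g_eval
}

#' Analytic sensitivity map over the (V_half, k) plane
#'
#' Deterministic counterpart of [compute_map()]: threshold sensitivity from
#' the threshold IAF theory at every node, and (optionally) inverse-gain
#' sensitivity from one of the spike-correlated theories.
#'
#' @param grid a [grid_spec()].
#' @param template an [x_conductance()] template.
#' @param iaf an [iaf_params()].
#' @param theory `"threshold"` for S_theta only, or one of "pre", "post",
#'   "prepost" to add S_E.
#' @return An object of class `theory_map`: data.frame with V_half, k,
#'   S_theta and (if requested) S_E; attribute `theory`.
#' @export
theory_map <- function(grid, template, iaf,
                       theory = c("threshold", "pre", "post", "prepost")) {
  theory <- match.arg(theory)
  cells <- expand.grid(V_half = grid$V_half, k = grid$k, KEEP.OUT.ATTRS = FALSE)
  cells$S_theta <- NA_real_
  if (theory != "threshold") cells$S_E <- NA_real_
  for (i in seq_len(nrow(cells))) {
    xt <- x_modify(template, V_half = cells$V_half[i], k = cells$k[i])
    cells$S_theta[i] <- s_theta_analytic(xt, iaf)
    if (theory != "threshold")
      cells$S_E[i] <- s_E_analytic(xt, iaf, theory)
  }
  structure(cells, class = c("theory_map", "data.frame"),
            theory = theory, iaf = iaf, template = template, grid = grid)
}
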