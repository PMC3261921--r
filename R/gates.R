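#' Boltzmann gate kinetics
#'
#' First-order gate with a Boltzmann steady state
#' \eqn{x_\infty(V) = 1/(1 + e^{-(V - V_{1/2})/k})} (activation sign) and a
#' voltage-independent time constant. The e-fold slope `k` is stored strictly
#' positive; `type` encodes whether the gate opens ("activation") or closes
#' ("inactivation") with depolarization.
#'
#' @param V_half half-activation (or half-inactivation) potential, mV.
#' @param k e-fold slope of the Boltzmann voltage dependence, mV, strictly positive.
#' @param tau time constant in ms (> 0), or the string `"instantaneous"`.
#' @param type `"activation"` or `"inactivation"`.
#' @return An object of class `gate_kinetics`.
#' @examples
#' g <- gate_kinetics(-45, 5, tau = 5)
#' boltzmann_steady_state(-45, g) # 0.5 at the midpoint
#' @export
gate_kinetics <- function(V_half, k, tau = "instantaneous",
                          type = c("activation", "inactivation")) {
  type <- match.arg(type)
  if (!is.numeric(V_half) || length(V_half) != 1L || !is.finite(V_half))
    stop("invalid-parameter: V_half must be a finite number (mV)")
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k == 0)
    stop("invalid-parameter: e-fold slope k must be non-zero (gate_kinetics requires k > 0)")
  if (k < 0)
    stop("invalid-parameter: k must be strictly positive; use type = \"inactivation\" for gates closing with depolarization")
  inst <- identical(tau, "instantaneous")
  if (!inst) {
    if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) || tau <= 0)
      stop("invalid-parameter: tau must be > 0 ms or \"instantaneous\"")
  }
  structure(list(V_half = V_half, k = k,
                 tau = if (inst) Inf else tau,
                 instantaneous = inst, type = type),
            class = "gate_kinetics")
}

#' Steady-state open fraction of a Boltzmann gate
#'
#' @param V membrane potential, mV (vectorized).
#' @param gate a [gate_kinetics()] object.
#' @return Open fraction in (0, 1); increasing in `V` for activation gates,
#'   decreasing for inactivation gates.
#' @export
boltzmann_steady_state <- function(V, gate) {
  stopifnot(inherits(gate, "gate_kinetics"))
  s <- if (gate$type == "activation") 1 else -1
  1 / (1 + exp(-s * (V - gate$V_half) / gate$k))
}

#' Generic plastic X conductance
#'
#' The plastic voltage-gated conductance whose maximal conductance (and,
#' through [sensitivity_to_parameter()], kinetics) undergoes intrinsic
#' plasticity. Current: \eqn{I_X = g_{max} x^p y (V - E_X)} with first-order
#' Boltzmann activation `x` (power `p`) and optional inactivation `y`.
#'
#' @param gmax maximal conductance, mS/cm^2 (>= 0).
#' @param p activation power, integer in 1..4.
#' @param activation a [gate_kinetics()] of type "activation".
#' @param inactivation a [gate_kinetics()] of type "inactivation", or `NULL`.
#' @param E_X reversal potential, mV.
#' @return An object of class `x_conductance`.
#' @export
x_conductance <- function(gmax, p = 1L, activation, inactivation = NULL, E_X = 50) {
  if (!is.numeric(gmax) || gmax < 0) stop("invalid-parameter: gmax must be >= 0")
  if (!(p %in% 1:4)) stop("invalid-parameter: activation power p must be in {1,2,3,4}")
  stopifnot(inherits(activation, "gate_kinetics"))
  if (activation$type != "activation")
    stop("invalid-parameter: activation gate must have type \"activation\"")
  if (!is.null(inactivation)) {
    stopifnot(inherits(inactivation, "gate_kinetics"))
    if (inactivation$type != "inactivation")
      stop("invalid-parameter: inactivation gate must have type \"inactivation\"")
  }
  structure(list(gmax = gmax, p = as.integer(p), activation = activation,
                 inactivation = inactivation, E_X = E_X),
            class = "x_conductance")
}

#' Replace fields of an X conductance
#'
#' Convenience for sweeps: returns a copy of `x` with the given fields
#' replaced (`gmax`, `V_half`, `k`, `tau`, `p`, `E_X`).
#' @param x an [x_conductance()].
#' @param ... fields to replace.
#' @export
x_modify <- function(x, ...) {
  stopifnot(inherits(x, "x_conductance"))
  mods <- list(...)
  for (nm in names(mods)) {
    v <- mods[[nm]]
    switch(nm,
      gmax = { x$gmax <- v },
      p = { x$p <- as.integer(v) },
      E_X = { x$E_X <- v },
      V_half = { x$activation$V_half <- v },
      k = { x$activation$k <- v },
      tau = {
        inst <- identical(v, "instantaneous")
        x$activation$tau <- if (inst) Inf else v
        x$activation$instantaneous <- inst
      },
      stop("unsupported-parameter: ", nm))
  }
  if (x$gmax < 0) stop("invalid-parameter: gmax must be >= 0")
  if (x$activation$k <= 0) stop("invalid-parameter: k must be strictly positive")
  x
}

#' Membrane and action-potential current parameters
#'
#' Single-compartment membrane with specific capacitance, ohmic leak and a
#' named action-potential current set. The default AP set, `"golomb_rs"`, is a
#' regular-spiking neocortical model (transient sodium with instantaneous
#' cubed activation and first-order inactivation, plus a delayed-rectifier
#' potassium current with fourth-power activation); it is stored as a named,
#' swappable parameter set.
#'
#' @param capacitance specific capacitance, uF/cm^2 (> 0).
#' @param g_L leak maximal conductance, mS/cm^2 (>= 0).
#' @param E_L leak reversal potential, mV.
#' @param ap_model identifier of the AP-current parameter set.
#' @return An object of class `membrane_params`.
#' @export
membrane_params <- function(capacitance = 1, g_L = 0.05, E_L = -70,
                            ap_model = "golomb_rs") {
  if (capacitance <= 0) stop("invalid-parameter: capacitance must be > 0")
  if (g_L < 0) stop("invalid-parameter: g_L must be >= 0")
  ap <- ap_current_params(ap_model)
  structure(list(capacitance = capacitance, g_L = g_L, E_L = E_L,
                 ap_model = ap_model, ap = ap),
            class = "membrane_params")
}

#' Named action-potential current parameter sets
#'
#' `"golomb_rs"`: regular-spiking neocortical AP currents
#' (I_Na = gNa m_inf^3 h (V - VNa) with instantaneous m; I_Kdr = gK n^4 (V - VK)).
#' The delayed-rectifier time constant is calibrated so the baseline action
#' potential lasts 1.8 ms at the -20 mV level, the center of the admissibility
#' band. `"none"` disables AP currents (used by idealized fixtures).
#'
#' @param id parameter-set identifier.
#' @return A named list of AP-current parameters.
#' @export
ap_current_params <- function(id = "golomb_rs") {
  sets <- list(
    golomb_rs = list(
      gNa = 24, thm = -30, sgm = 9.5,       # m_inf, instantaneous, power 3
      thh = -53, sgh = -7,                  # h_inf (inactivation sign via negative slope)
      tauh0 = 0.37, tauh1 = 2.78, thth = -40.5, sgth = -6,
      gK = 3, thn = -30, sgn = 10,          # n_inf, power 4
      taun0 = 1.11, taun1 = 5.55, thtn = -27, sgtn = -15,
      VNa = 55, VK = -90),
    none = list(
      gNa = 0, thm = -30, sgm = 9.5, thh = -53, sgh = -7,
      tauh0 = 0.37, tauh1 = 2.78, thth = -40.5, sgth = -6,
      gK = 0, thn = -30, sgn = 10,
      taun0 = 1.11, taun1 = 5.55, thtn = -27, sgtn = -15,
      VNa = 55, VK = -90))
  if (!id %in% names(sets)) stop("unknown AP model id: ", id)
  sets[[id]]
}

#' Background synaptic noise parameters
#'
#' Excitatory and inhibitory populations of independent Poisson trains, each
#' train firing `rate` Hz and delivering `n_sync` synchronized unitary
#' conductances `g_unit` decaying exponentially with `tau_syn` toward reversal
#' `E_syn`. Defaults are calibrated so the standard model, with no X
#' conductance and zero injected current, fires spontaneously at ~15 Hz.
#'
#' @param e,i lists with fields `n_trains`, `n_sync`, `rate` (Hz), `g_unit`
#'   (mS/cm^2), `tau_syn` (ms), `E_syn` (mV) for the excitatory and inhibitory
#'   populations.
#' @param seed RNG seed (integer); simulations are reproducible given the seed.
#' @return An object of class `noise_params`.
#' @export
noise_params <- function(e = list(n_trains = 100, n_sync = 3, rate = 2,
                                  g_unit = 0.0128, tau_syn = 2, E_syn = 0),
                         i = list(n_trains = 50, n_sync = 3, rate = 5,
                                  g_unit = 0.0020, tau_syn = 10, E_syn = -80),
                         seed = 1L) {
  chk <- function(p, nm) {
    need <- c("n_trains", "n_sync", "rate", "g_unit", "tau_syn", "E_syn")
    if (!all(need %in% names(p))) stop("noise_params: ", nm, " must have fields ",
                                       paste(need, collapse = ", "))
    if (p$n_trains < 0 || p$n_sync < 0 || p$rate < 0 || p$g_unit < 0 || p$tau_syn <= 0)
      stop("invalid-parameter: noise counts/rates must be >= 0 and tau_syn > 0")
    p
  }
  structure(list(e = chk(e, "e"), i = chk(i, "i"), seed = as.integer(seed)),
            class = "noise_params")
}
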