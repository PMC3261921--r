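#' Sensitivity of threshold and inverse gain to a kinetic parameter
#'
#' Chain rule on the linear gmax dependence: for a kinetic parameter `q`
#' (one of `V_half`, `k`, `E_X`),
#' \deqn{dI_\theta/dq = \frac{dg_{max}}{dq} S_\theta + g_{max}
#'   \frac{\partial S_\theta}{\partial q}}
#' and likewise for the inverse gain. With independent plasticity
#' (`coupling = "independent"`) the first right-hand-side term vanishes.
#' The partial derivatives of the threshold sensitivity are analytic
#' (closed form of the Boltzmann); those of the inverse-gain sensitivity use
#' high-accuracy central differences of [s_E_analytic()].
#'
#' @param q parameter id: "V_half", "k" or "E_X".
#' @param x an [x_conductance()] with the gmax at which to evaluate.
#' @param iaf an [iaf_params()].
#' @param coupling "independent" or "coupled".
#' @param dgmax_dq cross-term dgmax/dq for the coupled case.
#' @param theory inverse-gain theory used for dE/dq.
#' @param include_E also compute the inverse-gain part (slower).
#' @return An object of class `parameter_sensitivity`: `q`, `dI_theta_dq`,
#'   `dE_dq` (or NA), `dS_theta_dq`, `method`, `gmax`.
#' @export
sensitivity_to_parameter <- function(q = c("V_half", "k", "E_X"), x, iaf,
                                     coupling = c("independent", "coupled"),
                                     dgmax_dq = 0, theory = "prepost",
                                     include_E = FALSE) {
  q <- match.arg(q)
  coupling <- match.arg(coupling)
  act <- x$activation
  xin <- boltzmann_steady_state(iaf$V_theta, act)
  yin <- if (is.null(x$inactivation)) 1 else
    boltzmann_steady_state(iaf$V_theta, x$inactivation)
  p <- x$p
  drive <- iaf$V_theta - x$E_X
  dS_dq <- switch(q,
    V_half = -p * xin^p * (1 - xin) / act$k * yin * drive,
    k = -p * xin^p * (1 - xin) * (iaf$V_theta - act$V_half) / act$k^2 * yin * drive,
    E_X = -xin^p * yin)
  S_th <- s_theta_analytic(x, iaf)
  cross <- if (coupling == "coupled") dgmax_dq else 0
  dI_dq <- cross * S_th + x$gmax * dS_dq
  dE_dq <- NA_real_
  if (include_E) {
    h <- switch(q, V_half = 0.5, k = 0.1, E_X = 1)
    se <- function(v) {
      xt <- if (q == "E_X") x_modify(x, E_X = v) else
        if (q == "V_half") x_modify(x, V_half = v) else x_modify(x, k = v)
      s_E_analytic(x_modify(xt, gmax = 0), iaf, theory)
    }
    q0 <- switch(q, V_half = act$V_half, k = act$k, E_X = x$E_X)
    dSE_dq <- (se(q0 + h) - se(q0 - h)) / (2 * h)
    SE <- s_E_analytic(x_modify(x, gmax = 0), iaf, theory)
    dE_dq <- cross * SE + x$gmax * dSE_dq
  }
  structure(list(q = q, dI_theta_dq = dI_dq, dE_dq = dE_dq,
                 dS_theta_dq = dS_dq, coupling = coupling,
                 method = "analytic", gmax = x$gmax),
            class = "parameter_sensitivity")
}

#' Finite-difference oracle for parameter sensitivities
#'
#' Central difference of the measured threshold and inverse gain under a
#' perturbation of a kinetic parameter, with a Richardson half-step check.
#' `measure` is any function of the parameter value returning
#' `list(I_theta =, E =)` — typically a wrapper running the full simulation
#' pipeline. Flags the estimate as non-smooth when the half-step pair
#' disagrees by more than 20%.
#'
#' @param q parameter id (bookkeeping only).
#' @param measure function of the parameter value.
#' @param q0 parameter value at which to differentiate.
#' @param step perturbation size.
#' @param richardson run the additional half-step pair.
#' @return An object of class `parameter_sensitivity` with fields
#'   `dI_theta_dq`, `dE_dq`, `dI_theta_dq_half`, `dE_dq_half`, `non_smooth`.
#' @export
finite_difference_oracle <- function(q, measure, q0, step, richardson = TRUE) {
  mp <- measure(q0 + step); mm <- measure(q0 - step)
  if (any(is.na(c(mp$I_theta, mm$I_theta, mp$E, mm$E))))
    stop("step-too-large: admissibility lost at the perturbed parameter")
  dI <- (mp$I_theta - mm$I_theta) / (2 * step)
  dE <- (mp$E - mm$E) / (2 * step)
  dI2 <- dE2 <- NA_real_
  non_smooth <- NA
  if (richardson) {
    mp2 <- measure(q0 + step / 2); mm2 <- measure(q0 - step / 2)
    dI2 <- (mp2$I_theta - mm2$I_theta) / step
    dE2 <- (mp2$E - mm2$E) / step
    rel <- function(a, b) if (abs(b) < 1e-12) abs(a - b) else abs(a - b) / abs(b)
    non_smooth <- rel(dI, dI2) > 0.2 || rel(dE, dE2) > 0.2
  }
  structure(list(q = q, dI_theta_dq = dI, dE_dq = dE,
                 dI_theta_dq_half = dI2, dE_dq_half = dE2,
                 non_smooth = non_smooth, method = "finite_difference",
                 step = step),
            class = "parameter_sensitivity")
}

#' Measured threshold and inverse gain as a function of a kinetic parameter
#'
#' Builds the `measure(q)` function used by [finite_difference_oracle()]:
#' noise-free by default for crisp central differences (the sensitivities do
#' not depend on the noise-induced threshold bias, which differentiates
#' away).
#'
#' @param q parameter id ("V_half", "k", "E_X" or "gmax").
#' @param template an [x_conductance()] with the gmax at which to measure.
#' @param membrane a [membrane_params()].
#' @param noise a [noise_params()] or NULL.
#' @param opts an [fi_options()].
#' @return function of the parameter value returning `list(I_theta, E, fi)`.
#' @export
measure_excitability_fn <- function(q, template, membrane = membrane_params(),
                                    noise = NULL, opts = fi_options()) {
  force(template); force(membrane); force(noise); force(opts)
  function(v) {
    xt <- switch(q,
                 V_half = x_modify(template, V_half = v),
                 k = x_modify(template, k = v),
                 E_X = x_modify(template, E_X = v),
                 gmax = x_modify(template, gmax = v),
                 stop("unsupported-parameter: ", q))
    fi <- .fit_for(membrane, xt, noise, opts)
    list(I_theta = fi$I_theta, E = fi$E, fi = fi)
  }
}
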