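#' X-conductance template presets
#'
#' Named templates spanning the conductance classes studied by the
#' sensitivity analysis. All use the standard first-order Boltzmann
#' activation with tau = 5 ms and p = 1 unless noted:
#'
#' * `na_standard` — sodium-type (E_X = +50 mV), V_half = -45, k = 5: sits
#'   near the sub-/supra-threshold boundary so both sensitivities are
#'   resolvable.
#' * `na_sub` — sub-threshold sodium-type, V_half = -60 (persistent-Na-like):
#'   large |S_theta|, negligible S_E.
#' * `na_supra` — supra-threshold sodium-type, V_half = -35: negligible
#'   S_theta, negative S_E.
#' * `k_standard` — potassium-type (E_X = -90 mV), V_half = -45.
#' * `ca_standard` — calcium-type (E_X = +150 mV), V_half = -45.
#' * `na_inactivating` — sub-threshold sodium-type with slow inactivation
#'   (V_half = -60, k = 6, tau = 20 ms).
#' * `na_instantaneous` — as `na_standard` with instantaneous activation.
#' * `loop_sub` / `loop_supra` — the sub- and supra-threshold templates used
#'   by the homeostatic-loop demonstrations (same kinetics as `na_sub` /
#'   `na_supra`).
#'
#' @param name template name.
#' @param gmax maximal conductance of the returned object, mS/cm^2.
#' @return An [x_conductance()].
#' @export
x_template <- function(name = c("na_standard", "na_sub", "na_supra",
                                "k_standard", "ca_standard",
                                "na_inactivating", "na_instantaneous",
                                "loop_sub", "loop_supra"),
                       gmax = 0) {
  name <- match.arg(name)
  act <- function(vh, k, tau = 5) gate_kinetics(vh, k, tau, "activation")
  switch(name,
    na_standard = x_conductance(gmax, 1, act(-45, 5), E_X = 50),
    na_sub = x_conductance(gmax, 1, act(-60, 5), E_X = 50),
    na_supra = x_conductance(gmax, 1, act(-35, 5), E_X = 50),
    k_standard = x_conductance(gmax, 1, act(-45, 5), E_X = -90),
    ca_standard = x_conductance(gmax, 1, act(-45, 5), E_X = 150),
    na_inactivating = x_conductance(gmax, 1, act(-60, 6),
      inactivation = gate_kinetics(-60, 6, 20, "inactivation"), E_X = 50),
    na_instantaneous = x_conductance(gmax, 1,
      gate_kinetics(-45, 5, "instantaneous", "activation"), E_X = 50),
    loop_sub = x_conductance(gmax, 1, act(-60, 5), E_X = 50),
    loop_supra = x_conductance(gmax, 1, act(-35, 5), E_X = 50))
}
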