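---
title: "Models and methods: how ipsense quantifies intrinsic plasticity effects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: how ipsense quantifies intrinsic plasticity effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

Intrinsic plasticity (IP) modifies a neuron's voltage-gated conductances and
thereby its input-output function. On the frequency-current (f-I) relation,
which this package takes as the operational readout of rate coding, IP can
shift the current threshold (rheobase) $I_\theta$, change the gain
$1/E$ (we work with the inverse gain $E$, in µA/cm² per Hz), or both. With a
near-linear f-I relation

$$f(I) = H(I - I_\theta)\,\frac{I - I_\theta}{E},$$

the effect of changing the maximal conductance $g_{max}$ of a generic
voltage-gated "X" conductance decomposes, by the chain rule, into

$$\frac{df}{dg_{max}} = -\frac{S_\theta + f\,S_E}{E},
\qquad S_\theta = \frac{dI_\theta}{dg_{max}},
\qquad S_E = \frac{dE}{dg_{max}}.$$

The package's central empirical finding (reproduced in the acceptance suite)
is that $I_\theta$ and $E$ depend linearly on $g_{max}$ over several orders
of magnitude, so the two sensitivities are constants of the conductance
*kinetics*, not of the amount of conductance. Mapping them over the
half-activation potential $V_{1/2}$ and e-fold slope $k$ of the activation
Boltzmann reveals two essentially disjoint domains: sub-threshold
conductances (substantially activated at the effective AP-threshold
potential $V_\theta$) control the threshold; supra-threshold, spike-driven
conductances control the gain.

## The conductance-based model

A single-compartment membrane,

$$C\dot V = I + I_{noise} - I_L - I_{Na} - I_{Kdr} - I_X
  \;(-\,I_{CaL}\ \text{in the loop model}),$$

with leak $I_L = g_L (V - E_L)$ and regular-spiking neocortical AP currents
(transient sodium $g_{Na} m_\infty^3(V)\, h\,(V - V_{Na})$ with
instantaneous activation, and delayed-rectifier potassium
$g_K n^4 (V - V_K)$), the Golomb-Amitai kinetics stored as the swappable
parameter set `"golomb_rs"`. The plastic conductance is

$$I_X = g_{max}\, x^p\, y\, (V - E_X), \qquad
\tau_x \dot x = x_\infty(V) - x, \qquad
x_\infty(V) = \frac{1}{1 + e^{-(V - V_{1/2})/k}},$$

with optional first-order inactivation $y$ of the same Boltzmann form and
opposite sign. Integration is fixed-step RK4 at `dt = 0.01` ms (halving the
step changes measured rates by < 1%, a property test). Gates start at their
steady-state values for the initial voltage; a 200 ms settling period
precedes every measurement.

Key numerical parameters (units mV, ms, µA/cm², mS/cm², µF/cm², µM):

| parameter | value | note |
|---|---|---|
| $C$ | 1 | specific capacitance |
| $g_L$, $E_L$ | 0.05, −70 | membrane time constant 20 ms |
| $g_{Na}$, $V_{Na}$ | 24, 55 | $m_\infty$: −30/9.5 (cubed); $h$: −53/−7 |
| $g_{K}$, $V_K$ | 3, −90 | $n$: −30/10 (fourth power) |
| $\tau_n(V)$ | 1.11 + 5.55·Boltz(V; −27, −15) | calibrated so the baseline AP lasts 1.80 ms at −20 mV |
| standard X | $V_{1/2}=-45$, $k=5$, $\tau_x=5$, $p=1$, $E_X=+50$ | sodium-type, near the domain boundary |

The AP-current constants follow the cited regular-spiking model; the
delayed-rectifier time constant was scaled once so the baseline action
potential, measured at the −20 mV level, lasts 1.80 ms — the center of the
admissibility band (below) — because the baseline model must pass its own
filter by construction. The standard template sits near the sub-/supra-
threshold boundary so that both $S_\theta$ and $S_E$ are resolvable there
(the linearity criterion exercises both regressions).

## Background synaptic noise

Excitatory and inhibitory populations of independent Poisson trains
(exc: 100 trains × 3 synchronized inputs at 2 Hz, τ = 2 ms, E = 0 mV;
inh: 50 × 3 at 5 Hz, τ = 10 ms, E = −80 mV) provide the in-vivo-like drive
that linearizes the f-I relation and sustains a spontaneous discharge. The
excitatory unitary conductance (0.0128 mS/cm²) was calibrated once so the
standard model fires at ≈ 15 Hz with zero injected current, and then frozen;
the inhibitory unitary conductance is 0.002 mS/cm². Identical marks make
the superposition of the per-train processes equivalent to one Poisson
stream per population at the summed rate, which is how the integrator
draws events (reproducible from a single seed). What the generator does
*not* emulate: synaptic rise times, short-term depression, correlations
between inputs, and conductance saturation — a green 15 Hz test therefore
establishes the calibrated operating point, not biological completeness of
the noise model.

## Measuring threshold, gain and sensitivities

* **Rate**: mean over 30 inter-spike intervals after settling.
  Near threshold the discharge is intermittent and the 30-ISI estimator
  reports the intra-burst rate; the threshold scan therefore defines
  "non-null frequency" within a finite probe window (4 s by default, with a
  fallback to the full measurement window when the short probe misses
  sparse firing).
* **f-I fit**: the currents eliciting 5 Hz and 60 Hz are located by
  bisection; 30 (scaled runs: 10-15) uniformly spaced currents in between
  are measured and the gain is the model-I (OLS) regression slope, with the
  correlation t-test (n−2 df) as the significance check. The window cuts
  the noise-dominated foot and the saturation shoulder.
* **Threshold**: *not* the regression intercept (biased when the gain
  changes) but the first current eliciting a non-null mean frequency,
  located on a scan grid and refined by bisection to 1% of the window.
* **Admissibility** (exclusion categories defining the physiological
  range): no discharge at +5 µA/cm² (high threshold / depolarization
  block); discharge at −5 µA/cm² (unrealistically negative threshold); gain
  outside baseline × [1/2.5, 2.5] (bounds inclusive); frequency saturation
  inside the fit window (upper-third local slope < 25% of lower-third);
  AP duration outside 1.8 ms ± 25% at −20 mV. The probe currents are about
  ±10× the bare rheobase (0.38 µA/cm²), scaled to this model: the model
  blocks above ≈ 8 µA/cm², so a 30 µA/cm² probe would misclassify
  everything including the baseline.
* **Sensitivities**: $g_{max}$ climbs a geometric ladder from
  $g_1 = g_L/1000$ (validated to leave $I_\theta$ and $E$ unchanged within
  0.5%, with automatic halving otherwise) until a category fails;
  $S_\theta$ and $S_E$ are the regression slopes of $I_\theta(g_{max})$ and
  $E(g_{max})$ over the admissible ladder. The default ratio is √2;
  map-scale runs use 4-8 (the estimates are slopes and are insensitive to
  ladder density once ≥ 4 points span the effective range — doubling $g_1$
  changes them by < 5%).

## The reduced (integrate-and-fire) theories

The reduced description uses the resting potential $V_r$ (= rest, −70), the
phenomenological spike threshold $V_s$ and the effective AP threshold
$V_\theta$, with $V_r < V_\theta \le V_s$.

**Threshold potentials.** $V_\theta$ is the local maximum (knee) of the
steady-state I-V relation $I_{hold}(V)$ — the saddle-node voltage that sets
the noise-free rheobase exactly (−58.4 mV for the bare model, knee current
0.376 vs measured rheobase 0.378 µA/cm²). $V_s$ is the following local
minimum (−37.6 mV), beyond which the spike is autonomous. A dV/dt-based
trace criterion (10 mV/ms) is also implemented; it lands ≈ 17 mV more
depolarized because it locates the upstroke inflection, not the saddle —
the criterion used is always recorded. Estimates are averaged over a weak
$g_{max}$ probe range.

**Threshold theory.** With instantaneous activation the threshold current
is the steady current at $V_\theta$, so

$$S_\theta = x_\infty(V_\theta)^p\,(V_\theta - E_X)$$

(times the steady inactivation at $V_\theta$ if present). Conductances
sharing $x_\infty(V_\theta)$ share $S_\theta$; iso-sensitivity lines in the
$(V_{1/2}, k)$ plane are straight and intersect at the central point
$O = (V_\theta, 0)$.

**Inverse-gain theories.** Three activation hypotheses over one ISI of the
leak + X membrane (integrated from $V_r$, spike emitted at $V_s$, frequency
$= 1/T$; the spike-duration correction $1/(T + T_{sp})$ is neglected, an
error that stays below ~16% up to 100 Hz and largely cancels in the
$g_{max}$-slope):

* *pre-spike* — the gate builds up from its resting level toward
  $x_\infty(V(t))$ with time constant $\tau_x$ (buildup in isolation);
* *post-spike* — the gate relaxes exponentially from its end-of-spike level,
  the spike having been entered at resting activation (relaxation in
  isolation);
* *pre/post-spike* — relaxation from the *self-consistent* end-of-spike
  level: the pre-spike buildup to $x_\infty(V_s)$ is carried through the
  spike (elevated further toward $x_\infty(V_{ap})$ over the 1.8 ms spike)
  and relaxes during the initial ISI period.

$S_E$ is the slope of the theory's inverse gain in $g_{max}$, evaluated in
the weak-conductance linear regime with the same 5-60 Hz window as the
simulations. A design note: a formulation in which the late-ISI gate
follows its quasi-steady value along the *bare-leak* voltage path was
implemented and rejected — the leaky reduced model crawls through the
saddle region that the real type-I neuron crosses with regenerative sodium
current, so that formulation's foot-dominated gain artifact anticorrelates
with the conductance-based measurements. The retained pre/post theory
reproduces the measured $S_E$ over the supra-threshold domain with r ≈ 0.96
and the correct sign everywhere, including the sign flip for potassium-type
reversal.

## Generalization to kinetic parameters

For a kinetic parameter $q$ ($V_{1/2}$, $k$, $E_X$),
$dI_\theta/dq = (dg_{max}/dq)\,S_\theta + g_{max}\,\partial S_\theta/\partial q$,
the first term vanishing when the plasticity of $g_{max}$ and $q$ are
independent. The $\partial S_\theta/\partial q$ are hand-derived closed
forms of the Boltzmann; $\partial S_E/\partial q$ uses central differences
of the deterministic theory value. This is a first-order theory: it is
validated (10%) against simulation finite differences at
$g_{max} = g_L/10$; at ten times that conductance the drift of $V_\theta$
itself — a second-order effect outside the theory — grows to tens of
percent.

## The homeostatic IP loop

A high-threshold calcium current $I_{CaL} = g_{CaL} m^2 (V - E_{Ca})$
($g_{CaL} = 0.02$, $m$: −20/6, τ = 1.5 ms, $E_{Ca} = 150$) translates
spiking into calcium influx into a 1 µm shell under a 10 µm-radius soma
(surface-to-volume factor 1.107 µm⁻¹), buffered back to the basal 0.1 µM
with τ = 100 ms. The resulting calcium-frequency relation is close to
linear (r > 0.999; slope ≈ 0.015 µM/Hz, i.e. ≈ 1 µM at 60 Hz). Calcium
drives a kinase/phosphatase cycle setting the phosphorylated, functional
fraction $f_\phi$ of the X channels:

$$\dot f_\phi = R_K(Ca)(1 - f_\phi) - R_P(Ca) f_\phi, \qquad
R_{K,P} = v_{K,P}\,\frac{Ca^{n}}{Ca^{n} + K_{K,P}^{n}}, \qquad
g_{max} = g_{sup} f_\phi.$$

Defaults: $v_K = 1.4\times10^{-4}$, $v_P = 2.9\times10^{-3}$ ms⁻¹,
$K_K = 0.15$, $K_P = 1.2$ µM, $n = 3$, $g_{sup} = 0.05$ mS/cm². The kinase
is the more calcium-sensitive enzyme but saturates lower, so the stationary
fraction falls from ≈ 0.95 at basal calcium to ≈ 0.06 under strong drive —
the homeostatic sign — while the time constant $1/(R_K + R_P)$ shrinks
from ≈ 30 s (slow induction in silence) to ≈ 0.4 s (rapid homeostasis under
hyper-activity). Physiological induction times are hours; tens of seconds
keeps the co-integration at dt = 0.01 ms affordable and preserves the
complete separation of timescales (membrane ms ≪ calcium 0.1 s ≪ cycle
10-100 s), which is what the loop's qualitative outcome depends on.

Silent neuron, no synaptic drive: $f_\phi$ rises, the threshold falls by
$S_\theta g_{sup} f_\phi$, and a spontaneous discharge emerges iff the
maximal modification crosses zero rheobase —
$I_{\theta,0} + S_\theta g_{sup} \le 0$ — i.e. only for sub-threshold
(large $|S_\theta|$) templates; the equilibrium rate settles where the
homeostatic brake balances the threshold advance (≈ 25 Hz for the
sub-threshold demonstration template). A rate-based engine (linear f-I with
the plastic threshold, linearized calcium, same cycle) reproduces the
conductance-based firing/silent map; both are compared cell-by-cell in the
acceptance suite. Stationarity criterion for reported steady frequencies:
the 1 s-binned rate changes < 2% over the last 20% of the run.

## Numerical and testing choices

* Fixed-step RK4 throughout; synaptic conductances decay analytically
  within a step; Poisson events are delivered at step boundaries.
* Gating functions are tabulated (0.05 mV grid, linear interpolation)
  for speed; the table approximation changes measured rates by < 0.01 Hz.
* Bisections: current-for-rate to (window/256); threshold refinement to
  (window/100); auxiliary activation-threshold currents to 1e-6 relative.
* All stochastic runs derive their stream from one master seed via a
  stable string hash (component streams independent of each other).
* Acceptance tests run 5×5 maps (publication-scale maps are >10³ nodes),
  geometric ratios 4-8 instead of √2, and 10 fit points instead of 30 —
  scaled sizes, unchanged protocol and unchanged tolerances. A green
  acceptance suite establishes that the scaled protocol reproduces the
  qualitative structure (linearity, dichotomy, theory agreement, loop
  border), not the publication-scale map resolution.
* A known nonlinear corner of the parameter space — steep activation
  (small k), half-activation near the threshold/rest region, fast
  activation, sodium-type reversal — breaks the linear g_max dependence:
  $I_\theta(g_{max})$ is strongly concave there (the I–V knee migrates as
  the conductance grows), so the regression slope under-reports the
  first-order sensitivity by up to ~4×. The linear fit is still applied,
  and the `linear` flag (r² > 0.99 of each regression) exposes these
  cells; map-level comparisons against the analytic theories are made over
  flagged-linear cells, where the constant-sensitivity description is
  well defined.

## Known limitations

* Voltage-independent activation time constants only.
* One X conductance at a time; no interactions between plastic conductances.
* Type I (continuous f-I) excitability only; the AP set is swappable but
  only the regular-spiking set ships.
* The admissibility probes are calibrated to this model's current scale;
  other AP models need rescaled probes.
* The inverse-gain theories are semi-quantitative (sign and structure,
  factor ≈ 1.3 in magnitude on the supra-threshold domain).
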