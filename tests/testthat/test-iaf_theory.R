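test_that("iso-sensitivity lines: closed forms and common intersection", {
  ln <- iso_sensitivity_lines(c(0.5, 0.9), V_theta = -50, p = 1)
  expect_equal(ln$slope[1], 0)            # c = 0.5: vertical-intercept line
  expect_equal(ln$intercept, c(-50, -50)) # all lines pass through (V_theta, 0)
  # c = 0.9, p = 1, k = 5: V_half = V_theta - 5 ln 9
  expect_equal(ln$intercept[2] + 5 * ln$slope[2], -50 - 5 * log(9))
  # any two distinct levels intersect exactly at (V_theta, 0)
  l2 <- iso_sensitivity_lines(c(0.2, 0.7), V_theta = -55, p = 2)
  expect_equal(l2$intercept[1], l2$intercept[2])
  expect_error(iso_sensitivity_lines(c(0, 0.5), -50), "levels must lie in")
  expect_error(iso_sensitivity_lines(1.2, -50), "levels must lie in")
})

test_that("analytic threshold sensitivity: zeros and kinetics dependence", {
  iaf <- iaf_params(V_r = -70, V_s = -40, V_theta = -55)
  # zero driving force
  x1 <- x_conductance(0, 1, gate_kinetics(-60, 5, 5), E_X = -55)
  expect_equal(s_theta_analytic(x1, iaf), 0)
  # no activation at threshold (V_half far depolarized)
  x2 <- x_conductance(0, 1, gate_kinetics(40, 2, 5), E_X = 50)
  expect_lt(abs(s_theta_analytic(x2, iaf)), 1e-10)
  # depends on (V_half, k) only through x_inf(V_theta)^p: two templates with
  # equal steady activation at V_theta share S_theta exactly
  xa <- x_conductance(0, 1, gate_kinetics(-60, 5, 5), E_X = 50)
  c0 <- boltzmann_steady_state(-55, xa$activation)
  k2 <- 8
  vh2 <- -55 - k2 * log(c0 / (1 - c0)) # same x_inf(V_theta) with another slope
  xb <- x_conductance(0, 1, gate_kinetics(vh2, k2, 20), E_X = 50)
  expect_equal(s_theta_analytic(xa, iaf), s_theta_analytic(xb, iaf),
               tolerance = 1e-10)
  # sign: inward conductance active at threshold
  expect_lt(s_theta_analytic(xa, iaf), 0)
})

test_that("steady I-V thresholds match the rheobase and are dt-robust", {
  mem <- std_membrane()
  x0 <- x_template("na_standard", 0)
  th <- iv_thresholds(mem, x0)
  expect_lt(th$V_theta, th$V_s)
  expect_gt(th$I_knee, 0)
  # stability of V_theta under a weak conductance probe (g1-range averaging)
  thg <- iv_thresholds(mem, x_template("na_standard", mem$g_L / 1000))
  expect_lt(abs(th$V_theta - thg$V_theta), 1)
})

test_that("effective threshold from traces: idealized and model-based", {
  # idealized IAF fixture: sawtooth ramps that take off at -50 mV
  dt <- 0.01
  ramp <- c(seq(-70, -50, length.out = 3000), seq(-50, 30, length.out = 60),
            seq(30, -70, length.out = 60))
  V <- rep(ramp, 4)
  tr <- structure(list(V = V, dt = dt,
                       spike_times = detect_spikes(V, dt)$spike_times),
                  class = "hh_trace")
  est <- effective_threshold(tr, "dvdt", dvdt_crit = 10)
  expect_lt(abs(est$V_theta - (-50)), 2)
  # HH-trace estimate: dt refinement moves V_theta by < 0.5 mV
  mem <- std_membrane()
  vt <- sapply(c(0.01, 0.005), function(d) {
    t2 <- simulate_neuron(mem, x_template("na_standard", 0), I = 1, dt = d,
                          t_max = 1200, settle = 400, record_every = 1L)
    effective_threshold(t2, "dvdt")$V_theta
  })
  expect_lt(abs(diff(vt)), 0.5)
})

test_that("reduced-model trajectory: leaky closed form and monotone T(I)", {
  mem <- std_membrane()
  iaf <- iaf_params(V_r = -70, V_s = -40, V_theta = -55, membrane = mem)
  x0 <- x_template("na_standard", 0)
  tr <- iaf_trajectory("pre", x0, iaf, I = 2)
  gL <- mem$g_L
  Tclosed <- mem$capacitance / gL *
    log((2 - gL * (iaf$V_r - mem$E_L)) / (2 - gL * (iaf$V_s - mem$E_L)))
  expect_rel(tr$T, Tclosed, 1e-3)
  expect_equal(tr$f, 1000 / tr$T)
  # T strictly decreasing in I (numeric sweep)
  Ts <- vapply(c(1.7, 2, 2.5, 3.5, 5), function(I)
    iaf_trajectory("prepost", x_template("na_supra", 0.01), iaf, I,
                   record = FALSE)$T, numeric(1))
  expect_true(all(diff(Ts) < 0))
  expect_error(iaf_trajectory("pre", x0, iaf, I = 0.5), class = "ipsense_no_spike")
})

test_that("spike-duration bias on 1/T frequencies is minute below 100 Hz", {
  T_spike <- 1.8
  f <- seq(5, 100, by = 5)
  T <- 1000 / f
  rel_err <- abs(1 / T - 1 / (T + T_spike)) / (1 / T)
  expect_lt(max(rel_err), 0.16)
  expect_lt(rel_err[f == 50][1], 0.09)
})

test_that("inverse-gain theories: inert conductance, signs, reductions", {
  mem <- std_membrane()
  iaf <- estimate_iaf_params(mem, x_template("na_standard"))
  # activation never engaged: S_E = 0
  x_inert <- x_conductance(0, 1, gate_kinetics(60, 2, 5), E_X = 50)
  expect_lt(abs(s_E_analytic(x_inert, iaf, "prepost")), 1e-6)
  # supra-threshold inward: gain increases (S_E < 0)
  expect_lt(s_E_analytic(x_template("na_supra"), iaf, "prepost"), 0)
  # potassium reversal flips the sign at matched kinetics
  k_supra <- x_modify(x_template("k_standard"), V_half = -35)
  expect_gt(s_E_analytic(k_supra, iaf, "prepost"), 0)
  # with a flat activation between V_r and V_s (no buildup possible) the
  # pre/post theory reduces exactly to the post-only theory
  x_flat <- x_conductance(0, 1, gate_kinetics(20, 2, 5), E_X = 50)
  expect_equal(s_E_analytic(x_flat, iaf, "prepost"),
               s_E_analytic(x_flat, iaf, "post"), tolerance = 1e-8)
  # theory maps are deterministic
  g <- grid_spec(c(-50, -40), c(4, 6), 10, 2)
  m1 <- theory_map(g, x_template("na_standard"), iaf, "prepost")
  m2 <- theory_map(g, x_template("na_standard"), iaf, "prepost")
  expect_identical(as.data.frame(m1), as.data.frame(m2))
})

test_that("auxiliary activation-threshold currents solve the clamped relation", {
  iaf <- iaf_params(V_r = -70, V_s = -40, V_theta = -55)
  x <- x_conductance(0.02, 1, gate_kinetics(-50, 5, 5), E_X = 50)
  Ia <- activation_threshold_currents(x, iaf)
  # closed form: I_a = g_L (V_theta - E_L) + g a^p (V_theta - E_X)
  for (nm in names(Ia)) {
    a <- switch(nm, I0 = 0, I1 = 1,
                I_xr = boltzmann_steady_state(-70, x$activation),
                I_xs = boltzmann_steady_state(-40, x$activation))
    closed <- iaf$g_L * (iaf$V_theta - iaf$E_L) + x$gmax * a * (iaf$V_theta - x$E_X)
    expect_lt(abs(Ia[[nm]] - closed), 1e-4)
  }
})
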