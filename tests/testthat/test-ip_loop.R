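test_that("aKP closed forms: Hill limits and homeostatic direction", {
  akp <- akp_params()
  d0 <- akp_dynamics(0, 0.5, akp)
  expect_equal(d0$R_K, 0)            # Hill terms vanish at the origin
  expect_equal(d0$R_P, 0)
  expect_equal(d0$dfdt, 0)
  expect_equal(d0$tau, Inf)
  db <- akp_dynamics(0.1, 0, akp)    # basal calcium
  dh <- akp_dynamics(2, 0, akp)      # hyper-activity
  expect_gt(db$f_star, 0.9)          # silent neuron: functional fraction high
  expect_lt(dh$f_star, 0.2)          # active neuron: fraction driven down
  expect_gt(db$tau, 10 * dh$tau)     # slow at low activity, fast at high
  # f* monotone decreasing in calcium over the physiological range
  ca <- seq(0.05, 3, by = 0.05)
  fstar <- akp_dynamics(ca, 0, akp)$f_star
  expect_true(all(diff(fstar) < 1e-9))
  # tau maximal at the basal end
  tau <- akp_dynamics(ca, 0, akp)$tau
  expect_equal(which.max(tau), 1L)
})

test_that("step-calcium relaxation matches the closed-form time constant", {
  akp <- akp_params()
  Ca <- 0.8
  d <- akp_dynamics(Ca, 0, akp)
  dt <- 5
  f <- 0
  ts <- seq(dt, 8 * d$tau, by = dt)
  fs <- numeric(length(ts))
  for (i in seq_along(ts)) {
    k1 <- akp_dynamics(Ca, f, akp)$dfdt
    k2 <- akp_dynamics(Ca, f + dt / 2 * k1, akp)$dfdt
    k3 <- akp_dynamics(Ca, f + dt / 2 * k2, akp)$dfdt
    k4 <- akp_dynamics(Ca, f + dt * k3, akp)$dfdt
    f <- f + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    fs[i] <- f
  }
  # exponential-fit oracle: log-linear regression of (f* - f)
  keep <- fs < 0.99 * d$f_star
  fit <- model_I_regression(ts[keep], log(d$f_star - fs[keep]))
  expect_rel(-1 / fit$slope, d$tau, 0.02)
  expect_rel(fs[length(fs)], d$f_star, 0.01)
})

test_that("calcium-frequency relation is close to linear", {
  mem <- std_membrane()
  cf <- fit_ca_frequency(mem, x_template("loop_sub"), currents = seq(0.5, 2.5, 0.5),
                         t_probe = 2000)
  expect_gt(cf$fit$r, 0.99)
  expect_gt(cf$slope, 0)
  # calcium stays at/above basal (influx + relaxation structure)
  expect_true(all(cf$data$Ca >= calcium_params()$Ca_b - 1e-6))
})

test_that("decoupled loop (g_sup = 0) stays silent while f_phi relaxes", {
  mem <- std_membrane()
  akp0 <- akp_params(g_sup = 0)
  tr <- simulate_loop_hh(mem, x_template("loop_sub"), calcium_params(), akp0,
                         duration = 30000, record_every = 2000L)
  expect_false(tr$fired)
  expect_equal(tr$steady_frequency, 0)
  # f_phi heads toward its basal stationary value
  fb <- akp_dynamics(calcium_params()$Ca_b, 0, akp_params())$f_star
  expect_gt(tail(tr$f_phi, 1), 0.5 * (1 - exp(-1)) * fb)
  expect_true(all(tr$f_phi >= 0 & tr$f_phi <= 1))
  expect_equal(tr$gmax, 0 * tr$f_phi)
})

test_that("rate-engine loop: frozen threshold stays silent, plastic one fires", {
  akp <- akp_params()
  # S_theta = 0: threshold never moves; silent forever at I = 0
  tr0 <- simulate_loop_rate(S_theta = 0, I_theta0 = 0.4, E0 = 0.04, akp = akp,
                            duration = 60000)
  expect_false(tr0$fired)
  expect_equal(tr0$steady_frequency, 0)
  # sufficiently negative S_theta: threshold crosses zero, discharge emerges
  tr1 <- simulate_loop_rate(S_theta = -60, I_theta0 = 0.4, E0 = 0.04, akp = akp,
                            duration = 120000)
  expect_true(tr1$fired)
  expect_gt(tr1$steady_frequency, 0)
  expect_true(all(tr1$f_phi >= 0 & tr1$f_phi <= 1))
  # border case criterion: I_theta0 + S_theta g_sup f* > 0 stays silent
  s_border <- -0.9 * 0.4 / (akp$g_sup *
    akp_dynamics(calcium_params()$Ca_b, 0, akp)$f_star)
  tr2 <- simulate_loop_rate(S_theta = s_border, I_theta0 = 0.4, E0 = 0.04,
                            akp = akp, duration = 120000)
  expect_false(tr2$fired)
})

test_that("conductance-based loop: sub-threshold template fires, f_phi bounded", {
  mem <- std_membrane()
  tr <- simulate_loop_hh(mem, x_template("loop_sub"), calcium_params(),
                         akp_params(), duration = 60000, record_every = 2000L)
  expect_true(tr$fired)
  expect_gt(tr$steady_frequency, 1)
  expect_true(all(tr$f_phi >= 0 & tr$f_phi <= 1))
  expect_true(all(tr$Ca >= 0))
  expect_equal(tr$gmax, akp_params()$g_sup * tr$f_phi)
  # calcium rises above basal once firing starts
  expect_gt(max(tr$Ca), calcium_params()$Ca_b * 2)
})
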