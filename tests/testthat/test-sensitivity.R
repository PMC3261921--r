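# synthetic fi_curve fixture for admissibility category tests
make_fi <- function(gain = 25, ap = 1.8, currents = seq(0, 2, length.out = 12),
                    I_theta = -0.1, sat = FALSE) {
  freqs <- if (sat) {
    60 * (1 - exp(-2.2 * currents)) # saturating shoulder inside the window
  } else {
    gain * (currents - I_theta)
  }
  structure(list(currents = currents, frequencies = freqs, n_isi = 30L,
                 I_theta = I_theta, E = 1 / gain, gain = gain,
                 fit = model_I_regression(currents, freqs),
                 F_low = 5, F_high = 60, I_low = min(currents),
                 I_high = max(currents), ap_duration = ap,
                 spontaneous = FALSE, poor_linearity = FALSE),
            class = "fi_curve")
}

test_that("admissibility categories from fit diagnostics", {
  mem <- std_membrane()
  x <- x_template("na_standard", 0.01)
  base <- make_fi(gain = 25)
  chk <- function(fi) admissibility_check(mem, x, NULL, base, fi_options(),
                                          fi = fi, run_probes = FALSE)
  expect_equal(chk(make_fi(gain = 25))$category, "pass")
  # gain bounds are inclusive at exactly 2.5x / (1/2.5)x
  expect_equal(chk(make_fi(gain = 25 * 2.5))$category, "pass")
  expect_equal(chk(make_fi(gain = 25 * 2.5 + 0.01))$category, "high_gain")
  expect_equal(chk(make_fi(gain = 25 / 2.5))$category, "pass")
  expect_equal(chk(make_fi(gain = 25 / 2.5 - 0.01))$category, "low_gain")
  # AP duration band 1.8 ms +/- 25%
  expect_equal(chk(make_fi(ap = 2.5))$category, "long_AP")   # 2.5 > 2.25
  expect_equal(chk(make_fi(ap = 1.0))$category, "short_AP")  # 1.0 < 1.35
  expect_equal(chk(make_fi(ap = 2.25))$category, "pass")
  # frequency saturation inside the fit window
  expect_equal(chk(make_fi(sat = TRUE))$category, "saturation")
})

test_that("current probes classify extreme models", {
  mem <- std_membrane()
  base <- make_fi()
  opts <- test_opts()
  # enormous outward conductance: no discharge at the large probe current
  x_block <- x_conductance(3, 1, gate_kinetics(-80, 5, 5), E_X = -90)
  v <- admissibility_check(mem, x_block, NULL, base, opts)
  expect_equal(v$category, "high_threshold")
  # strong low-threshold inward conductance: fires even at the negative probe
  x_spont <- x_conductance(0.07, 1, gate_kinetics(-75, 2, 5), E_X = 50)
  v2 <- admissibility_check(mem, x_spont, NULL, base, opts)
  expect_equal(v2$category, "spontaneous")
  # the baseline model passes its own filter by construction
  rf <- ipsense:::.closure_for(mem, x_template("na_standard", 0), NULL, opts)
  fi0 <- fit_fi(rf, opts$F_low, opts$F_high, opts$n_points, c(0, 3))
  v3 <- admissibility_check(mem, x_template("na_standard", 0), NULL, fi0,
                            opts, fi = fi0)
  expect_equal(v3$category, "pass")
})

test_that("gmax progression on a pass-all stub covers the requested ladder", {
  # exercise the geometric ladder logic through estimate_sensitivities on a
  # linear synthetic world: I_theta(g) = a + S g, E constant
  mem <- std_membrane()
  # duplicate-leak X conductance (E_X = E_L, always-open gate): the threshold
  # shift has the closed-form leak oracle S_theta = V_theta_eff - E_L
  x_leak <- x_conductance(0, 1, gate_kinetics(-120, 2, 0.1), E_X = mem$E_L)
  opts <- test_opts(n_points = 8L)
  est <- estimate_sensitivities(x_leak, mem, noise = NULL, g1 = 5e-5,
                                ratio = 8, opts = opts)
  # closed-form leak-addition oracle: rheobase = knee of the algebraic steady
  # I-V relation; regress it over the same gmax ladder (no simulation)
  knee <- vapply(est$gmax, function(g)
    iv_thresholds(mem, x_modify(x_leak, gmax = g))$I_knee, numeric(1))
  oracle <- model_I_regression(est$gmax, knee)$slope
  expect_rel(est$S_theta, oracle, 0.1)
  expect_gt(est$S_theta, 0)  # added leak raises the threshold
  # first-order closed form at weak conductance: S_theta ~ V_theta - E_L
  vtheta <- iv_thresholds(mem, x_modify(x_leak, gmax = 0))$V_theta
  d <- 0.005
  fd <- (iv_thresholds(mem, x_modify(x_leak, gmax = d))$I_knee -
         iv_thresholds(mem, x_modify(x_leak, gmax = 0))$I_knee) / d
  expect_rel(fd, vtheta - mem$E_L, 0.1)
  # progression is a strictly increasing geometric sequence
  expect_true(all(diff(log(est$gmax)) > 0))
  expect_rel(max(diff(log(est$gmax))), log(8), 1e-9)
})

test_that("sensitivities are independent of the progression origin", {
  mem <- std_membrane()
  xt <- x_template("na_standard")
  opts <- test_opts(n_points = 8L)
  e1 <- estimate_sensitivities(xt, mem, noise = NULL, g1 = 5e-5, ratio = 2,
                               opts = opts)
  e2 <- estimate_sensitivities(xt, mem, noise = NULL, g1 = 1e-4, ratio = 2,
                               opts = opts)
  expect_rel(e2$S_theta, e1$S_theta, 0.05)
  expect_rel(e2$S_E, e1$S_E, 0.05)
})

test_that("degenerate start errors cleanly", {
  mem <- std_membrane()
  # an X that already reshapes excitability at g1 and cannot be downscaled
  x_strong <- x_conductance(0, 1, gate_kinetics(-75, 2, 5), E_X = 50)
  expect_error(
    gmax_progression(x_strong, mem, noise = NULL, g1 = 0.5, ratio = 2,
                     max_downscale = 0L, opts = test_opts(n_points = 8L)),
    "degenerate-start")
})

test_that("compute_map populates cells and records metadata (stub grid)", {
  mem <- std_membrane()
  g <- grid_spec(c(-60, -45), c(4, 8), 15, 4)   # 2 x 2, fast cells
  opts <- test_opts(n_points = 8L)
  m <- compute_map(g, x_template("na_standard"), mem, noise = NULL,
                   ratio = 16, opts = opts)
  expect_equal(nrow(m), 4L)
  expect_true(all(c("V_half", "k", "S_theta", "S_E", "r2_theta", "r2_E",
                    "n_gmax", "fail_category") %in% names(m)))
  expect_equal(attr(m, "ap_model"), "golomb_rs")
  expect_true(all(is.finite(m$S_theta)))
  # sub cell more threshold-sensitive than supra cell
  sub <- m$V_half == -60 & m$k == 4
  sup <- m$V_half == -45 & m$k == 4
  expect_gt(abs(m$S_theta[sub]), abs(m$S_theta[sup]))
})

test_that("map caching resumes without recomputation", {
  mem <- std_membrane()
  tmp <- withr::local_tempdir()
  g <- grid_spec(c(-55, -50), c(5, 5), 5, 1)    # 2 x 1
  opts <- test_opts(n_points = 8L)
  m1 <- compute_map(g, x_template("na_standard"), mem, noise = NULL,
                    ratio = 16, opts = opts, cache_dir = tmp)
  t0 <- Sys.time()
  m2 <- compute_map(g, x_template("na_standard"), mem, noise = NULL,
                    ratio = 16, opts = opts, cache_dir = tmp)
  expect_lt(as.numeric(difftime(Sys.time(), t0, units = "secs")), 30)
  expect_equal(m1$S_theta, m2$S_theta)
})
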