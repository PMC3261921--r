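test_that("mean_frequency: periodic, degenerate and jittered cases", {
  expect_equal(mean_frequency(seq(0, 600, by = 20), 30L), 50)
  expect_equal(mean_frequency(numeric(0)), 0)
  expect_equal(mean_frequency(123.4), 0)
  set.seed(7)
  st <- cumsum(runif(40, 10, 40))
  # brute-force oracle over the event list: n ISIs / elapsed time
  n <- 30L
  oracle <- 1000 * n / (st[n + 1] - st[1])
  expect_equal(mean_frequency(st, n), oracle)
  # fewer spikes than requested ISIs: all available ISIs are used
  expect_equal(mean_frequency(st[1:5], 30L), 1000 * 4 / (st[5] - st[1]))
})

test_that("model-I regression: closed forms and the correlation test", {
  xs <- c(1, 2, 3, 5, 8)
  fit <- model_I_regression(xs, 2 * xs + 1)
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 1)
  expect_equal(fit$r, 1)
  expect_lt(fit$p_value, 1e-10)
  # frozen closed-form OLS for a 5-point textbook set: slope = Sxy/Sxx
  ys <- c(2.1, 2.9, 4.2, 5.8, 9.1)
  sl <- sum((xs - mean(xs)) * (ys - mean(ys))) / sum((xs - mean(xs))^2)
  fit2 <- model_I_regression(xs, ys)
  expect_equal(fit2$slope, sl)
  expect_equal(fit2$t_statistic,
               fit2$r * sqrt((5 - 2) / (1 - fit2$r^2)))
  expect_error(model_I_regression(rep(1, 5), ys), "zero variance")
  expect_error(model_I_regression(1:2, 1:2), "n >= 3")
})

test_that("correlation-test p-values are uniform under the null", {
  set.seed(11)
  n_rep <- 400
  p <- replicate(n_rep, model_I_regression(rnorm(30), rnorm(30))$p_value)
  # Monte-Carlo calibration: rejection rate at 5% within binomial 3-sigma
  rate <- mean(p < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / n_rep))
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("fit_fi recovers a perfectly linear synthetic f-I exactly", {
  rf <- linear_rate_fn(gain = 25, I_theta = 0.5)
  fi <- fit_fi(rf, F_low = 5, F_high = 60, n_points = 12L, I_bracket = c(0, 4))
  expect_rel(fi$gain, 25, 1e-6)
  expect_rel(fi$E, 1 / 25, 1e-6)
  expect_lt(abs(fi$I_theta - 0.5), 0.01)
  expect_false(fi$poor_linearity)
  # affine consistency: shifting the threshold shifts I_theta, not the gain
  rf2 <- linear_rate_fn(gain = 25, I_theta = 1.5)
  fi2 <- fit_fi(rf2, F_low = 5, F_high = 60, n_points = 12L, I_bracket = c(0, 4))
  expect_rel(fi2$gain, 25, 1e-6)
  expect_lt(abs((fi2$I_theta - fi$I_theta) - 1), 0.02)
})

test_that("find_current_threshold: scan semantics and error classes", {
  rf <- linear_rate_fn(gain = 25, I_theta = 0.5)
  th <- find_current_threshold(rf, seq(0, 2, by = 0.1))
  expect_false(attr(th, "spontaneous"))
  expect_lt(abs(as.numeric(th) - 0.5), 0.1 / 4 + 1e-9)
  expect_error(find_current_threshold(rf, seq(-1, 0.2, by = 0.1)),
               class = "ipsense_no_spiking")
  expect_true(attr(find_current_threshold(rf, seq(0.9, 2, 0.1)), "spontaneous"))
})

test_that("threshold precedes the fit window and E matches a finite difference", {
  mem <- std_membrane()
  rf <- rate_closure(mem, x_template("na_standard", 0), NULL, t_max = 8000)
  fi <- fit_fi(rf, n_points = 10L, I_bracket = c(0, 3))
  expect_lte(fi$I_theta, min(fi$currents))
  expect_lt(fi$fit$p_value, 0.05)
  # two-point finite difference of the same curve mid-range vs fitted E
  k <- length(fi$currents)
  i1 <- floor(k / 2); i2 <- i1 + 2L
  E_fd <- (fi$currents[i2] - fi$currents[i1]) /
    (fi$frequencies[i2] - fi$frequencies[i1])
  expect_rel(E_fd, fi$E, 0.25) # noise-free foot curvature allows some slack
  # monotone rate coding across the fitted range
  expect_true(all(diff(fi$frequencies) > -1e-9))
})
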