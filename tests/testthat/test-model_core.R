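test_that("Boltzmann steady state: closed-form values and monotonicity", {
  g <- gate_kinetics(-30, 5, tau = 5)
  expect_equal(boltzmann_steady_state(-30, g), 0.5)
  expect_equal(boltzmann_steady_state(-30 + 5 * log(9), g), 0.9)
  # frozen high-precision oracle value: 1/(1 + exp((-30 - (-50))/5)) at V = -50
  expect_equal(boltzmann_steady_state(-50, g), 0.01798620996209156, tolerance = 1e-12)
  V <- seq(-100, 20, by = 0.5)
  expect_true(all(diff(boltzmann_steady_state(V, g)) > 0))
  gi <- gate_kinetics(-60, 7, tau = 20, type = "inactivation")
  expect_true(all(diff(boltzmann_steady_state(V, gi)) < 0))
  expect_equal(boltzmann_steady_state(-60, gi), 0.5)
  expect_error(gate_kinetics(-30, 0, 5), "k must be non-zero")
  expect_error(gate_kinetics(-30, -5, 5), "strictly positive")
})

test_that("sub-rheobase model is quiescent and relaxes to rest", {
  mem <- std_membrane()
  tr <- simulate_neuron(mem, x_template("na_standard", 0), I = 0,
                        t_max = 1000, record_every = 10L)
  expect_length(tr$spike_times, 0)
  expect_lt(abs(tr$V_end - (-69.8)), 0.5) # rest slightly above E_L (window Na)
  # current conservation at numerical steady state: holding current ~ 0
  expect_lt(abs(steady_iv(mem, x_template("na_standard", 0), tr$V_end)), 1e-3)
})

test_that("bare-model rheobase is stable under dt refinement", {
  mem <- std_membrane()
  x0 <- x_template("na_standard", 0)
  rheo <- function(dt) {
    rf <- rate_closure(mem, x0, NULL, dt = dt, t_max = 3000)
    as.numeric(find_current_threshold(rf, seq(0.2, 1, 0.1), resolution = 0.002))
  }
  r1 <- rheo(0.01)
  r2 <- rheo(0.005)
  expect_lt(abs(r1 - r2) / r1, 0.01)
  # and it matches the steady I-V knee (the bisection oracle's closed-form twin)
  knee <- iv_thresholds(mem, x0)$I_knee
  expect_lt(abs(r1 - knee) / knee, 0.05)
})

test_that("mean frequency converges under dt halving (integration convergence)", {
  mem <- std_membrane()
  x0 <- x_template("na_standard", 0)
  f <- function(dt) {
    out <- ipsense:::.sim_raw(mem, x0, I = 1, dt = dt, t_max = 3000,
                              settle = 200, stop_spikes = 31L)
    mean_frequency(out$spike_times[out$spike_times > 200], 30L)
  }
  expect_lt(abs(f(0.01) - f(0.005)) / f(0.01), 0.01)
})

test_that("inward sub-threshold X raises the firing rate at fixed current", {
  mem <- std_membrane()
  rf0 <- rate_closure(mem, x_template("na_sub", 0), NULL, t_max = 4000)
  rf1 <- rate_closure(mem, x_template("na_sub", 0.02), NULL, t_max = 4000)
  expect_gt(rf1(1), rf0(1))
})

test_that("all gating variables remain in [0, 1]", {
  mem <- std_membrane()
  tr <- simulate_neuron(mem, x_template("na_inactivating", 0.01), I = 2,
                        t_max = 1000, record_every = 5L)
  for (gv in c("x", "h", "n", "y")) {
    expect_true(all(tr[[gv]] >= 0 & tr[[gv]] <= 1), label = paste("gate", gv))
  }
})

test_that("spike detection on constructed series", {
  dt <- 0.01
  quiet <- rep(-65, 2000)
  expect_length(detect_spikes(quiet, dt)$spike_times, 0)
  ap <- synthetic_ap(dt)
  v <- c(rep(-70, 1000), ap, rep(-70, 2000), ap, rep(-70, 2000), ap, rep(-70, 500))
  det <- detect_spikes(v, dt)
  expect_length(det$spike_times, 3L)
  expect_true(all(diff(det$spike_times) > 0))
  expect_length(det$ap_durations, 3L)
  expect_true(all(det$ap_durations > 0 & det$ap_durations < 4))
})

test_that("AP duration of the standard model sits in the admissibility band", {
  mem <- std_membrane()
  tr <- simulate_neuron(mem, x_template("na_standard", 0), I = 1,
                        t_max = 1500, settle = 200, record_every = 0L)
  expect_gt(length(tr$ap_durations), 5)
  d <- mean(tr$ap_durations)
  expect_gt(d, 1.8 * 0.75)
  expect_lt(d, 1.8 * 1.25)
})

test_that("noise is reproducible given the seed and vanishes in the null limit", {
  mem <- std_membrane()
  x0 <- x_template("na_standard", 0)
  nz <- noise_params(seed = 42L)
  t1 <- simulate_neuron(mem, x0, I = 0, noise = nz, t_max = 2000, record_every = 10L)
  t2 <- simulate_neuron(mem, x0, I = 0, noise = nz, t_max = 2000, record_every = 10L)
  expect_identical(t1$V, t2$V)
  expect_identical(t1$spike_times, t2$spike_times)
  t3 <- simulate_neuron(mem, x0, I = 0, noise = noise_params(seed = 43L),
                        t_max = 2000, record_every = 10L)
  expect_false(identical(t3$spike_times, t1$spike_times))
  # E_syn at E_L and g_unit -> 0: mean V agrees with noise-free within 0.5 mV
  nz0 <- noise_params(e = list(n_trains = 100, n_sync = 3, rate = 2,
                               g_unit = 1e-9, tau_syn = 2, E_syn = -70),
                      i = list(n_trains = 50, n_sync = 3, rate = 5,
                               g_unit = 1e-9, tau_syn = 10, E_syn = -70),
                      seed = 1L)
  tn <- simulate_neuron(mem, x0, I = 0, noise = nz0, t_max = 1500, record_every = 10L)
  tq <- simulate_neuron(mem, x0, I = 0, noise = NULL, t_max = 1500, record_every = 10L)
  keep <- seq(50, length(tn$V))
  expect_lt(abs(mean(tn$V[keep]) - mean(tq$V[keep])), 0.5)
})

test_that("spike-count stop raises a timeout error when unattainable", {
  mem <- std_membrane()
  expect_error(
    simulate_neuron(mem, x_template("na_standard", 0), I = 0, t_max = 500,
                    stop_spikes = 5L),
    class = "ipsense_timeout")
})
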