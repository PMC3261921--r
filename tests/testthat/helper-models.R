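# Shared fixtures: cheap canonical objects used across test files.
std_membrane <- function() membrane_params()

# fast options for tests that exercise the full pipeline: fewer fit points
# and shorter probe windows than the analysis defaults, same protocol
test_opts <- function(...) {
  args <- utils::modifyList(list(n_points = 10L, t_max = 8000,
                                 threshold_t_max = 3000), list(...))
  do.call(fi_options, args)
}

# a perfectly linear synthetic rate closure: f = gain * (I - I_theta), 0 below
linear_rate_fn <- function(gain = 25, I_theta = 0.5) {
  fn <- function(I) max(0, gain * (I - I_theta))
  attr(fn, "pars") <- list(membrane = std_membrane(),
                           x = x_template("na_standard", 0), noise = NULL,
                           dt = 0.01, n_isi = 30L, settle = 200, t_max = 1e4)
  fn
}

# stereotyped AP waveform inserted into synthetic voltage series
synthetic_ap <- function(dt, peak = 30, base = -70) {
  tt <- seq(0, 4, by = dt)
  base + (peak - base) * exp(-((tt - 1.2) / 0.6)^2)
}

expect_rel <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / max(abs(expected), 1e-12), tol)
}
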