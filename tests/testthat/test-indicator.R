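test_that("F_min follows from fixed F_max and sensitivity", {
  expect_equal(indicator_params("positive", 1, 0.25)$F_min, 0.8)
  expect_equal(indicator_params("positive", 1, 1)$F_min, 0.5)
  # the 5x-baseline sensitivity axis: 0.2 -> F_min 0.8333, 1.0 -> 0.5
  expect_equal(indicator_params("negative", 1, 0.2)$F_min, 1 / 1.2)
  expect_equal(indicator_params("negative", 1, 5 * 0.2)$F_min, 0.5)
  expect_error(indicator_params("positive", 1, -0.1), "sensitivity")
  expect_error(indicator_params("positive", 0, 0.2), "F_max")
  p <- indicator_params("positive", 100, 0.2)
  expect_equal(p$sensitivity, (p$F_max - p$F_min) / p$F_min)
})

test_that("polarity maps rest and spike to the correct ends of the range", {
  st <- spike_train(50, 400, 400)
  vt <- simulate_voltage_trace(st, subthreshold_sd = 0, seed = 1)
  pp <- indicator_params("positive", 100, 0.25)
  pn <- indicator_params("negative", 100, 0.25)
  fp <- voltage_to_fluorescence(vt, pp)
  fn <- voltage_to_fluorescence(vt, pn)
  expect_equal(fp$f[1], pp$F_min)          # rest -> F_min (positive)
  expect_equal(fp$f[50], pp$F_max)         # spike -> F_max
  expect_equal(fn$f[1], pn$F_max)          # rest -> F_max (negative)
  expect_equal(fn$f[50], pn$F_min)         # spike -> F_min
})

test_that("mirror symmetry: pos + neg = F_min + F_max pointwise", {
  st <- simulate_spike_train(1000, 400, 5, seed = 2)
  vt <- simulate_voltage_trace(st, subthreshold_sd = 0, seed = 2)
  p <- indicator_params("positive", 100, 0.5)
  n <- indicator_params("negative", 100, 0.5)
  fp <- voltage_to_fluorescence(vt, p)$f
  fn <- voltage_to_fluorescence(vt, n)$f
  expect_equal(fp + fn, rep(p$F_min + p$F_max, 1000))
})

test_that("dF/F closed forms hold for a rest-to-spike step", {
  s <- 0.37
  p <- indicator_params("positive", 100, s)
  n <- indicator_params("negative", 100, s)
  v <- c(rep(0, 10), rep(1, 10))
  fp <- voltage_to_fluorescence(v, p)$f
  fn <- voltage_to_fluorescence(v, n)$f
  expect_equal((fp[20] - fp[1]) / fp[1], s)                 # +s
  expect_equal((fn[20] - fn[1]) / fn[1], -s / (1 + s))      # -s/(1+s)
})

test_that("fluorescence is monotone in v and clipped to the range", {
  v <- seq(-0.5, 1.5, by = 0.01)
  p <- indicator_params("positive", 10, 0.5)
  n <- indicator_params("negative", 10, 0.5)
  fp <- voltage_to_fluorescence(v, p)$f
  fn <- voltage_to_fluorescence(v, n)$f
  expect_true(all(diff(fp) >= 0))
  expect_true(all(diff(fn) <= 0))
  expect_true(all(fp >= p$F_min & fp <= p$F_max))
  expect_true(all(fn >= n$F_min & fn <= n$F_max))
})

test_that("optional kinetics filter slows edges without changing the range", {
  p <- indicator_params("positive", 1, 1, tau_on = 2e-3, tau_off = 8e-3)
  v <- c(rep(0, 100), rep(1, 100), rep(0, 200))
  f <- voltage_to_fluorescence(v, p, frame_rate_hz = 1000)$f
  f0 <- voltage_to_fluorescence(v, indicator_params("positive", 1, 1),
                                frame_rate_hz = 1000)$f
  expect_lt(f[101], f0[101])               # rising edge is low-passed
  expect_gt(f[210], f0[210])               # falling edge decays slowly
  # asymmetric taus: rise (tau_on 2 ms) faster than decay (tau_off 8 ms)
  rise_t <- which(f[101:200] > 0.5 + 0.5 * (1 - exp(-1)))[1]
  dec_t <- which(f[201:400] < 1 - 0.5 * (1 - exp(-1)))[1]
  expect_lt(rise_t, dec_t)
})
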