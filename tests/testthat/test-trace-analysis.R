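test_that("bleach fit recovers a known exponential and its tau branch", {
  tvec <- 0:9999
  fit <- fit_bleach(100 * exp(-tvec / 5000))
  expect_lt(abs(fit$tau / 5000 - 1), 0.01)
  expect_false(fit$fallback)
  # constant trace: infinite-tau branch, corrected == input
  cst <- fit_bleach(rep(7, 500))
  expect_identical(cst$tau, Inf)
  expect_equal(cst$corrected, rep(7, 500))
  # with additive offset
  fit2 <- fit_bleach(40 * exp(-tvec / 3000) + 60)
  expect_lt(abs(fit2$tau / 3000 - 1), 0.01)
  expect_lt(abs(fit2$C - 60), 1)
})

test_that("bleach correction flattens a spiking bleached trace", {
  st <- simulate_spike_train(10000, 400, 25, seed = 4)
  vt <- simulate_voltage_trace(st, subthreshold_sd = 0.05, seed = 4)
  f <- voltage_to_fluorescence(vt, indicator_params("positive", 100, 0.5))$f
  bleached <- f * exp(-(0:9999) / 8000)
  corr <- fit_bleach(bleached)$corrected
  # residual baseline slope under 1% of F0 per 10,000 frames
  base <- moving_percentile_baseline(corr, window_s = 1, percentile = 10)
  slope <- coef(lm(base ~ seq_along(base)))[2] * 10000
  expect_lt(abs(slope) / mean(base), 0.01)
})

test_that("bleach-correct after bleaching matches the unbleached trace", {
  st <- spike_train(integer(0), 8000)
  vt <- simulate_voltage_trace(st, subthreshold_sd = 0.05, seed = 9)
  ind <- indicator_params("positive", 100, 0.2)
  f0 <- voltage_to_fluorescence(vt, ind)$f
  corr <- fit_bleach(f0 * exp(-(0:7999) / 6000))$corrected
  expect_lt(sqrt(mean((corr - f0)^2)) / mean(f0), 0.02)
})

test_that("dF/F arithmetic, its identity case, and its inverse", {
  f <- c(rep(100, 50), 110, rep(100, 49))
  d <- compute_dff(f, baseline_window = 1:50)
  expect_equal(d$f0, 100)
  expect_equal(d$dff[51], 0.10)
  expect_equal(compute_dff(rep(5, 100), 1:100)$dff, rep(0, 100))
  expect_equal(dff_to_f(d), f)                       # exact inverse
  expect_error(compute_dff(rep(-1, 100), 1:100), "F0")
})

test_that("forward model round trip: peak dF/F equals the sensitivity", {
  st <- spike_train(300, 600, 400)
  vt <- simulate_voltage_trace(st, subthreshold_sd = 0, seed = 1)
  f <- voltage_to_fluorescence(vt, indicator_params("positive", 100, 0.25))
  d <- compute_dff(f, baseline_window = 1:200)
  expect_equal(max(d$dff), 0.25, tolerance = 1e-9)
})

test_that("moving-percentile baseline: constant, equivariance, spikes", {
  expect_equal(moving_percentile_baseline(rep(4, 500), 1, 10), rep(4, 500))
  st <- tonic_train(4000, 200)
  f <- 50 + 30 * tonic_trace(4000, st)
  base <- moving_percentile_baseline(f, window_s = 1, percentile = 10)
  expect_lt(max(abs(base - 50)), 1e-6)     # sparse spikes are ignored
  # adding a constant shifts the baseline by that constant
  base2 <- moving_percentile_baseline(f + 13, window_s = 1, percentile = 10)
  expect_equal(base2, base + 13)
  # top side tracks the upper envelope (negative-going convention)
  fneg <- 100 - 30 * tonic_trace(4000, st)
  btop <- moving_percentile_baseline(fneg, 1, 10, side = "top")
  expect_lt(max(abs(btop - 100)), 1e-6)
  expect_error(moving_percentile_baseline(rep(1, 100), window_s = 1,
                                          frame_rate_hz = 400), "longer")
})

test_that("strided percentile evaluation matches the exact computation", {
  set.seed(6)
  f <- cumsum(rnorm(2000)) + 100
  exact <- moving_percentile_baseline(f, 0.5, 10, step = 1)
  fast <- moving_percentile_baseline(f, 0.5, 10)
  expect_lt(max(abs(exact - fast)) / diff(range(f)), 0.03)
})

test_that("F-V curves summarize voltage-clamp steps with the right sign", {
  volts <- seq(-110, 50, by = 20)
  mk <- function(slope_sign) lapply(volts, function(v)
    list(voltage = v, dff = rep(slope_sign * 0.006 * (v + 70), 50) +
           rnorm(50, sd = 1e-4)))
  set.seed(1)
  up <- build_fv_curve(mk(+1))
  dn <- build_fv_curve(mk(-1))
  expect_length(up$voltages, 9)            # -110:50 in 20 mV steps
  expect_identical(up$slope_sign, "positive")
  expect_identical(dn$slope_sign, "negative")
  # duplicate voltages are averaged
  dup <- build_fv_curve(list(list(voltage = 0, dff = rep(1, 20)),
                             list(voltage = 0, dff = rep(3, 20)),
                             list(voltage = 20, dff = rep(4, 20))))
  expect_equal(dup$dff_means[dup$voltages == 0], 2)
  expect_error(build_fv_curve(list(list(voltage = 0, dff = 1))), "2")
})
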