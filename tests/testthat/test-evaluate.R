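# independent oracle: IoU via dense binary label vectors
iou_oracle <- function(truth, inferred, n_frames) {
  a <- logical(n_frames); a[truth] <- TRUE
  b <- logical(n_frames); b[inferred] <- TRUE
  if (!any(a | b)) return(1)
  sum(a & b) / sum(a | b)
}

test_that("counting examples and edge cases", {
  ev <- spike_iou(c(10, 20), c(10, 30), n_frames = 100)
  expect_equal(ev$iou, 1 / 3)
  expect_equal(ev$error_rate, 2 / 3)
  same <- spike_iou(c(5, 6, 7), c(5, 6, 7), n_frames = 10)
  expect_equal(same$iou, 1)
  expect_equal(same$error_rate, 0)
  expect_equal(spike_iou(integer(0), integer(0), n_frames = 10)$iou, 1)
  expect_equal(spike_iou(c(1, 2), integer(0), n_frames = 10)$iou, 0)
})

test_that("spike_iou matches the brute-force label computation", {
  set.seed(11)
  for (i in 1:1000) {
    n <- sample(20:60, 1)
    truth <- sort(sample(n, sample(0:8, 1)))
    inferred <- sort(sample(n, sample(0:8, 1)))
    ev <- spike_iou(truth, inferred, n_frames = n)
    expect_identical(ev$iou, iou_oracle(truth, inferred, n))
    expect_identical(ev$error_rate, 1 - ev$iou)
    if (ev$n_true + ev$n_inferred > 0)
      expect_identical(ev$iou,
                       ev$n_intersect / (ev$n_true + ev$n_inferred -
                                           ev$n_intersect))
  }
})

test_that("IoU is symmetric and bounded", {
  set.seed(12)
  for (i in 1:50) {
    a <- sort(sample(100, 6)); b <- sort(sample(100, 6))
    ev1 <- spike_iou(a, b, 100); ev2 <- spike_iou(b, a, 100)
    expect_identical(ev1$iou, ev2$iou)
    expect_gte(ev1$iou, 0); expect_lte(ev1$iou, 1)
    if (ev1$iou == 1) expect_identical(a, b)
  }
})

test_that("tolerance matching is greedy, one-to-one, and nearest-first", {
  # inferred 11 matches truth 10 (distance 1); inferred 13 then takes 15
  ev <- spike_iou(c(10, 15), c(11, 13), n_frames = 30, tolerance_frames = 2)
  expect_equal(ev$n_intersect, 2)
  expect_equal(ev$iou, 1)
  # one truth cannot absorb two inferred events
  ev2 <- spike_iou(10, c(9, 11), n_frames = 30, tolerance_frames = 2)
  expect_equal(ev2$n_intersect, 1)
  expect_equal(ev2$n_inferred, 2)
  # beyond tolerance: no match
  ev3 <- spike_iou(10, 14, n_frames = 30, tolerance_frames = 2)
  expect_equal(ev3$n_intersect, 0)
})

sweep_from_grid <- function(grid)
  structure(list(grid = grid, config = default_run_config(), base_seed = 1),
            class = "gevi_sweep")

fake_grid <- function(err_fun, densities = c(1, 2, 4, 8, 16), reps = 3,
                      sens = 1) {
  do.call(rbind, lapply(c("positive", "negative"), function(p)
    do.call(rbind, lapply(densities, function(d)
      data.frame(polarity = p, sensitivity = sens, density = d,
                 rep = seq_len(reps), seed = seq_len(reps),
                 error_rate = err_fun(p, d), iou = 1 - err_fun(p, d),
                 n_true = 10L, n_inferred = 10L,
                 mean_event_z = 8)))))
}

test_that("identical polarity curves give ratio 1 for both summaries", {
  sw <- sweep_from_grid(fake_grid(function(p, d) pmin(1, d / 20)))
  expect_equal(as.numeric(matched_density_ratio(sw)), 1, tolerance = 1e-9)
  expect_equal(as.numeric(fidelity_ratio(sw)), 1)
})

test_that("a known density shift is recovered by interpolation", {
  # positive tolerates exactly 3x the density of negative at every error
  err <- function(p, d) {
    d_eff <- if (p == "positive") d / 3 else d
    pmin(1, pmax(0, 0.25 * log2(d_eff) + 0.2))
  }
  sw <- sweep_from_grid(fake_grid(err))
  r_log <- as.numeric(matched_density_ratio(sw, error_target = 0.5))
  r_lin <- as.numeric(matched_density_ratio(sw, error_target = 0.5,
                                            interp = "linear"))
  expect_equal(r_log, 3, tolerance = 0.02)
  # the two interpolation schemes agree on smooth curves
  expect_lt(abs(r_lin / r_log - 1), 0.10)
})

test_that("unreachable error targets are censored or rejected", {
  err <- function(p, d)
    if (p == "positive") 0.05 else pmin(1, 0.3 * log2(d) + 0.1)
  sw <- sweep_from_grid(fake_grid(err))
  r <- matched_density_ratio(sw, error_target = 0.6)
  expect_true(attr(r, "censored"))
  expect_equal(attr(r, "density_positive"), 16)
  expect_error(matched_density_ratio(sw, error_target = 2), "range")
})

test_that("fidelity ratio reads the requested cell and flags zero division", {
  err <- function(p, d) if (p == "positive") 0.2 else 0.8
  sw <- sweep_from_grid(fake_grid(err))
  expect_equal(as.numeric(fidelity_ratio(sw)), 0.8 / 0.2)
  z <- sweep_from_grid(fake_grid(function(p, d)
    if (p == "positive") 0.2 else 1))
  fz <- fidelity_ratio(z)
  expect_true(is.infinite(fz))
  expect_true(attr(fz, "zero_denominator"))
})

test_that("small sweeps run end-to-end, reproducibly, and error-free when noiseless", {
  # refractory above the level-3:6 band's ~10-frame resolution limit so that
  # every ground-truth spike is individually resolvable
  cfg <- tiny_config(noise_coeff = 0, n_background_per_neuron = 0,
                     refractory_frames = 12)
  sw <- run_polarity_sweep(densities = 1, sensitivities = 0.5,
                           polarities = c("positive", "negative"),
                           n_reps = 2, config = cfg, base_seed = 5)
  expect_equal(nrow(sw$grid), 4)
  expect_true(all(sw$grid$error_rate == 0))
  sw2 <- run_polarity_sweep(densities = 1, sensitivities = 0.5,
                            polarities = c("positive", "negative"),
                            n_reps = 2, config = cfg, base_seed = 5)
  expect_identical(sw$grid, sw2$grid)
  sm <- summary(sw)
  expect_equal(nrow(sm), 2)
  expect_true(all(sm$mean_error == 0))
})
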