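make_cell <- function(frames, n_frames, dim, ctr, seed = 1, sub_sd = 0) {
  st <- spike_train(frames, n_frames)
  list(voltage = simulate_voltage_trace(st, subthreshold_sd = sub_sd,
                                        seed = seed),
       footprint = simulate_footprint(dim, ctr, 2, seed = seed))
}

test_that("a noiseless movie is exactly footprint x fluorescence", {
  cell <- make_cell(c(50, 120), 300, c(16, 16), c(8, 8))
  ind <- indicator_params("positive", 100, 0.5)
  rec <- assemble_recording(list(cell), indicator = ind,
                            bleach_tau_frames = Inf, noise_coeff = 0,
                            offset = 0, seed = 1)
  f <- voltage_to_fluorescence(cell$voltage, ind)$f
  expected <- outer(f, as.vector(cell$footprint$weights))
  expect_equal(matrix(rec$movie, nrow = 300), expected, tolerance = 1e-12)
})

test_that("total intensity is conserved without noise", {
  cells <- list(make_cell(c(50, 120), 300, c(16, 16), c(8, 8), seed = 1),
                make_cell(c(70, 200), 300, c(16, 16), c(5, 11), seed = 2))
  ind <- indicator_params("negative", 80, 0.3)
  rec <- assemble_recording(cells, indicator = ind, bleach_tau_frames = 5000,
                            noise_coeff = 0, offset = 3, seed = 1)
  per_frame <- apply(rec$movie, 1, sum)
  traces <- sapply(cells, function(cell)
    voltage_to_fluorescence(cell$voltage, ind)$f)
  expected <- rowSums(traces) * rec$bleach_curve + 3 * 16 * 16
  expect_equal(per_frame, expected, tolerance = 1e-9)
})

test_that("bleaching decays the frame mean as exp(-t/tau)", {
  cell <- make_cell(integer(0), 2000, c(16, 16), c(8, 8))
  rec <- assemble_recording(list(cell), bleach_tau_frames = 800,
                            noise_coeff = 0, offset = 0, seed = 1)
  fm <- apply(rec$movie, 1, mean)
  fit <- fit_bleach(fm)
  expect_lt(abs(fit$tau / 800 - 1), 0.01)
  expect_true(all(diff(rec$bleach_curve) <= 0))
  expect_equal(rec$bleach_curve[1], 1)
})

test_that("proportional pixel noise has SD = coeff x signal", {
  # constant signal: one flat 'neuron' plus offset, long integration
  cell <- make_cell(integer(0), 10000, c(4, 4), c(2, 2))
  rec <- assemble_recording(list(cell), indicator =
                              indicator_params("positive", 100, 0.2),
                            bleach_tau_frames = Inf, noise_coeff = 0.05,
                            offset = 20, seed = 3, clip = FALSE)
  M <- matrix(rec$movie, nrow = 10000)
  mean_px <- colMeans(M)
  sd_px <- apply(M, 2, sd)
  expect_true(all(abs(sd_px / (0.05 * mean_px) - 1) < 0.05))
})

test_that("recordings are bit-identical under the same seed and config", {
  cfg <- tiny_config()
  r1 <- simulate_recording(cfg, seed = 11, n_neurons = 2)
  r2 <- simulate_recording(cfg, seed = 11, n_neurons = 2)
  expect_identical(r1$movie, r2$movie)
  r3 <- simulate_recording(cfg, seed = 12, n_neurons = 2)
  expect_false(identical(r1$movie, r3$movie))
  expect_length(r1$background, 2 * cfg$n_background_per_neuron)
  expect_true(min(r1$movie) >= 0)
})

test_that("mismatched traces or footprints are rejected", {
  a <- make_cell(10, 100, c(8, 8), c(4, 4))
  b <- make_cell(10, 200, c(8, 8), c(4, 4))
  expect_error(assemble_recording(list(a, b)), "same length")
  d <- make_cell(10, 100, c(10, 10), c(4, 4))
  expect_error(assemble_recording(list(a, d)), "frame shape")
})
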