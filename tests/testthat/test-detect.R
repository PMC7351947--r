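test_that("degenerate traces yield no events; short traces error", {
  expect_length(wavelet_detect(rep(1, 200))$spike_frames, 0)
  expect_error(wavelet_detect(rnorm(50)), "64")
})

test_that("white noise at a matched null threshold stays at the null rate", {
  # threshold at the 99.9th percentile of a noise-only null: expect about
  # 0.1% of candidate samples, i.e. a handful of events in 4000 frames
  set.seed(10)
  null_max <- replicate(50, {
    y <- wavelet_detect(rnorm(2000), threshold_k = Inf)$reconstruction
    quantile(y^2, 0.999)
  })
  thr <- median(null_max)
  fp <- vapply(1:20, function(s) {
    set.seed(100 + s)
    length(wavelet_detect(rnorm(4000), threshold = thr)$spike_frames)
  }, 0L)
  # 0.1% of 4000 samples, merged into events: a loose upper bound of ~8
  expect_lt(mean(fp), 8)
})

test_that("tonic spiking at SNR 10 is recovered fully with no extras", {
  truth <- tonic_train(4000, 80, jitter = 10, seed = 3)
  x <- tonic_trace(4000, truth, noise_sd = 0.1, seed = 3)
  det <- wavelet_detect(x)
  ev <- spike_iou(truth, det$spike_frames, n_frames = 4000,
                  tolerance_frames = 2)
  expect_equal(ev$n_intersect, length(truth))   # 100% recall within 2 frames
  expect_equal(ev$n_inferred, length(truth))    # no false positives
})

test_that("detection is invariant to positive rescaling of the trace", {
  truth <- tonic_train(2000, 100, jitter = 5, seed = 2)
  x <- tonic_trace(2000, truth, noise_sd = 0.08, seed = 2)
  d1 <- wavelet_detect(x)
  d2 <- wavelet_detect(1000 * x)
  expect_identical(d1$spike_frames, d2$spike_frames)
  expect_equal(d1$event_z, d2$event_z)
})

test_that("one threshold detects matched-SNR events of either polarity", {
  truth <- tonic_train(4000, 120, jitter = 8, seed = 5)
  up <- tonic_trace(4000, truth, noise_sd = 0.08, seed = 5)
  down <- -tonic_trace(4000, truth, noise_sd = 0.08, seed = 5)
  dup <- wavelet_detect(up, sign = "both")
  ddn <- wavelet_detect(down, sign = "both")
  expect_identical(dup$spike_frames,
                   wavelet_detect(up)$spike_frames)
  iou_up <- spike_iou(truth, dup$spike_frames, 4000, tolerance_frames = 2)$iou
  iou_dn <- spike_iou(truth, ddn$spike_frames, 4000, tolerance_frames = 2)$iou
  expect_equal(iou_up, iou_dn)
})

test_that("noiseless extraction returns the true trace up to scale", {
  cfg <- tiny_config(noise_coeff = 0, n_background_per_neuron = 0,
                     subthreshold_sd = 0.05)
  rec <- simulate_recording(cfg, seed = 21)
  tr <- extract_trace(rec)
  f_true <- rec$neurons[[1]]$fluor$f * rec$bleach_curve
  expect_gt(cor(tr$f, f_true), 1 - 1e-9)
})

test_that("weight refinement beats an imperfect seed ROI under background", {
  # the seed is a sloppy manual ROI (displaced, 1.6x too large); refinement
  # should recover the cell's pixels. Compared on trend-removed traces so the
  # shared bleach trend does not dominate the correlation.
  hp <- function(x) gevisim:::highpass_ma(x, 400)
  cfg <- tiny_config(subthreshold_sd = 0.05)
  cors <- vapply(1:8, function(s) {
    rec <- simulate_recording(cfg, seed = 30 + s)
    fp <- rec$neurons[[1]]$footprint
    seed_fp <- simulate_footprint(
      dim(fp$weights), pmin(pmax(fp$centroid + c(2, -2), 4), 21),
      radius_px = 1.6 * 2, seed = s)
    f_true <- hp(rec$neurons[[1]]$fluor$f * rec$bleach_curve)
    roi <- extract_trace(rec, seed_footprint = seed_fp, n_iter = 0,
                         background_subtract = FALSE)
    ref <- extract_trace(rec, seed_footprint = seed_fp)
    c(roi = cor(hp(roi$f), f_true), refined = cor(hp(ref$f), f_true))
  }, c(roi = 0, refined = 0))
  expect_gte(mean(cors["refined", ]), mean(cors["roi", ]))
})

test_that("negative-going movies detect like positive-going ones", {
  cfgp <- tiny_config(noise_coeff = 0, n_background_per_neuron = 0,
                      polarity = "positive")
  cfgn <- tiny_config(noise_coeff = 0, n_background_per_neuron = 0,
                      polarity = "negative")
  recp <- simulate_recording(cfgp, seed = 41)
  recn <- simulate_recording(cfgn, seed = 41)
  detp <- detect_from_movie(recp)
  detn <- detect_from_movie(recn)
  expect_identical(detp$spike_frames, detn$spike_frames)
  expect_identical(detp$spike_frames,
                   recp$neurons[[1]]$voltage$spikes$frames)
})

test_that("movie detection is deterministic and exact when noiseless", {
  cfg <- tiny_config(noise_coeff = 0, n_background_per_neuron = 0)
  rec <- simulate_recording(cfg, seed = 55)
  d1 <- detect_from_movie(rec)
  d2 <- detect_from_movie(rec)
  expect_identical(d1$spike_frames, d2$spike_frames)
  expect_identical(d1$spike_frames, rec$neurons[[1]]$voltage$spikes$frames)
})

test_that("empty seed overlap is rejected", {
  cfg <- tiny_config(noise_coeff = 0)
  rec <- simulate_recording(cfg, seed = 1)
  bad <- rec$neurons[[1]]$footprint
  bad$weights <- bad$weights * 0
  expect_error(extract_trace(rec, seed_footprint = bad), "overlap")
})
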