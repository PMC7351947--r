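#' Assemble a simulated fluorescence movie from neurons and background
#'
#' Implements the movie-synthesis recipe: each neuron's normalized voltage
#' trace is converted to an indicator fluorescence trace
#' ([voltage_to_fluorescence]), multiplied by a shared single-exponential
#' bleaching curve `exp(-t / bleach_tau_frames)` (a parametric stand-in for an
#' empirically measured curve; `Inf` disables bleaching), outer-multiplied
#' with its unit-sum spatial footprint, and summed across neurons on top of a
#' flat background offset. Per-pixel Gaussian noise is then added frame-wise:
#' with `noise_model = "proportional"` the noise SD at a pixel is
#' `noise_coeff` times that pixel's signal (the dominant regime of one-photon
#' voltage imaging, and the mechanism that differentiates indicator
#' polarities); with `"additive"` it is the constant `noise_sd` regardless of
#' signal (a control that removes the polarity asymmetry). Negative pixels are
#' clipped to zero.
#'
#' @param neurons list of `list(voltage =, footprint =, params =)` for
#'   in-focus neurons; `params` may be omitted when `indicator` is given.
#' @param background same structure for out-of-focus neurons (may be empty).
#' @param indicator default [indicator_params] applied to any neuron without
#'   its own `params`.
#' @param bleach_tau_frames bleaching time constant in frames (> 0 or `Inf`).
#' @param noise_model `"proportional"` or `"additive"`.
#' @param noise_coeff unitless noise proportionality constant (SD per unit
#'   signal) for the proportional model.
#' @param noise_sd absolute noise SD in counts for the additive model.
#' @param offset flat background intensity added to every pixel (counts);
#'   models unlabeled-tissue fluorescence and is subject to the same noise.
#' @param seed integer seed for the pixel noise.
#' @param clip clip negative pixels to zero (default TRUE).
#' @return an object of class `sim_recording`: `movie` (T x H x W array),
#'   `neurons`, `background` (each with their traces and footprints),
#'   `bleach_curve`, `frame_rate_hz`, noise settings, `offset`, `seed`.
#' @export
assemble_recording <- function(neurons, background = list(),
                               indicator = indicator_params("positive"),
                               bleach_tau_frames = Inf,
                               noise_model = c("proportional", "additive"),
                               noise_coeff = 0.1, noise_sd = 1,
                               offset = 10, seed = 1, clip = TRUE) {
  noise_model <- match.arg(noise_model)
  assert_that(length(neurons) >= 1, "need at least one in-focus neuron")
  assert_that(bleach_tau_frames > 0, "bleach_tau_frames must be > 0 (or Inf)")
  all_cells <- c(neurons, background)
  dm <- dim(all_cells[[1]]$footprint$weights)
  n_frames <- all_cells[[1]]$voltage$n_frames
  for (cell in all_cells) {
    assert_that(identical(dim(cell$footprint$weights), dm),
                "all footprints must share the frame shape")
    assert_that(cell$voltage$n_frames == n_frames,
                "all voltage traces must have the same length")
  }
  tvec <- seq_len(n_frames) - 1
  bleach <- if (is.finite(bleach_tau_frames)) exp(-tvec / bleach_tau_frames)
            else rep(1, n_frames)

  cells <- lapply(all_cells, function(cell) {
    p <- cell$params %||% indicator
    cell$params <- p
    cell$fluor <- voltage_to_fluorescence(cell$voltage, p)
    cell
  })
  # traces (cells x T, bleached) and footprints (pixels x cells)
  tr <- do.call(rbind, lapply(cells, function(cell) cell$fluor$f * bleach))
  fpm <- do.call(cbind, lapply(cells, function(cell) as.vector(cell$footprint$weights)))
  signal <- fpm %*% tr                      # pixels x T
  signal <- signal + offset
  if (noise_model == "proportional" && noise_coeff > 0) {
    noise <- with_seed(seed,
      matrix(rnorm(length(signal)), nrow(signal)) * (noise_coeff * signal))
    signal <- signal + noise
  } else if (noise_model == "additive" && noise_sd > 0) {
    signal <- signal + with_seed(seed,
      matrix(rnorm(length(signal), sd = noise_sd), nrow(signal)))
  }
  if (clip) signal[signal < 0] <- 0
  movie <- array(t(signal), dim = c(n_frames, dm[1], dm[2]))

  n_in <- length(neurons)
  structure(list(movie = movie,
                 neurons = cells[seq_len(n_in)],
                 background = if (length(cells) > n_in) cells[-seq_len(n_in)] else list(),
                 bleach_curve = bleach,
                 bleach_tau_frames = bleach_tau_frames,
                 frame_rate_hz = all_cells[[1]]$voltage$spikes$frame_rate_hz,
                 noise_model = noise_model, noise_coeff = noise_coeff,
                 noise_sd = noise_sd, offset = offset, seed = seed),
            class = "sim_recording")
}

#' @export
print.sim_recording <- function(x, ...) {
  d <- dim(x$movie)
  cat(sprintf(paste0("<sim_recording> %d frames of %dx%d px at %g Hz\n",
                     "  %d in-focus neuron(s), %d background neuron(s)\n",
                     "  bleach tau %s frames, %s noise (coeff %.3g), offset %g\n"),
              d[1], d[2], d[3], x$frame_rate_hz, length(x$neurons),
              length(x$background),
              if (is.finite(x$bleach_tau_frames))
                format(x$bleach_tau_frames) else "Inf",
              x$noise_model,
              if (x$noise_model == "proportional") x$noise_coeff else x$noise_sd,
              x$offset))
  invisible(x)
}

#' Simulate a complete ground-truthed recording from a run configuration
#'
#' Convenience wrapper tying the generators together: draws spike trains,
#' voltage traces and footprints for `n_neurons` in-focus neurons placed
#' uniformly at random in the field of view, attaches
#' `n_background_per_neuron` out-of-focus neurons to each, and assembles the
#' movie. All randomness is derived from `seed` via [seed_stream()], so the
#' recording is bit-reproducible from `(config, seed)`.
#'
#' @param config a run configuration, see [default_run_config()]. Any field
#'   can be overridden via `...`.
#' @param seed integer base seed.
#' @param ... named overrides merged into `config`.
#' @return a `sim_recording`; ground truth is available as
#'   `rec$neurons[[i]]$voltage$spikes`.
#' @examples
#' rec <- simulate_recording(default_run_config(frames = 512, fov = c(16, 16),
#'                                              mean_spikes = 3), seed = 1)
#' rec
#' @export
simulate_recording <- function(config = default_run_config(), seed = 1, ...) {
  config <- merge_config(config, list(...))
  ind <- indicator_params(config$polarity, config$F_max, config$sensitivity)
  H <- config$fov[1]; W <- config$fov[2]
  margin <- min(3 * config$footprint_radius_px, (min(H, W) - 1) / 2)

  neurons <- vector("list", config$n_neurons)
  background <- list()
  centroids <- matrix(numeric(0), ncol = 2)
  min_sep <- 2 * config$footprint_radius_px   # somata are volume-exclusive
  for (i in seq_len(config$n_neurons)) {
    si <- seed_stream(seed, 10, i)
    st <- simulate_spike_train(config$frames, config$frame_rate_hz,
                               config$mean_spikes, config$refractory_frames,
                               seed = seed_stream(si, 1))
    vt <- simulate_voltage_trace(st, config$ap_rise_frames,
                                 config$ap_decay_tau_frames,
                                 config$subthreshold_sd,
                                 config$subthreshold_tau_frames,
                                 seed = seed_stream(si, 2))
    ctr <- with_seed(seed_stream(si, 3), {
      cand <- c(runif(1, 1 + margin, H - margin),
                runif(1, 1 + margin, W - margin))
      for (try in seq_len(100)) {
        if (!nrow(centroids) ||
            min(sqrt(rowSums(sweep(centroids, 2, cand)^2))) >= min_sep) break
        cand <- c(runif(1, 1 + margin, H - margin),
                  runif(1, 1 + margin, W - margin))
      }
      cand
    })
    centroids <- rbind(centroids, ctr)
    fp <- simulate_footprint(c(H, W), ctr, config$footprint_radius_px,
                             seed = seed_stream(si, 4))
    neurons[[i]] <- list(voltage = vt, footprint = fp)
    if (config$n_background_per_neuron > 0) {
      bg <- simulate_background_neurons(
        fp, st, config$n_background_per_neuron,
        blur_px = config$background_blur_px,
        displace_px = config$background_displace_px,
        seed = seed_stream(si, 5),
        rise_frames = config$ap_rise_frames,
        decay_tau_frames = config$ap_decay_tau_frames,
        subthreshold_sd = config$subthreshold_sd,
        subthreshold_tau_frames = config$subthreshold_tau_frames)
      background <- c(background, bg)
    }
  }
  assemble_recording(neurons, background, indicator = ind,
                     bleach_tau_frames = config$bleach_tau_frames,
                     noise_model = config$noise_model,
                     noise_coeff = config$noise_coeff,
                     noise_sd = config$noise_sd,
                     offset = config$offset,
                     seed = seed_stream(seed, 20))
}
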