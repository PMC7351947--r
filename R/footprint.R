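#' Simulate a soma-like spatial footprint
#'
#' A compact, unit-sum, anisotropic Gaussian blob standing in for a labeled
#' soma. The seed draws a mild random elongation (axis ratio up to ~1.3) and
#' orientation so that no two cells are pixel-identical; with the same seed and
#' arguments the map is reproduced exactly. Weights are truncated at
#' `4 * radius_px` from the centroid and normalized to sum to one, so footprint
#' brightness is carried entirely by the indicator/brightness model.
#'
#' @param dim integer `(H, W)` frame shape in pixels.
#' @param centroid numeric `(row, col)` in pixels (1-based), inside the frame.
#' @param radius_px Gaussian radius (sigma) of the soma in pixels.
#' @param seed integer seed for the shape jitter.
#' @param in_focus logical flag carried on the object.
#' @return an object of class `spatial_footprint` with fields `weights`
#'   (H x W matrix), `centroid`, `in_focus`, and the generating shape
#'   parameters (`sigma_major`, `sigma_minor`, `theta`).
#' @examples
#' fp <- simulate_footprint(c(64, 64), centroid = c(32, 32), radius_px = 3)
#' sum(fp$weights)
#' @export
simulate_footprint <- function(dim, centroid, radius_px = 2, seed = 1,
                               in_focus = TRUE) {
  assert_that(length(dim) == 2 && all(dim >= 1), "dim must be (H, W)")
  assert_that(radius_px > 0, "radius_px must be > 0")
  assert_that(length(centroid) == 2 &&
                centroid[1] >= 1 && centroid[1] <= dim[1] &&
                centroid[2] >= 1 && centroid[2] <= dim[2],
              "centroid must lie inside the frame")
  shp <- with_seed(seed, c(ratio = runif(1, 1, 1.3), theta = runif(1, 0, pi)))
  # equal-area elongation: sigma_major * sigma_minor == radius_px^2
  s_maj <- radius_px * sqrt(shp[["ratio"]])
  s_min <- radius_px / sqrt(shp[["ratio"]])
  footprint_from_gaussian(dim, centroid, s_maj, s_min, shp[["theta"]],
                          in_focus = in_focus)
}

# Evaluate a unit-sum truncated anisotropic Gaussian on the pixel grid.
footprint_from_gaussian <- function(dim, centroid, sigma_major, sigma_minor,
                                    theta, in_focus = TRUE) {
  H <- dim[1]; W <- dim[2]
  dr <- matrix(seq_len(H) - centroid[1], H, W)
  dc <- matrix(seq_len(W) - centroid[2], H, W, byrow = TRUE)
  u <- dr * cos(theta) + dc * sin(theta)
  v <- -dr * sin(theta) + dc * cos(theta)
  q <- (u / sigma_major)^2 + (v / sigma_minor)^2
  wts <- exp(-q / 2)
  wts[q > 32] <- 0                       # truncate at 4 sigma (equal-area)
  s <- sum(wts)
  assert_that(s > 0, "footprint has no support inside the frame")
  structure(list(weights = wts / s, centroid = as.numeric(centroid),
                 in_focus = isTRUE(in_focus),
                 sigma_major = sigma_major, sigma_minor = sigma_minor,
                 theta = theta),
            class = "spatial_footprint")
}

#' Weight centroid and second moment of a footprint
#'
#' @param fp a `spatial_footprint`.
#' @return list with `centroid` (weight-averaged row/col) and `second_moment`
#'   (trace of the spatial covariance of the weights, in px^2).
#' @export
footprint_moments <- function(fp) {
  stopifnot(inherits(fp, "spatial_footprint"))
  w <- fp$weights
  H <- nrow(w); W <- ncol(w)
  rows <- matrix(seq_len(H), H, W)
  cols <- matrix(seq_len(W), H, W, byrow = TRUE)
  s <- sum(w)
  mr <- sum(rows * w) / s
  mc <- sum(cols * w) / s
  m2 <- sum(((rows - mr)^2 + (cols - mc)^2) * w) / s
  list(centroid = c(mr, mc), second_moment = m2)
}

#' @export
print.spatial_footprint <- function(x, ...) {
  cat(sprintf("<spatial_footprint> %dx%d px, centroid (%.1f, %.1f), %s\n",
              nrow(x$weights), ncol(x$weights), x$centroid[1], x$centroid[2],
              if (x$in_focus) "in focus" else "out of focus"))
  invisible(x)
}

#' Simulate out-of-focus background neurons for one target neuron
#'
#' Each background neuron gets (i) a blurred copy of the target's footprint
#' placed at a randomly displaced centroid — realized by inflating the
#' target's Gaussian profile by `blur_px` in quadrature, which for these
#' Gaussian footprints equals convolution with a Gaussian blur kernel — and
#' (ii) a voltage trace built from the target's spike train circularly shifted
#' by an independent random offset ("temporally shuffled": same spike count
#' and ISI structure, independent phase).
#'
#' @param target a `spatial_footprint` of the in-focus target neuron.
#' @param target_spikes the target's [spike_train].
#' @param n_background number of background neurons (default 5).
#' @param blur_px Gaussian blur sigma in pixels (> 0).
#' @param displace_px maximum centroid displacement (uniform in a disk).
#' @param seed integer seed.
#' @param ... further arguments passed to [simulate_voltage_trace()]
#'   (waveform and subthreshold parameters).
#' @return list of `n_background` elements, each
#'   `list(voltage = voltage_trace, footprint = spatial_footprint)` with
#'   `in_focus = FALSE`.
#' @export
simulate_background_neurons <- function(target, target_spikes,
                                        n_background = 5, blur_px = 8,
                                        displace_px = 12, seed = 1, ...) {
  stopifnot(inherits(target, "spatial_footprint"),
            inherits(target_spikes, "spike_train"))
  assert_that(n_background >= 0, "n_background must be >= 0")
  assert_that(blur_px > 0, "blur_px must be > 0")
  if (n_background == 0) return(list())
  dm <- dim(target$weights)
  lapply(seq_len(n_background), function(i) {
    si <- seed_stream(seed, i)
    pos <- with_seed(si, {
      ang <- runif(1, 0, 2 * pi)
      rad <- displace_px * sqrt(runif(1))
      off <- round(runif(1, 1, target_spikes$n_frames - 1))
      c(ang, rad, off)
    })
    ctr <- pmin(pmax(target$centroid +
                       pos[2] * c(cos(pos[1]), sin(pos[1])), 1), dm)
    fp <- footprint_from_gaussian(
      dm, ctr,
      sqrt(target$sigma_major^2 + blur_px^2),
      sqrt(target$sigma_minor^2 + blur_px^2),
      target$theta, in_focus = FALSE)
    spikes <- shift_spike_train(target_spikes, pos[3])
    vt <- simulate_voltage_trace(spikes, seed = seed_stream(si, 1), ...)
    list(voltage = vt, footprint = fp)
  })
}
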