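#' Spike train object
#'
#' A ground-truth spike train: strictly increasing 1-based frame indices within
#' a recording of `n_frames` frames sampled at `frame_rate_hz`.
#'
#' @param frames integer vector of spike frames (1-based), strictly increasing.
#' @param n_frames total number of frames in the recording.
#' @param frame_rate_hz sampling rate in frames per second.
#' @return an object of class `spike_train`.
#' @export
spike_train <- function(frames, n_frames, frame_rate_hz = 400) {
  frames <- as.integer(round(frames))
  assert_that(n_frames >= 1, "n_frames must be a positive count")
  assert_that(frame_rate_hz > 0, "frame_rate_hz must be > 0")
  if (length(frames)) {
    assert_that(all(diff(frames) > 0), "spike frames must be strictly increasing")
    assert_that(frames[1] >= 1 && frames[length(frames)] <= n_frames,
                "spike frames must lie in [1, n_frames]")
  }
  structure(list(frames = frames, n_frames = as.integer(n_frames),
                 frame_rate_hz = frame_rate_hz),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d spikes over %d frames (%.4g s at %g Hz)\n",
              length(x$frames), x$n_frames, x$n_frames / x$frame_rate_hz,
              x$frame_rate_hz))
  invisible(x)
}

#' @export
length.spike_train <- function(x) length(x$frames)

#' Simulate a Poisson spike train with a refractory period
#'
#' Spike times follow a homogeneous Poisson process thinned by an absolute
#' refractory period. The underlying rate is dead-time corrected
#' (`lambda / (1 - lambda * refractory)`) so that the *thinned* train still has
#' the requested expected count: without the correction a mean-100-spike,
#' 40,000-frame recording would come out ~1% short.
#'
#' @param n_frames recording length in frames (must exceed the refractory
#'   period).
#' @param frame_rate_hz frames per second.
#' @param mean_spikes expected number of spikes in the whole recording.
#' @param refractory_frames minimum gap between consecutive spikes, in frames
#'   (>= 1; default 4, i.e. 10 ms at 400 Hz).
#' @param seed integer seed; the result is a pure function of the arguments.
#' @return a [spike_train].
#' @examples
#' st <- simulate_spike_train(4000, 400, mean_spikes = 10, seed = 1)
#' length(st$frames)
#' @export
simulate_spike_train <- function(n_frames, frame_rate_hz = 400,
                                 mean_spikes = 100, refractory_frames = 4,
                                 seed = 1) {
  assert_that(length(n_frames) == 1 && n_frames > 0, "n_frames must be positive")
  assert_that(mean_spikes >= 0, "mean_spikes must be >= 0")
  assert_that(refractory_frames >= 1, "refractory_frames must be >= 1")
  assert_that(n_frames > refractory_frames,
              "n_frames must exceed refractory_frames")
  if (mean_spikes == 0)
    return(spike_train(integer(0), n_frames, frame_rate_hz))

  lambda <- mean_spikes / n_frames            # spikes per frame
  dead <- lambda * refractory_frames
  assert_that(dead < 1, "mean_spikes too high for this refractory period")
  lambda_eff <- lambda / (1 - dead)           # dead-time corrected rate

  with_seed(seed, {
    # draw exponential inter-arrival gaps plus the dead time until past the end
    n_guess <- max(16L, ceiling(1.5 * mean_spikes + 6 * sqrt(mean_spikes + 1)))
    times <- numeric(0)
    t_cur <- 0
    repeat {
      gaps <- stats::rexp(n_guess, rate = lambda_eff) + refractory_frames
      times <- c(times, t_cur + cumsum(gaps))
      t_cur <- times[length(times)]
      if (t_cur > n_frames) break
    }
    frames <- unique(pmin(ceiling(times[times <= n_frames]), n_frames))
    # ceiling() can collapse events in the same frame; enforce the gap exactly
    keep <- !logical(length(frames))
    last <- -Inf
    for (i in seq_along(frames)) {
      if (frames[i] - last >= refractory_frames) last <- frames[i]
      else keep[i] <- FALSE
    }
    spike_train(frames[keep], n_frames, frame_rate_hz)
  })
}

#' Circularly shift the spike times of a train
#'
#' Used to "temporally shuffle" background-neuron spiking: the spike count and
#' the inter-spike-interval structure are preserved, only the phase changes.
#'
#' @param spikes a [spike_train].
#' @param offset_frames integer shift applied modulo the recording length.
#' @return a [spike_train] with the same number of spikes.
#' @export
shift_spike_train <- function(spikes, offset_frames) {
  stopifnot(inherits(spikes, "spike_train"))
  f <- sort(((spikes$frames - 1 + round(offset_frames)) %% spikes$n_frames) + 1)
  spike_train(unique(f), spikes$n_frames, spikes$frame_rate_hz)
}
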