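#' Stereotyped action-potential waveform
#'
#' Unit-peak optical action-potential kernel: a linear rise over `rise_frames`
#' frames followed by an exponential decay with time constant
#' `decay_tau_frames`. At the default 400 Hz this is a 2-frame (5 ms) rise and
#' a 3-frame (7.5 ms) decay, comparable to the optical transient of a fast
#' eFRET indicator. The kernel is truncated where it falls below `tol`.
#'
#' @param rise_frames frames from onset to peak (>= 1).
#' @param decay_tau_frames exponential decay constant in frames.
#' @param tol truncation level relative to the unit peak.
#' @return numeric kernel with attribute `peak` giving the peak index.
#' @export
ap_waveform <- function(rise_frames = 2, decay_tau_frames = 3, tol = 1e-3) {
  assert_that(rise_frames >= 1, "rise_frames must be >= 1")
  assert_that(decay_tau_frames > 0, "decay_tau_frames must be > 0")
  rise <- seq_len(rise_frames) / rise_frames
  n_dec <- max(1L, ceiling(-decay_tau_frames * log(tol)))
  dec <- exp(-seq_len(n_dec) / decay_tau_frames)
  w <- c(rise, dec[dec >= tol])
  structure(w, peak = as.integer(rise_frames))
}

#' Simulate a normalized voltage trace from a spike train
#'
#' Builds the per-neuron "voltage trace" that drives the indicator model:
#' rest level 0, mean spike height 1. Each spike contributes a stereotyped
#' unit-peak waveform ([ap_waveform]); waveforms that overlap collapse by
#' pointwise maximum rather than summing, so bursting cannot exceed unit
#' amplitude. Subthreshold activity is an Ornstein-Uhlenbeck (AR(1))
#' fluctuation with standard deviation `subthreshold_sd` and correlation time
#' `subthreshold_tau_frames`.
#'
#' @param spikes a [spike_train] giving ground-truth spike frames; each spike
#'   frame is the frame of its waveform peak.
#' @param rise_frames,decay_tau_frames waveform shape, see [ap_waveform].
#' @param subthreshold_sd standard deviation of the subthreshold fluctuation,
#'   as a fraction of spike height (default 0.1).
#' @param subthreshold_tau_frames correlation time of the fluctuation in
#'   frames (default 50, i.e. 125 ms at 400 Hz).
#' @param seed integer seed for the subthreshold noise.
#' @return an object of class `voltage_trace` with fields `v` (numeric,
#'   length `n_frames`), `spikes`, and `n_frames`.
#' @examples
#' st <- spike_train(c(100L, 200L), 400)
#' vt <- simulate_voltage_trace(st, subthreshold_sd = 0, seed = 1)
#' vt$v[c(100, 200)]
#' @export
simulate_voltage_trace <- function(spikes, rise_frames = 2,
                                   decay_tau_frames = 3,
                                   subthreshold_sd = 0.1,
                                   subthreshold_tau_frames = 50,
                                   seed = 1) {
  stopifnot(inherits(spikes, "spike_train"))
  assert_that(subthreshold_sd >= 0, "subthreshold_sd must be >= 0")
  n <- spikes$n_frames
  w <- ap_waveform(rise_frames, decay_tau_frames)
  pk <- attr(w, "peak")
  v <- numeric(n)
  for (f in spikes$frames) {
    idx <- (f - pk + 1):(f - pk + length(w))
    ok <- idx >= 1 & idx <= n
    v[idx[ok]] <- pmax(v[idx[ok]], w[ok])
  }
  if (subthreshold_sd > 0) {
    phi <- exp(-1 / subthreshold_tau_frames)
    innov_sd <- subthreshold_sd * sqrt(1 - phi^2)
    sub <- with_seed(seed, {
      e <- rnorm(n, sd = innov_sd)
      e[1] <- rnorm(1, sd = subthreshold_sd)
      as.numeric(stats::filter(e, phi, method = "recursive"))
    })
    v <- v + sub
  }
  structure(list(v = v, spikes = spikes, n_frames = n),
            class = "voltage_trace")
}

#' @export
print.voltage_trace <- function(x, ...) {
  cat(sprintf("<voltage_trace> %d frames, %d spikes, range [%.3g, %.3g]\n",
              x$n_frames, length(x$spikes$frames), min(x$v), max(x$v)))
  invisible(x)
}
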