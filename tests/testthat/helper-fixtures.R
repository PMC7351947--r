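# Small fixtures shared across tests; everything generated in code.

# a fast, small recording configuration for pipeline tests
tiny_config <- function(...) {
  default_run_config(frames = 2000, mean_spikes = 6, fov = c(24L, 24L),
                     bleach_tau_frames = 10000, ...)
}

# regular tonic spike train with jitter, for detector tests
tonic_train <- function(n_frames, period, jitter = 0, seed = 1,
                        margin = 100) {
  base <- seq(margin, n_frames - margin, by = period)
  if (jitter > 0) {
    set.seed(seed)
    base <- base + sample(-jitter:jitter, length(base), replace = TRUE)
  }
  sort(unique(round(base)))
}

# synthetic spiking trace: unit AP waveforms + white noise
tonic_trace <- function(n_frames, truth, noise_sd = 0, seed = 1) {
  v <- numeric(n_frames)
  w <- ap_waveform()
  for (f in truth) {
    idx <- (f - 1):(f - 2 + length(w))
    ok <- idx >= 1 & idx <= n_frames
    v[idx[ok]] <- pmax(v[idx[ok]], w[ok])
  }
  if (noise_sd > 0) {
    set.seed(seed)
    v <- v + rnorm(n_frames, sd = noise_sd)
  }
  v
}
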