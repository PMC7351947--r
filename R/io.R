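# Movie, trace and manifest I/O. Movies travel as multi-frame 32-bit float
# TIFF; intensities are stored divided by 2^16 (an exact power-of-two scale,
# so the float mantissa is preserved) because the TIFF writer expects [0, 1].

.movie_tiff_scale <- 65536

#' Read / write a movie as multi-frame 32-bit float TIFF
#'
#' `write_movie()` stores a T x H x W array one frame per TIFF page;
#' `read_movie()` returns it. A write-then-read round trip is exact at
#' float32 precision. Intensities must be non-negative and below 2^16
#' counts.
#'
#' @param movie T x H x W numeric array (or a `sim_recording`).
#' @param path TIFF file path.
#' @return `read_movie()`: a T x H x W array. `write_movie()`: `path`,
#'   invisibly.
#' @export
write_movie <- function(movie, path) {
  if (inherits(movie, "sim_recording")) movie <- movie$movie
  assert_that(length(dim(movie)) == 3, "movie must be a T x H x W array")
  assert_that(max(movie) < .movie_tiff_scale && min(movie) >= 0,
              "movie intensities must be in [0, 65536) counts")
  frames <- lapply(seq_len(dim(movie)[1]),
                   function(t) movie[t, , ] / .movie_tiff_scale)
  tiff::writeTIFF(frames, path, bits.per.sample = 32L, reduce = FALSE,
                  compression = "none")
  invisible(path)
}

#' @rdname write_movie
#' @export
read_movie <- function(path) {
  assert_that(file.exists(path), "no such file: ", path)
  frames <- tryCatch(tiff::readTIFF(path, all = TRUE),
                     error = function(e)
                       stop_invalid("not a readable TIFF movie: ", path,
                                    " (", conditionMessage(e), ")"))
  if (is.matrix(frames)) frames <- list(frames)
  dims <- unique(lapply(frames, dim))
  assert_that(length(dims) == 1 && length(dims[[1]]) == 2,
              "ragged or non-grayscale TIFF pages in ", path)
  H <- dims[[1]][1]; W <- dims[[1]][2]
  movie <- array(0, dim = c(length(frames), H, W))
  for (t in seq_along(frames)) movie[t, , ] <- frames[[t]]
  movie * .movie_tiff_scale
}

#' Read / write traces as CSV
#'
#' Two columns, `frame` and `intensity` (or `dff`).
#'
#' @param trace a [fluorescence_trace], `dff_trace`, or numeric vector.
#' @param path CSV path.
#' @export
write_trace_csv <- function(trace, path) {
  x <- if (inherits(trace, "fluorescence_trace")) trace$f
       else if (inherits(trace, "dff_trace")) trace$dff
       else as.numeric(trace)
  write.csv(data.frame(frame = seq_along(x), intensity = x), path,
            row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @param frame_rate_hz rate attached to the returned trace.
#' @export
read_trace_csv <- function(path, frame_rate_hz = 400) {
  d <- read.csv(path)
  assert_that(all(c("frame", "intensity") %in% names(d)),
              "trace CSV needs 'frame' and 'intensity' columns")
  fluorescence_trace(d$intensity[order(d$frame)], frame_rate_hz)
}

#' Write ground-truth or inferred spikes as CSV
#'
#' Columns `neuron_id`, `spike_frame`; one row per spike.
#'
#' @param spikes a [spike_train], a `detection`, or a list of either
#'   (one entry per neuron).
#' @param path CSV path.
#' @export
write_spikes_csv <- function(spikes, path) {
  if (inherits(spikes, c("spike_train", "detection"))) spikes <- list(spikes)
  rows <- lapply(seq_along(spikes), function(i) {
    s <- spikes[[i]]
    f <- if (inherits(s, "spike_train")) s$frames else s$spike_frames
    if (!length(f)) return(NULL)
    data.frame(neuron_id = i, spike_frame = f)
  })
  d <- do.call(rbind, rows)
  if (is.null(d)) d <- data.frame(neuron_id = integer(0),
                                  spike_frame = integer(0))
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spikes_csv
#' @export
read_spikes_csv <- function(path) {
  d <- read.csv(path)
  assert_that(all(c("neuron_id", "spike_frame") %in% names(d)),
              "spikes CSV needs 'neuron_id' and 'spike_frame' columns")
  lapply(split(d$spike_frame, d$neuron_id), sort)
}

# short stable content hash (FNV-1a over the serialized object)
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Write a reproducibility manifest for a pipeline stage
#'
#' JSON record of the stage name, inputs, seed, config (and its hash),
#' package version and timestamp — enough to regenerate the stage's outputs
#' bit-identically.
#'
#' @param path output JSON path.
#' @param stage stage name (e.g. `"simulate"`).
#' @param config the `run_config` used.
#' @param seed base seed used.
#' @param inputs,outputs character vectors of file paths.
#' @export
write_manifest <- function(path, stage, config, seed, inputs = character(0),
                           outputs = character(0)) {
  manifest <- list(
    stage = stage,
    seed = seed,
    config = unclass(config),
    config_hash = config_hash(unclass(config)),
    inputs = inputs,
    outputs = outputs,
    package = "gevisim",
    version = as.character(utils::packageVersion("gevisim")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
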