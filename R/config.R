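#' Default run configuration
#'
#' One flat list of every tunable parameter of the simulation and detection
#' pipeline, with defaults matching the package's reference study conditions:
#' 400 Hz imaging, 40,000-frame recordings with a mean of 100 spikes per
#' neuron (i.e. 1 Hz tonic firing), 5 out-of-focus background neurons per
#' target, fixed `F_max`, and signal-proportional Gaussian pixel noise.
#' Unknown fields are rejected by [merge_config()] / [load_run_config()].
#'
#' @param ... named overrides of any default field.
#' @return object of class `run_config` (a named list).
#' @section Fields:
#' \describe{
#'   \item{frames, frame_rate_hz}{recording length (frames) and rate (Hz).}
#'   \item{mean_spikes, refractory_frames}{expected spikes per recording and
#'     the absolute refractory gap (frames).}
#'   \item{ap_rise_frames, ap_decay_tau_frames}{optical action-potential
#'     waveform shape.}
#'   \item{subthreshold_sd, subthreshold_tau_frames}{subthreshold fluctuation
#'     SD (fraction of spike height) and correlation time (frames).}
#'   \item{fov, footprint_radius_px}{field of view (H, W) in pixels and soma
#'     Gaussian radius.}
#'   \item{n_neurons}{in-focus (labeled) neurons in the field = density.}
#'   \item{n_background_per_neuron, background_blur_px,
#'     background_displace_px}{out-of-focus background neurons per target and
#'     their blur / placement scales.}
#'   \item{polarity, F_max, sensitivity}{indicator model: polarity, fixed
#'     maximum brightness (counts) and `dF/F_min`.}
#'   \item{bleach_tau_frames}{photobleaching time constant (frames; `Inf`
#'     disables).}
#'   \item{noise_model, noise_coeff, noise_sd, offset}{pixel noise model
#'     (`"proportional"` SD = coeff x signal, or `"additive"` constant SD)
#'     and the flat background offset (counts/pixel).}
#'   \item{threshold_k, min_separation_frames, n_iter}{detection settings:
#'     wavelet threshold (robust SDs), event merge distance, extractor
#'     iterations.}
#' }
#' @export
default_run_config <- function(...) {
  cfg <- list(
    frames = 40000L,
    frame_rate_hz = 400,
    mean_spikes = 100,
    refractory_frames = 4,
    ap_rise_frames = 2,
    ap_decay_tau_frames = 3,
    subthreshold_sd = 0.1,
    subthreshold_tau_frames = 50,
    fov = c(32L, 32L),
    footprint_radius_px = 2,
    n_neurons = 1L,
    n_background_per_neuron = 5L,
    background_blur_px = 8,
    background_displace_px = 12,
    polarity = "positive",
    F_max = 100,
    sensitivity = 0.2,
    bleach_tau_frames = 20000,
    noise_model = "proportional",
    noise_coeff = 0.1,
    noise_sd = 1,
    offset = 2,
    threshold_k = 7,
    min_separation_frames = 4,
    n_iter = 3
  )
  structure(merge_config(structure(cfg, class = "run_config"), list(...)),
            class = "run_config")
}

#' Merge overrides into a run configuration, rejecting unknown keys
#'
#' @param config a `run_config`.
#' @param overrides named list of replacement values.
#' @return the merged `run_config`.
#' @export
merge_config <- function(config, overrides) {
  if (!length(overrides)) return(config)
  unknown <- setdiff(names(overrides), names(config))
  assert_that(length(unknown) == 0,
              "unknown config field(s): ", paste(unknown, collapse = ", "))
  structure(modifyList(unclass(config), overrides), class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-24s %s\n", nm, paste(format(x[[nm]]), collapse = " ")))
  }
  invisible(x)
}

#' Load / save a run configuration as YAML
#'
#' Round-trips losslessly; unknown keys in the file are rejected with an
#' error listing them, missing keys take their defaults.
#'
#' @param path YAML file path.
#' @return [load_run_config()]: a validated `run_config`.
#' @export
load_run_config <- function(path) {
  assert_that(file.exists(path), "config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.null(raw$fov)) raw$fov <- as.integer(raw$fov)
  for (nm in c("bleach_tau_frames"))
    if (!is.null(raw[[nm]]) && is.character(raw[[nm]]))
      raw[[nm]] <- as.numeric(gsub("\\.inf", "Inf", raw[[nm]], fixed = TRUE))
  cfg <- merge_config(default_run_config(), raw)
  validate_run_config(cfg)
}

#' @rdname load_run_config
#' @param config a `run_config` to write.
#' @export
save_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

validate_run_config <- function(cfg) {
  assert_that(cfg$frames > 0, "frames must be > 0")
  assert_that(cfg$frame_rate_hz > 0, "frame_rate_hz must be > 0")
  assert_that(cfg$polarity %in% c("positive", "negative"),
              "polarity must be 'positive' or 'negative'")
  assert_that(cfg$noise_model %in% c("proportional", "additive"),
              "noise_model must be 'proportional' or 'additive'")
  assert_that(length(cfg$fov) == 2 && all(cfg$fov >= 4),
              "fov must be (H, W) with H, W >= 4")
  assert_that(cfg$sensitivity > 0, "sensitivity must be > 0")
  assert_that(cfg$F_max > 0, "F_max must be > 0")
  cfg
}
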