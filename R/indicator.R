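#' Indicator parameters from polarity, maximum brightness and sensitivity
#'
#' Voltage indicators are modeled as linear reporters whose fluorescence spans
#' `[F_min, F_max]`. `F_max` is held fixed (the maximum brightness set by the
#' dye/fluorophore) and `F_min` is derived from the sensitivity
#' `dF/F_min = (F_max - F_min) / F_min`, giving `F_min = F_max / (1 +
#' sensitivity)`. Polarity decides which end of the range maps to rest: a
#' positive-going indicator rests at `F_min` and brightens to `F_max` at the
#' mean spike height; a negative-going indicator rests at `F_max` and dims to
#' `F_min`.
#'
#' @param polarity `"positive"` or `"negative"`.
#' @param F_max fixed maximum fluorescence (arbitrary counts, > 0).
#' @param sensitivity fractional response per action potential,
#'   `(F_max - F_min) / F_min` (> 0).
#' @param tau_on,tau_off optional first-order response time constants in
#'   seconds (rising / falling); `NULL` (default) disables kinetics filtering.
#' @return an object of class `indicator_params` with fields `polarity`,
#'   `F_max`, `F_min`, `sensitivity`, `tau_on`, `tau_off`.
#' @examples
#' indicator_params("positive", F_max = 1, sensitivity = 0.25)$F_min  # 0.8
#' @export
indicator_params <- function(polarity = c("positive", "negative"),
                             F_max = 100, sensitivity = 0.2,
                             tau_on = NULL, tau_off = NULL) {
  polarity <- match.arg(polarity)
  assert_that(F_max > 0, "F_max must be > 0")
  assert_that(sensitivity > 0, "sensitivity must be > 0")
  F_min <- F_max / (1 + sensitivity)
  structure(list(polarity = polarity, F_max = F_max, F_min = F_min,
                 sensitivity = sensitivity, tau_on = tau_on,
                 tau_off = tau_off),
            class = "indicator_params")
}

#' @export
print.indicator_params <- function(x, ...) {
  cat(sprintf(
    "<indicator_params> %s-going, F_max %.4g, F_min %.4g (dF/F_min = %.3g)\n",
    x$polarity, x$F_max, x$F_min, x$sensitivity))
  if (!is.null(x$tau_on))
    cat(sprintf("  kinetics: tau_on %.3g s, tau_off %.3g s\n",
                x$tau_on, x$tau_off %||% x$tau_on))
  invisible(x)
}

#' Convert a normalized voltage trace to an indicator fluorescence trace
#'
#' Linear range scaling between `F_min` and `F_max`:
#' positive-going `f = F_min + v (F_max - F_min)`, negative-going
#' `f = F_max - v (F_max - F_min)`, where `v` is normalized activity (0 rest,
#' 1 mean spike height). Subthreshold excursions that would leave
#' `[F_min, F_max]` are clipped. If `tau_on`/`tau_off` are set on the
#' parameters, an asymmetric single-pole low-pass (rising edges filtered with
#' `tau_on`, falling with `tau_off`) is applied after scaling.
#'
#' @param v a `voltage_trace` (or bare numeric vector of normalized activity).
#' @param params an [indicator_params] object.
#' @param frame_rate_hz frame rate, needed only when kinetics filtering is on
#'   and `v` is a bare vector.
#' @return an object of class `fluorescence_trace`: fields `f` (counts per
#'   frame), `frame_rate_hz`, `params`.
#' @export
voltage_to_fluorescence <- function(v, params, frame_rate_hz = 400) {
  stopifnot(inherits(params, "indicator_params"))
  if (inherits(v, "voltage_trace")) {
    rate <- v$spikes$frame_rate_hz
    vv <- v$v
  } else {
    rate <- frame_rate_hz
    vv <- as.numeric(v)
  }
  span <- params$F_max - params$F_min
  f <- if (params$polarity == "positive") params$F_min + vv * span
       else params$F_max - vv * span
  f <- pmin(pmax(f, params$F_min), params$F_max)
  if (!is.null(params$tau_on)) {
    tau_on <- params$tau_on
    tau_off <- params$tau_off %||% tau_on
    # a depolarization moves f up for positive polarity, down for negative
    up_is_on <- params$polarity == "positive"
    a_on <- 1 - exp(-1 / (tau_on * rate))
    a_off <- 1 - exp(-1 / (tau_off * rate))
    out <- numeric(length(f))
    out[1] <- f[1]
    for (t in seq_along(f)[-1]) {
      rising <- f[t] > out[t - 1]
      a <- if (rising == up_is_on) a_on else a_off
      out[t] <- out[t - 1] + a * (f[t] - out[t - 1])
    }
    f <- out
  }
  fluorescence_trace(f, rate, params)
}

#' Fluorescence trace container
#'
#' @param f numeric intensity per frame.
#' @param frame_rate_hz frames per second.
#' @param params optional [indicator_params] that generated the trace.
#' @return object of class `fluorescence_trace`.
#' @export
fluorescence_trace <- function(f, frame_rate_hz = 400, params = NULL) {
  assert_that(frame_rate_hz > 0, "frame_rate_hz must be > 0")
  structure(list(f = as.numeric(f), frame_rate_hz = frame_rate_hz,
                 params = params),
            class = "fluorescence_trace")
}

#' @export
print.fluorescence_trace <- function(x, ...) {
  cat(sprintf("<fluorescence_trace> %d frames at %g Hz, range [%.4g, %.4g]\n",
              length(x$f), x$frame_rate_hz, min(x$f), max(x$f)))
  invisible(x)
}
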