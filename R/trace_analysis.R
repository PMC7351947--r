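#' Fit and remove photobleaching from a fluorescence trace
#'
#' Fits `F(t) = A exp(-t / tau) + C` by nonlinear least squares (Levenberg-
#' Marquardt, multi-start over log-spaced tau) and divides it out:
#' `corrected = F / fit * fit[1]`, the standard correction for multiplicative
#' bleaching. A trace with no appreciable decay takes the `tau = Inf` branch
#' and is returned unchanged; a non-convergent fit falls back to a linear
#' detrend and sets the `fallback` flag.
#'
#' @param f a [fluorescence_trace] or numeric vector.
#' @return object of class `bleach_fit`: `corrected` (same type as input),
#'   `A`, `tau`, `C` (tau in frames), `fitted`, `fallback`.
#' @examples
#' fb <- fit_bleach(100 * exp(-(0:999) / 300))
#' fb$tau
#' @export
fit_bleach <- function(f) {
  fx <- if (inherits(f, "fluorescence_trace")) f$f else as.numeric(f)
  n <- length(fx)
  assert_that(n >= 30, "trace too short for a 3-parameter bleach fit")
  tvec <- seq_len(n) - 1

  wrap <- function(fitted, A, tau, C, fallback = FALSE) {
    corrected <- fx / fitted * fitted[1]
    out <- f
    if (inherits(f, "fluorescence_trace")) out$f <- corrected
    else out <- corrected
    structure(list(corrected = out, A = A, tau = tau, C = C,
                   fitted = fitted, fallback = fallback),
              class = "bleach_fit")
  }

  rng <- diff(range(fx))
  if (rng <= 1e-12 * max(abs(fx), 1))             # constant: tau -> Inf branch
    return(wrap(rep(mean(fx), n), A = 0, tau = Inf, C = mean(fx)))

  # profile the linear parameters (A, C) out and search over log(tau): the
  # 1-D profile is smooth and cannot hit the singular Jacobians that a joint
  # 3-parameter start sometimes does on weakly decaying traces
  prof <- function(ltau) {
    ex <- exp(-tvec / exp(ltau))
    co <- stats::lm.fit(cbind(ex, 1), fx)$coefficients
    list(rss = sum((fx - co[1] * ex - co[2])^2),
         A = unname(co[1]), C = unname(co[2]))
  }
  p <- tryCatch({
    grid <- log(n * c(1 / 50, 1 / 10, 1 / 3, 1, 3, 10, 50))
    rss_g <- vapply(grid, function(g) prof(g)$rss, 0)
    i0 <- which.min(rss_g)
    lo <- grid[max(1, i0 - 1)]; hi <- grid[min(length(grid), i0 + 1)]
    opt <- stats::optimize(function(g) prof(g)$rss, c(lo, hi), tol = 1e-8)
    best <- prof(opt$minimum)
    st <- c(A = best$A, tau = exp(opt$minimum), C = best$C)
    polish <- tryCatch(
      coef(minpack.lm::nlsLM(fx ~ A * exp(-tvec / tau) + C,
                             start = as.list(st),
                             lower = c(-Inf, 1e-6, -Inf),
                             control = minpack.lm::nls.lm.control(maxiter = 200))),
      error = function(e) st)
    polish
  }, error = function(e) NULL)
  if (is.null(p)) {                               # linear detrend fallback
    co <- stats::lm.fit(cbind(1, tvec), fx)$coefficients
    fitted <- co[1] + co[2] * tvec
    return(wrap(fitted, A = NA_real_, tau = NA_real_, C = NA_real_,
                fallback = TRUE))
  }
  # negligible decay amplitude: treat as constant rather than divide noise
  if (abs(p[["A"]]) < 1e-8 * max(abs(fx), 1))
    return(wrap(rep(mean(fx), n), A = 0, tau = Inf, C = mean(fx)))
  fitted <- p[["A"]] * exp(-tvec / p[["tau"]]) + p[["C"]]
  wrap(fitted, A = p[["A"]], tau = p[["tau"]], C = p[["C"]])
}

#' @export
print.bleach_fit <- function(x, ...) {
  if (x$fallback)
    cat("<bleach_fit> exponential fit failed; linear detrend applied\n")
  else
    cat(sprintf("<bleach_fit> A %.4g, tau %.5g frames, C %.4g\n",
                x$A, x$tau, x$C))
  invisible(x)
}

#' @export
coef.bleach_fit <- function(object, ...)
  c(A = object$A, tau = object$tau, C = object$C)

#' Compute dF/F against a fixed baseline window
#'
#' `F0` is the mean fluorescence over `baseline_window` (e.g. the second
#' before stimulation) and `dff = (F - F0) / F0`.
#'
#' @param f [fluorescence_trace] or numeric vector.
#' @param baseline_window integer frame indices of the baseline period
#'   (default: the first second of the trace).
#' @return object of class `dff_trace`: `dff`, `f0` (scalar here, per-frame
#'   for [moving_dff()]), `frame_rate_hz`.
#' @export
compute_dff <- function(f, baseline_window = NULL) {
  rate <- if (inherits(f, "fluorescence_trace")) f$frame_rate_hz else 400
  fx <- if (inherits(f, "fluorescence_trace")) f$f else as.numeric(f)
  if (is.null(baseline_window))
    baseline_window <- seq_len(min(length(fx), round(rate)))
  assert_that(all(baseline_window >= 1 & baseline_window <= length(fx)),
              "baseline_window must lie within the trace")
  f0 <- mean(fx[baseline_window])
  assert_that(f0 > 0, "baseline F0 must be > 0 (check background subtraction)")
  structure(list(dff = (fx - f0) / f0, f0 = f0, frame_rate_hz = rate),
            class = "dff_trace")
}

#' @export
print.dff_trace <- function(x, ...) {
  cat(sprintf("<dff_trace> %d frames, dF/F range [%.3g, %.3g]\n",
              length(x$dff), min(x$dff), max(x$dff)))
  invisible(x)
}

#' Invert a dff_trace back to raw fluorescence
#'
#' @param x a `dff_trace`.
#' @return numeric: `F = F0 * (1 + dff)` frame-wise.
#' @export
dff_to_f <- function(x) {
  stopifnot(inherits(x, "dff_trace"))
  x$f0 * (1 + x$dff)
}

#' Moving-percentile baseline of a fluorescence trace
#'
#' Centered moving-window percentile, the resting-fluorescence estimator used
#' for tonically active neurons: the bottom 10th percentile of a 1 s window
#' for a positive-going indicator (spikes protrude upward), the top 10th
#' percentile for a negative-going one. Window edges are truncated.
#'
#' @param f [fluorescence_trace] or numeric vector.
#' @param window_s window length in seconds (default 1).
#' @param percentile percentile within the window (default 10).
#' @param side `"bottom"` (default; percentile taken as-is) or `"top"`
#'   (the `100 - percentile` quantile).
#' @param frame_rate_hz used when `f` is a bare vector.
#' @param step evaluate the window percentile every `step` frames and
#'   interpolate linearly in between (1 = exact at every frame). The default
#'   `NULL` uses `window / 20`, which changes the baseline negligibly (it
#'   varies on the window timescale) at a fraction of the cost.
#' @return numeric per-frame baseline, same length as the trace.
#' @export
moving_percentile_baseline <- function(f, window_s = 1, percentile = 10,
                                       side = c("bottom", "top"),
                                       frame_rate_hz = 400, step = NULL) {
  side <- match.arg(side)
  rate <- if (inherits(f, "fluorescence_trace")) f$frame_rate_hz else frame_rate_hz
  fx <- if (inherits(f, "fluorescence_trace")) f$f else as.numeric(f)
  n <- length(fx)
  win <- round(window_s * rate)
  assert_that(win >= 10, "window must span at least 10 samples")
  assert_that(win <= n, "window longer than the trace")
  p <- if (side == "bottom") percentile / 100 else 1 - percentile / 100
  step <- step %||% max(1L, win %/% 20L)
  at <- unique(c(seq(1L, n, by = step), n))
  h <- win %/% 2
  q <- vapply(at, function(i)
    quantile(fx[max(1L, i - h):min(n, i + h)], probs = p, names = FALSE),
    0)
  if (length(at) == n) q else approx(at, q, xout = seq_len(n))$y
}

#' dF/F against a moving-percentile baseline
#'
#' Per-frame `F0` from [moving_percentile_baseline()];
#' `dff = (F - F0) / F0` frame-wise.
#'
#' @inheritParams moving_percentile_baseline
#' @return a `dff_trace` whose `f0` is the per-frame baseline.
#' @export
moving_dff <- function(f, window_s = 1, percentile = 10,
                       side = c("bottom", "top"), frame_rate_hz = 400) {
  side <- match.arg(side)
  rate <- if (inherits(f, "fluorescence_trace")) f$frame_rate_hz else frame_rate_hz
  fx <- if (inherits(f, "fluorescence_trace")) f$f else as.numeric(f)
  f0 <- moving_percentile_baseline(f, window_s, percentile, side, frame_rate_hz)
  assert_that(all(f0 > 0), "moving baseline must stay > 0")
  structure(list(dff = (fx - f0) / f0, f0 = f0, frame_rate_hz = rate),
            class = "dff_trace")
}
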