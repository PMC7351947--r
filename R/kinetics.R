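#' Fit a double-exponential to an indicator step response
#'
#' Kinetics of the fluorescence response to a voltage step (e.g. a 100 mV
#' clamp step imaged at 3200 Hz) are summarized by
#' `y(t) = a1 exp(-t / tau1) + a2 exp(-t / tau2) + c`, fit by Levenberg-
#' Marquardt least squares. Initialization is a multi-start over log-spaced
#' `(tau1, tau2)` pairs with amplitudes solved linearly at each start; the
#' best-residual refinement is reported. Time constants are returned ordered
#' (`tau1 <= tau2`). Data that are really single-exponential are not an
#' error: one component simply absorbs the amplitude.
#'
#' @param y response samples (a `dff_trace` or numeric), starting at the step.
#' @param time_s sample times in seconds (default from `sample_rate_hz`).
#' @param sample_rate_hz sampling rate used when `time_s` is missing
#'   (default 3200).
#' @param t0 index of the step onset; samples before it are dropped.
#' @param n_starts number of log-spaced tau values per axis in the
#'   multi-start grid.
#' @return object of class `kinetics_fit` with fields `a1, tau1, a2, tau2, c`
#'   (taus in seconds), `residual` (RMS), `fitted`, `time_s`, and methods
#'   [coef()], [predict()], [print()].
#' @examples
#' t <- seq(0, 0.03, by = 1 / 3200)
#' y <- 0.7 * exp(-t / 8e-4) + 0.3 * exp(-t / 5e-3)
#' coef(fit_double_exponential(y, time_s = t))
#' @export
fit_double_exponential <- function(y, time_s = NULL, sample_rate_hz = 3200,
                                   t0 = 1, n_starts = 5) {
  yy <- if (inherits(y, "dff_trace")) y$dff else as.numeric(y)
  if (is.null(time_s)) time_s <- (seq_along(yy) - 1) / sample_rate_hz
  assert_that(length(time_s) == length(yy), "time_s must match y in length")
  keep <- seq_along(yy) >= t0
  yy <- yy[keep]; tt <- time_s[keep] - time_s[which(keep)[1]]
  assert_that(length(yy) >= 10, "need at least 10 samples after the step")

  span <- max(tt[tt > 0])
  taus <- exp(seq(log(max(tt[tt > 0][1], span / 200)), log(span),
                  length.out = n_starts))
  # linear amplitudes for each tau pair; LM-refine the best few starts
  starts <- list()
  for (i in seq_len(n_starts)) for (j in i:n_starts) {
    X <- cbind(exp(-tt / taus[i]), exp(-tt / taus[j]), 1)
    co <- tryCatch(stats::lm.fit(X, yy)$coefficients, error = function(e) NULL)
    if (is.null(co) || anyNA(co)) next
    rss <- sum((yy - X %*% co)^2)
    starts[[length(starts) + 1]] <-
      list(rss = rss, a1 = unname(co[1]), tau1 = taus[i],
           a2 = unname(co[2]), tau2 = taus[j], c = unname(co[3]))
  }
  assert_that(length(starts) > 0,
              "could not initialize the double-exponential fit")
  starts <- starts[order(vapply(starts, `[[`, 0, "rss"))]

  p <- NULL; best_rss <- Inf
  for (st in head(starts, 4)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        yy ~ a1 * exp(-tt / tau1) + a2 * exp(-tt / tau2) + cc,
        start = list(a1 = st$a1, tau1 = st$tau1, a2 = st$a2,
                     tau2 = max(st$tau2, st$tau1 * 1.01), cc = st$c),
        lower = c(-Inf, 1e-9, -Inf, 1e-9, -Inf),
        control = minpack.lm::nls.lm.control(maxiter = 500,
                                             ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (rss < best_rss) { best_rss <- rss; p <- coef(fit) }
  }
  if (is.null(p)) {
    st <- starts[[1]]
    p <- c(a1 = st$a1, tau1 = st$tau1, a2 = st$a2, tau2 = st$tau2, cc = st$c)
  }
  if (p[["tau1"]] > p[["tau2"]])
    p <- p[c("a2", "tau2", "a1", "tau1", "cc")]
  fitted <- p[[1]] * exp(-tt / p[[2]]) + p[[3]] * exp(-tt / p[[4]]) + p[[5]]
  structure(list(a1 = unname(p[[1]]), tau1 = unname(p[[2]]),
                 a2 = unname(p[[3]]), tau2 = unname(p[[4]]),
                 c = unname(p[[5]]),
                 residual = sqrt(mean((yy - fitted)^2)),
                 fitted = fitted, time_s = tt, y = yy),
            class = "kinetics_fit")
}

#' @export
coef.kinetics_fit <- function(object, ...)
  c(a1 = object$a1, tau1 = object$tau1, a2 = object$a2, tau2 = object$tau2,
    c = object$c)

#' @export
predict.kinetics_fit <- function(object, time_s = object$time_s, ...) {
  object$a1 * exp(-time_s / object$tau1) +
    object$a2 * exp(-time_s / object$tau2) + object$c
}

#' @export
print.kinetics_fit <- function(x, ...) {
  tot <- abs(x$a1) + abs(x$a2)
  cat(sprintf(paste0("<kinetics_fit> a1 %.3g (tau1 %.4g ms, %.0f%%), ",
                     "a2 %.3g (tau2 %.4g ms, %.0f%%), c %.3g\n",
                     "  RMS residual %.3g\n"),
              x$a1, 1e3 * x$tau1, 100 * abs(x$a1) / tot,
              x$a2, 1e3 * x$tau2, 100 * abs(x$a2) / tot, x$c, x$residual))
  invisible(x)
}

#' Build a fluorescence-voltage (F-V) curve from voltage-clamp steps
#'
#' Summarizes steady-state `dF/F` per command voltage (the protocol steps a
#' clamped cell from -110 mV to +50 mV in 20 mV increments). Duplicate
#' voltages are averaged; the slope sign comes from a least-squares line.
#'
#' @param step_dffs list of `list(voltage = mV, dff = dff_trace or numeric)`;
#'   for each step the steady-state response is the mean over
#'   `steady_frac` tail of the trace.
#' @param steady_frac final fraction of each trace treated as steady state.
#' @return object of class `fv_curve`: `voltages`, `dff_means`, `dff_sds`,
#'   `slope`, `slope_sign`.
#' @export
build_fv_curve <- function(step_dffs, steady_frac = 0.5) {
  assert_that(length(step_dffs) >= 2, "need at least 2 voltage steps")
  volts <- vapply(step_dffs, function(s) as.numeric(s$voltage), 0)
  vals <- vapply(step_dffs, function(s) {
    d <- if (inherits(s$dff, "dff_trace")) s$dff$dff else as.numeric(s$dff)
    tail_idx <- seq.int(max(1, ceiling(length(d) * (1 - steady_frac))), length(d))
    mean(d[tail_idx])
  }, 0)
  sds <- vapply(step_dffs, function(s) {
    d <- if (inherits(s$dff, "dff_trace")) s$dff$dff else as.numeric(s$dff)
    tail_idx <- seq.int(max(1, ceiling(length(d) * (1 - steady_frac))), length(d))
    sd(d[tail_idx])
  }, 0)
  grid <- sort(unique(volts))
  assert_that(length(grid) >= 2, "need at least 2 distinct voltages")
  means <- vapply(grid, function(v) mean(vals[volts == v]), 0)
  sdm <- vapply(grid, function(v) mean(sds[volts == v]), 0)
  slope <- unname(coef(lm(means ~ grid))[2])
  structure(list(voltages = grid, dff_means = means, dff_sds = sdm,
                 slope = slope,
                 slope_sign = if (slope >= 0) "positive" else "negative"),
            class = "fv_curve")
}

#' @export
print.fv_curve <- function(x, ...) {
  cat(sprintf("<fv_curve> %d voltages (%g to %g mV), slope %s (%.3g /mV)\n",
              length(x$voltages), min(x$voltages), max(x$voltages),
              x$slope_sign, x$slope))
  invisible(x)
}

#' @export
plot.fv_curve <- function(x, ...) {
  plot(x$voltages, x$dff_means, type = "b", pch = 16,
       xlab = "membrane voltage (mV)", ylab = expression(Delta * F / F[0]),
       ...)
  arrows(x$voltages, x$dff_means - x$dff_sds,
         x$voltages, x$dff_means + x$dff_sds,
         angle = 90, code = 3, length = 0.03)
  invisible(x)
}
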