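#' Run a density x sensitivity x polarity detection sweep
#'
#' For every combination of labeling density (number of in-focus neurons in a
#' fixed field of view, each bringing its own out-of-focus background
#' neurons), indicator sensitivity, polarity and replicate seed: simulate a
#' recording ([simulate_recording]), run the movie spike-detection pipeline
#' on the first (target) neuron ([detect_from_movie]), and score it against
#' ground truth ([spike_iou]). Replicate seeds derive deterministically from
#' `(base_seed, cell, rep)`, so a sweep is exactly reproducible. Per-cell
#' failures are recorded as `NA` rows, not fatal.
#'
#' @param densities integer vector of neuron counts.
#' @param sensitivities numeric vector of `dF/F_min` values.
#' @param polarities character vector, subset of
#'   `c("positive", "negative")`.
#' @param n_reps replicates per grid cell.
#' @param config base run configuration ([default_run_config]); `n_neurons`,
#'   `sensitivity` and `polarity` are overridden by the grid.
#' @param base_seed integer seed for the whole sweep.
#' @param tolerance_frames IoU matching tolerance (default 0, no binning).
#' @param verbose print one line per grid cell.
#' @return object of class `gevi_sweep`: `grid` (data.frame with one row per
#'   cell x replicate: polarity, sensitivity, density, rep, seed, iou,
#'   error_rate, n_true, n_inferred, mean_event_z), plus the config.
#' @export
run_polarity_sweep <- function(densities = c(1, 2, 4, 8, 16),
                               sensitivities = c(0.2, 1.0),
                               polarities = c("positive", "negative"),
                               n_reps = 20,
                               config = default_run_config(),
                               base_seed = 1, tolerance_frames = 0,
                               verbose = FALSE) {
  assert_that(length(densities) > 0 && length(sensitivities) > 0 &&
                length(polarities) > 0, "all grid axes must be non-empty")
  assert_that(n_reps >= 1, "n_reps must be >= 1")
  cells <- expand.grid(polarity = polarities, sensitivity = sensitivities,
                       density = densities, stringsAsFactors = FALSE)
  rows <- vector("list", nrow(cells) * n_reps)
  k <- 0L
  for (ci in seq_len(nrow(cells))) {
    cell <- cells[ci, ]
    for (rep_i in seq_len(n_reps)) {
      k <- k + 1L
      seed <- seed_stream(base_seed, ci, rep_i)
      res <- tryCatch({
        rec <- simulate_recording(config, seed = seed,
                                  n_neurons = cell$density,
                                  sensitivity = cell$sensitivity,
                                  polarity = cell$polarity)
        det <- detect_from_movie(rec,
                                 n_iter = config$n_iter,
                                 threshold_k = config$threshold_k,
                                 min_separation_frames =
                                   config$min_separation_frames)
        truth <- rec$neurons[[1]]$voltage$spikes
        ev <- spike_iou(truth, det$spike_frames, n_frames = truth$n_frames,
                        tolerance_frames = tolerance_frames,
                        mean_event_z = if (length(det$event_z))
                          mean(det$event_z) else NA_real_)
        data.frame(polarity = cell$polarity, sensitivity = cell$sensitivity,
                   density = cell$density, rep = rep_i, seed = seed,
                   iou = ev$iou, error_rate = ev$error_rate,
                   n_true = ev$n_true, n_inferred = ev$n_inferred,
                   mean_event_z = ev$mean_event_z)
      }, error = function(e) {
        warning(sprintf("sweep cell (%s, s=%g, d=%d, rep %d) failed: %s",
                        cell$polarity, cell$sensitivity, cell$density, rep_i,
                        conditionMessage(e)), call. = FALSE)
        data.frame(polarity = cell$polarity, sensitivity = cell$sensitivity,
                   density = cell$density, rep = rep_i, seed = seed,
                   iou = NA_real_, error_rate = NA_real_, n_true = NA_integer_,
                   n_inferred = NA_integer_, mean_event_z = NA_real_)
      })
      rows[[k]] <- res
    }
    if (verbose) {
      done <- do.call(rbind, rows[(k - n_reps + 1):k])
      message(sprintf("cell %s s=%g d=%2d: mean error %.3f",
                      cell$polarity, cell$sensitivity, cell$density,
                      mean(done$error_rate, na.rm = TRUE)))
    }
  }
  structure(list(grid = do.call(rbind, rows), config = config,
                 base_seed = base_seed),
            class = "gevi_sweep")
}

#' @export
print.gevi_sweep <- function(x, ...) {
  g <- x$grid
  cat(sprintf(paste0("<gevi_sweep> %d recordings: densities {%s} x ",
                     "sensitivities {%s} x polarities {%s}, %d rep(s)\n"),
              nrow(g), paste(sort(unique(g$density)), collapse = ", "),
              paste(sort(unique(g$sensitivity)), collapse = ", "),
              paste(unique(g$polarity), collapse = ", "),
              max(g$rep)))
  print(summary(x))
  invisible(x)
}

#' Summarize a sweep: mean error per grid cell with bootstrap CI
#'
#' @param object a `gevi_sweep`.
#' @param n_boot bootstrap resamples for the CI of the per-cell mean error.
#' @param conf confidence level.
#' @param seed seed for the bootstrap.
#' @param ... ignored.
#' @return data.frame with one row per (polarity, sensitivity, density):
#'   `mean_error`, `ci_lo`, `ci_hi`, `mean_fidelity`, `mean_event_z`,
#'   `n_reps`.
#' @export
summary.gevi_sweep <- function(object, n_boot = 200, conf = 0.95, seed = 1,
                               ...) {
  g <- object$grid
  keys <- unique(g[, c("polarity", "sensitivity", "density")])
  keys <- keys[order(keys$polarity, keys$sensitivity, keys$density), ]
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sel <- g$polarity == keys$polarity[i] &
      g$sensitivity == keys$sensitivity[i] & g$density == keys$density[i]
    err <- g$error_rate[sel]
    err_ok <- err[!is.na(err)]
    ci <- c(NA_real_, NA_real_)
    if (length(err_ok) > 1) {
      bs <- with_seed(seed_stream(seed, i), replicate(n_boot,
        mean(sample(err_ok, length(err_ok), replace = TRUE))))
      ci <- unname(quantile(bs, c((1 - conf) / 2, 1 - (1 - conf) / 2)))
    }
    data.frame(keys[i, ], mean_error = mean(err_ok),
               ci_lo = ci[1], ci_hi = ci[2],
               mean_fidelity = mean(1 - err_ok),
               mean_event_z = mean(g$mean_event_z[sel], na.rm = TRUE),
               n_reps = length(err_ok))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
plot.gevi_sweep <- function(x, sensitivity = NULL, ...) {
  sm <- summary(x)
  if (!is.null(sensitivity)) sm <- sm[sm$sensitivity %in% sensitivity, ]
  combos <- unique(sm[, c("polarity", "sensitivity")])
  cols <- ifelse(combos$polarity == "positive", "#D55E00", "#0072B2")
  ltys <- as.integer(factor(combos$sensitivity))
  plot(NA, xlim = range(sm$density), ylim = c(0, 1), log = "x",
       xlab = "labeling density (neurons per field)",
       ylab = "spike detection error (1 - IoU)", ...)
  for (i in seq_len(nrow(combos))) {
    sel <- sm$polarity == combos$polarity[i] &
      sm$sensitivity == combos$sensitivity[i]
    lines(sm$density[sel], sm$mean_error[sel], type = "b", pch = 16,
          col = cols[i], lty = ltys[i])
  }
  legend("topleft", bty = "n",
         legend = sprintf("%s, dF/F %g", combos$polarity, combos$sensitivity),
         col = cols, lty = ltys, pch = 16)
  invisible(x)
}

#' Matched-error density ratio between polarities
#'
#' Interpolates each polarity's error-vs-density curve (log-density axis by
#' default, where the curves are closer to linear) at a common error target
#' and returns the fold difference in tolerable density,
#' `density(positive) / density(negative)`, at the given sensitivity. This is
#' the "how much more densely can you label with a positive-going indicator
#' at the same spike detection error" summary.
#'
#' If the positive-going curve never reaches the error target inside the
#' simulated density range (it is still too accurate at the highest density),
#' the ratio is computed with the highest simulated density in the numerator
#' and flagged `censored = TRUE`: the true fold change is at least the
#' returned value.
#'
#' @param sweep a `gevi_sweep` covering both polarities.
#' @param sensitivity sensitivity at which to compare (default: highest in
#'   the sweep).
#' @param error_target error rate at which densities are matched; `NULL`
#'   (default) uses the midpoint of the negative-going curve's achievable
#'   range.
#' @param interp `"log"` (default) or `"linear"` density interpolation.
#' @return the fold change (numeric) with attributes `error_target`,
#'   `density_positive`, `density_negative`, `censored`.
#' @export
matched_density_ratio <- function(sweep, sensitivity = NULL,
                                  error_target = NULL,
                                  interp = c("log", "linear")) {
  interp <- match.arg(interp)
  sm <- summary(sweep)
  sensitivity <- sensitivity %||% max(sm$sensitivity)
  curves <- lapply(c(positive = "positive", negative = "negative"),
    function(p) {
      cv <- sm[sm$polarity == p & sm$sensitivity == sensitivity, ]
      assert_that(nrow(cv) >= 2,
                  sprintf("sweep lacks a %s-going curve at sensitivity %g",
                          p, sensitivity))
      cv <- cv[order(cv$density), ]
      cv$mono_error <- cummax(cv$mean_error)  # enforce monotone interpolation
      cv
    })
  if (is.null(error_target)) {
    neg <- curves$negative
    error_target <- mean(range(neg$mono_error))
  }
  dens_at <- function(cv) {
    x <- if (interp == "log") log(cv$density) else cv$density
    if (error_target < min(cv$mono_error) || error_target > max(cv$mono_error))
      return(NA_real_)
    d <- approx(cv$mono_error, x, xout = error_target, ties = "ordered")$y
    if (interp == "log") exp(d) else d
  }
  d_neg <- dens_at(curves$negative)
  assert_that(is.finite(d_neg),
              sprintf("error target %.3g outside the negative curve range [%.3g, %.3g]",
                      error_target, min(curves$negative$mono_error),
                      max(curves$negative$mono_error)))
  d_pos <- dens_at(curves$positive)
  censored <- FALSE
  if (!is.finite(d_pos)) {
    if (error_target > max(curves$positive$mono_error)) {
      d_pos <- max(curves$positive$density)   # lower bound: still below target
      censored <- TRUE
    } else {
      stop_invalid(sprintf(
        "error target %.3g below the positive curve range [%.3g, %.3g]",
        error_target, min(curves$positive$mono_error),
        max(curves$positive$mono_error)))
    }
  }
  structure(d_pos / d_neg, error_target = error_target,
            density_positive = d_pos, density_negative = d_neg,
            censored = censored)
}

#' Fidelity ratio between polarities at one grid cell
#'
#' Ratio of mean spike-detection fidelity, positive-going over
#' negative-going, at a given density and sensitivity. Fidelity defaults to
#' `1 - error_rate` (i.e. IoU); `measure = "mean_event_z"` uses the mean
#' event z-score instead (both candidate readings of "detection fidelity"
#' are available).
#'
#' @param sweep a `gevi_sweep`.
#' @param density,sensitivity grid cell (defaults: highest of each).
#' @param measure `"one_minus_error"` (default) or `"mean_event_z"`.
#' @return the fold change; `Inf` with attribute `zero_denominator = TRUE`
#'   when the negative-going fidelity is 0.
#' @export
fidelity_ratio <- function(sweep, density = NULL, sensitivity = NULL,
                           measure = c("one_minus_error", "mean_event_z")) {
  measure <- match.arg(measure)
  g <- sweep$grid
  density <- density %||% max(g$density)
  sensitivity <- sensitivity %||% max(g$sensitivity)
  val <- function(p) {
    sel <- g$polarity == p & g$density == density &
      g$sensitivity == sensitivity
    assert_that(any(sel), sprintf("no %s-going cell at (d=%g, s=%g)",
                                  p, density, sensitivity))
    if (measure == "one_minus_error") mean(1 - g$error_rate[sel], na.rm = TRUE)
    else mean(g$mean_event_z[sel], na.rm = TRUE)
  }
  fp <- val("positive"); fn <- val("negative")
  if (fn == 0)
    return(structure(Inf, zero_denominator = TRUE, fidelity_positive = fp,
                     fidelity_negative = 0))
  structure(fp / fn, zero_denominator = FALSE, fidelity_positive = fp,
            fidelity_negative = fn)
}
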