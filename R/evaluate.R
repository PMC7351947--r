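#' Score an inferred spike train against ground truth with IoU
#'
#' Spikes are compared as binary per-frame labels at the imaging rate,
#' without binning: `IoU = |intersection| / |union|` of the two label sets,
#' and the spike-detection error rate is `1 - IoU`. With
#' `tolerance_frames > 0`, inferred events are first greedily matched
#' one-to-one to the nearest ground-truth frame within the tolerance (closest
#' pairs first, earlier frame on ties) and matched events are snapped to
#' their ground-truth frame before the label comparison. Two empty trains
#' compare as `IoU = 1`.
#'
#' @param truth,inferred [spike_train] objects (or bare integer frame
#'   vectors) on the same time base.
#' @param n_frames recording length, required when both arguments are bare
#'   vectors.
#' @param tolerance_frames matching tolerance in frames (default 0: exact).
#' @param mean_event_z optional detection fidelity z-score carried through to
#'   the result.
#' @return object of class `evaluation`: `iou`, `error_rate` (= 1 - iou),
#'   `n_true`, `n_inferred`, `n_intersect`, `mean_event_z`.
#' @examples
#' spike_iou(c(10, 20), c(10, 30), n_frames = 100)$iou  # 1/3
#' @export
spike_iou <- function(truth, inferred, n_frames = NULL, tolerance_frames = 0,
                      mean_event_z = NA_real_) {
  tf <- if (inherits(truth, "spike_train")) truth$frames else
    as.integer(round(truth))
  inf <- if (inherits(inferred, "spike_train")) inferred$frames else
    as.integer(round(inferred))
  if (inherits(truth, "spike_train")) n_frames <- n_frames %||% truth$n_frames
  if (inherits(inferred, "spike_train"))
    n_frames <- n_frames %||% inferred$n_frames
  assert_that(!is.null(n_frames), "n_frames is required for bare frame vectors")
  tf <- sort(unique(tf)); inf <- sort(unique(inf))

  if (tolerance_frames > 0 && length(tf) && length(inf)) {
    pairs <- expand.grid(i = seq_along(inf), t = seq_along(tf))
    pairs$dt <- abs(inf[pairs$i] - tf[pairs$t])
    pairs <- pairs[pairs$dt <= tolerance_frames, , drop = FALSE]
    pairs <- pairs[order(pairs$dt, tf[pairs$t]), , drop = FALSE]
    used_i <- logical(length(inf)); used_t <- logical(length(tf))
    for (r in seq_len(nrow(pairs))) {
      i <- pairs$i[r]; t <- pairs$t[r]
      if (!used_i[i] && !used_t[t]) {
        inf[i] <- tf[t]
        used_i[i] <- TRUE; used_t[t] <- TRUE
      }
    }
    inf <- sort(unique(inf))
  }

  n_int <- length(intersect(tf, inf))
  n_union <- length(union(tf, inf))
  iou <- if (n_union == 0) 1 else n_int / n_union
  structure(list(iou = iou, error_rate = 1 - iou,
                 n_true = length(tf), n_inferred = length(inf),
                 n_intersect = n_int, mean_event_z = mean_event_z),
            class = "evaluation")
}

#' @export
print.evaluation <- function(x, ...) {
  cat(sprintf(
    "<evaluation> IoU %.3f (error %.3f): %d true, %d inferred, %d shared\n",
    x$iou, x$error_rate, x$n_true, x$n_inferred, x$n_intersect))
  invisible(x)
}
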