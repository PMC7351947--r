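# Maximal overlap discrete wavelet transform (MODWT) and its additive
# multiresolution analysis (MRA), after Percival & Walden (2000), ch. 5.
# Only the filters needed here are shipped; sym4 is the detector's default.

# Least-asymmetric (Symlet) 4-tap-pair scaling filters, standard constants.
.wavelet_filters <- list(
  haar = c(0.7071067811865476, 0.7071067811865476),
  sym4 = c(0.03222310060404270, -0.01260396726203783, -0.09921954357684722,
           0.29785779560527736, 0.80373875180591614, 0.49761866763201545,
           -0.02963552764599851, -0.07576571478927333)
)

wavelet_filter <- function(wavelet = "sym4") {
  g <- .wavelet_filters[[match.arg(wavelet, names(.wavelet_filters))]]
  L <- length(g)
  h <- rev(g) * (-1)^(seq_len(L) - 1)      # quadrature mirror
  list(g = g, h = h, L = L)
}

# y_t = x_{(t - s) mod N}  (circular lag by s frames)
circ_lag <- function(x, s) {
  n <- length(x)
  s <- s %% n
  if (s == 0) return(x)
  c(x[(n - s + 1):n], x[1:(n - s)])
}

modwt_filter_step <- function(v, filt, j, inverse = FALSE) {
  step <- 2^(j - 1)
  out <- numeric(length(v))
  for (l in seq_along(filt)) {
    s <- (l - 1) * step * (if (inverse) -1 else 1)
    out <- out + filt[l] * circ_lag(v, s)
  }
  out
}

#' Maximal overlap discrete wavelet transform
#'
#' Shift-invariant (undecimated) wavelet decomposition with per-level
#' rescaled filters, circular filtering. With `boundary = "reflection"` the
#' series is first extended to twice its length by reflection and the
#' coefficients are truncated back, which avoids wrap-around artifacts when
#' the two ends of a trace differ (e.g. under photobleaching).
#'
#' @param x numeric series, length at least `2^n_levels`.
#' @param wavelet `"sym4"` (default) or `"haar"`.
#' @param n_levels decomposition depth J (default 6).
#' @param boundary `"periodic"` or `"reflection"`.
#' @return object of class `modwt`: `W` (length-N x J matrix of wavelet
#'   coefficients), `V` (level-J scaling coefficients), plus the settings.
#' @export
modwt <- function(x, wavelet = "sym4", n_levels = 6,
                  boundary = c("periodic", "reflection")) {
  boundary <- match.arg(boundary)
  n <- length(x)
  assert_that(n >= 2^n_levels,
              sprintf("series too short for %d levels: need >= %d samples, got %d",
                      n_levels, 2^n_levels, n))
  xe <- if (boundary == "reflection") c(x, rev(x)) else x
  filt <- wavelet_filter(wavelet)
  gt <- filt$g / sqrt(2)
  ht <- filt$h / sqrt(2)
  W <- matrix(0, length(xe), n_levels)
  v <- xe
  for (j in seq_len(n_levels)) {
    W[, j] <- modwt_filter_step(v, ht, j)
    v <- modwt_filter_step(v, gt, j)
  }
  structure(list(W = W[seq_len(n), , drop = FALSE], V = v[seq_len(n)],
                 W_full = if (boundary == "reflection") W else NULL,
                 V_full = if (boundary == "reflection") v else NULL,
                 n = n, wavelet = wavelet, n_levels = n_levels,
                 boundary = boundary),
            class = "modwt")
}

#' Additive multiresolution analysis from a MODWT
#'
#' Reconstructs the zero-phase detail series `D1..DJ` and the smooth `SJ`;
#' their sum equals the input exactly (to float tolerance), which is the
#' transform's correctness certificate. Each detail `Dj` is the part of the
#' signal in the dyadic frequency band `[f_s / 2^(j+1), f_s / 2^j]`.
#'
#' @param x numeric series or a fitted [modwt] object.
#' @param ... passed on to [modwt()] when `x` is numeric.
#' @return N x (J + 1) matrix with columns `D1..DJ, S`.
#' @export
modwt_mra <- function(x, ...) {
  fit <- if (inherits(x, "modwt")) x else modwt(x, ...)
  filt <- wavelet_filter(fit$wavelet)
  gt <- filt$g / sqrt(2)
  ht <- filt$h / sqrt(2)
  J <- fit$n_levels
  W <- if (is.null(fit$W_full)) fit$W else fit$W_full
  Vj <- if (is.null(fit$V_full)) fit$V else fit$V_full
  nfull <- nrow(W)
  out <- matrix(0, fit$n, J + 1)
  colnames(out) <- c(paste0("D", seq_len(J)), "S")
  for (k in seq_len(J + 1)) {
    # invert with a single nonzero input: W_k (detail) or V_J (smooth)
    v <- if (k == J + 1) Vj else numeric(nfull)
    for (j in rev(seq_len(J))) {
      wj <- if (j == k) W[, j] else numeric(nfull)
      v <- modwt_filter_step(wj, ht, j, inverse = TRUE) +
           modwt_filter_step(v, gt, j, inverse = TRUE)
    }
    out[, k] <- v[seq_len(fit$n)]
  }
  out
}

#' Reconstruct the part of a signal carried by selected MODWT detail levels
#'
#' Equivalent to summing the corresponding columns of [modwt_mra()] but in a
#' single inverse pass (the inverse transform is linear in the
#' coefficients), which is what the event detector calls in its inner loop.
#'
#' @param x numeric series or a fitted [modwt] object.
#' @param levels detail levels to keep (e.g. `3:6`).
#' @param include_smooth also add the level-J smooth (default FALSE).
#' @param ... passed to [modwt()] when `x` is numeric.
#' @return numeric series of the same length as the input.
#' @export
modwt_reconstruct <- function(x, levels, include_smooth = FALSE, ...) {
  fit <- if (inherits(x, "modwt")) x else modwt(x, ...)
  filt <- wavelet_filter(fit$wavelet)
  gt <- filt$g / sqrt(2)
  ht <- filt$h / sqrt(2)
  J <- fit$n_levels
  assert_that(all(levels >= 1 & levels <= J), "levels must lie in 1..n_levels")
  W <- if (is.null(fit$W_full)) fit$W else fit$W_full
  Vj <- if (is.null(fit$V_full)) fit$V else fit$V_full
  nfull <- nrow(W)
  v <- if (include_smooth) Vj else numeric(nfull)
  for (j in rev(seq_len(J))) {
    wj <- if (j %in% levels) W[, j] else numeric(nfull)
    v <- modwt_filter_step(wj, ht, j, inverse = TRUE) +
         modwt_filter_step(v, gt, j, inverse = TRUE)
  }
  v[seq_len(fit$n)]
}

#' @export
print.modwt <- function(x, ...) {
  cat(sprintf("<modwt> %s, %d levels, %d samples, %s boundary\n",
              x$wavelet, x$n_levels, x$n, x$boundary))
  invisible(x)
}
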