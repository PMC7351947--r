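#' Derive a child seed from a base seed and an index path
#'
#' Expands one user-facing integer seed into independent per-component seeds by
#' walking a Lehmer-style hash over the index path. Every stochastic step in the
#' package draws its seed this way, so a whole simulation (or a whole sweep) is
#' a pure function of its base seed while replicates stay decorrelated.
#'
#' @param seed base integer seed.
#' @param ... integer indices identifying the component (e.g. grid cell,
#'   replicate, stage). Any number of levels.
#' @return an integer in `[1, 2^31 - 2]` suitable for [set.seed()].
#' @examples
#' seed_stream(1, 3, 7)
#' @export
seed_stream <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed) %% 2147483647
  if (s <= 0) s <- s + 2147483646
  for (k in c(0, idx)) {
    # 48271 * 2^31 < 2^53: exact in doubles
    s <- (s * 48271 + as.double(k) + 1) %% 2147483647
    if (s == 0) s <- 1
  }
  as.integer(s)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
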