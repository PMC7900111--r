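#' @keywords internal
"_PACKAGE"

`%||%` <- function(x, y) if (is.null(x)) y else x

utils::globalVariables(c("fpr", "lower", "upper"))

#' Derive a stream-specific RNG seed from a master seed
#'
#' Deterministic mixing of a master seed with an integer offset, kept within
#' the 32-bit integer range so it is always a valid `set.seed()` argument.
#'
#' @param seed Master seed (integer).
#' @param offset Non-negative integer identifying the stream (e.g. subject
#'   index).
#' @return An integer seed.
#' @export
derive_seed <- function(seed, offset) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.numeric(offset))
  as.integer((abs(as.numeric(seed)) * 1103 + 1000003 * as.numeric(offset) + 12345) %%
               (.Machine$integer.max - 1)) + 1L
}

## Separable Gaussian smoothing of a 3D array, replicated edges.
## Used only for the smooth tissue background of the phantom generator.
gaussian_smooth_3d <- function(x, sigma) {
  stopifnot(length(dim(x)) == 3)
  if (sigma <= 0) return(x)
  half <- max(1L, ceiling(3 * sigma))
  off <- seq(-half, half)
  w <- exp(-off^2 / (2 * sigma^2))
  w <- w / sum(w)
  for (axis in 1:3) {
    n <- dim(x)[axis]
    acc <- array(0, dim(x))
    for (j in seq_along(off)) {
      idx <- pmin(pmax(seq_len(n) + off[j], 1L), n)  # replicate edges
      acc <- acc + w[j] * switch(axis,
        x[idx, , , drop = FALSE],
        x[, idx, , drop = FALSE],
        x[, , idx, drop = FALSE])
    }
    x <- acc
  }
  x
}

## stop() with call.=FALSE everywhere for clean user-facing messages
abort <- function(...) stop(..., call. = FALSE)
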