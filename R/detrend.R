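#' Remove slow intensity components with a moving-frame average
#'
#' For heterogeneous samples (cells) the immobile fraction and cell
#' structure dominate the raw spatial correlation.  Detrending removes
#' them: each frame has the centered temporal moving average of `window`
#' frames subtracted, and the global stack mean is added back so the mean
#' intensity is preserved.  Boundary frames use a shrunken window clipped
#' to the stack.  `mode = "replace"` instead substitutes each frame by the
#' moving average itself (the smoothing reading); the default subtractive
#' mode is what correlation of fast fluctuations requires.
#'
#' @param stack An [image_stack()].
#' @param window Number of frames in the moving average (default 3).
#' @param mode `"subtract"` (default) or `"replace"`.
#' @return A detrended `image_stack` (floating values, mean preserved and
#'   shifted to keep all values non-negative is NOT applied; negative
#'   fluctuation values are retained internally as a plain array).
#' @export
detrend <- function(stack, window = 3L, mode = c("subtract", "replace")) {
  mode <- match.arg(mode)
  stopifnot(inherits(stack, "image_stack"))
  nf <- dim(stack$data)[1L]
  if (window < 2) stop("window must be >= 2")
  if (window > nf) stop("window exceeds the number of frames")
  d <- dim(stack$data)
  x <- matrix(stack$data, nf, d[2] * d[3])  # frames x pixels
  half_lo <- (window - 1L) %/% 2L
  half_hi <- window - 1L - half_lo
  # centered moving average with shrunken one-sided windows at the edges,
  # via cumulative sums over the frame axis
  cs <- rbind(0, apply(x, 2L, cumsum))
  lo <- pmax(seq_len(nf) - half_lo, 1L)
  hi <- pmin(seq_len(nf) + half_hi, nf)
  avg <- (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) / (hi - lo + 1L)
  # add back the mean of the trend itself: with shrunken edge windows
  # mean(avg) differs slightly from mean(x), and this choice preserves
  # the stack mean exactly
  out <- if (mode == "subtract") x - avg + mean(avg) else avg
  res <- stack
  res$data <- array(out, dim = d)
  res$detrended <- TRUE
  res
}
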