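# Negative Pearson correlation loss: the training objective aligning the
# recovered rPPG trace with the reference PPG, sensitive to waveform trend
# and peak timing but invariant to amplitude and offset.

#' Sample Pearson correlation of two traces
#'
#' The sample correlation coefficient of two equal-length series. Symmetric
#' in its arguments and invariant to positive affine rescaling of either
#' series. Constant (zero-variance) input is an error in this analysis-mode
#' function; the training loss uses an epsilon-guarded variant instead.
#'
#' @param x,y numeric vectors of equal length `T >= 2`.
#' @return correlation in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("traces must have equal length")
  if (length(x) < 2L) stop("need at least two samples")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("degenerate input: constant series has no defined correlation")
  }
  stats::cor(x, y)
}

#' Negative Pearson correlation loss
#'
#' `1 - r(x, y)`: zero iff the traces are perfectly correlated, two iff
#' perfectly anti-correlated. For a list of paired clips the loss is the
#' mean of the per-clip losses, making the objective independent of batch
#' size.
#'
#' @param x,y numeric vectors of equal length, or lists of such vectors
#'   (paired clips).
#' @return loss in `[0, 2]`.
#' @export
neg_pearson <- function(x, y) {
  if (is.list(x)) {
    if (!is.list(y) || length(x) != length(y)) {
      stop("clip lists must be paired")
    }
    return(mean(mapply(neg_pearson, x, y)))
  }
  1 - pearson_r(x, y)
}
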