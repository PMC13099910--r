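# RMA-style probe-set summarization: quantile normalization across arrays
# followed by median-polish summarization of each probe-set block. The
# convolution background-correction step of the full RMA recipe is omitted:
# inputs here are already log2-scale intensities.

#' Quantile-normalize a matrix across arrays (columns)
#'
#' After normalization every column carries the same multiset of values: the
#' across-array mean of the sorted columns. Ties within an array receive the
#' mean of the reference values over the tied rank span (dense-rank
#' convention).
#'
#' @param x numeric matrix, features x arrays, at least two arrays.
#' @return matrix of the same dimensions.
#' @export
quantile_normalize <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) stop("x must be a numeric matrix")
  if (ncol(x) < 2) stop("quantile normalization needs at least 2 arrays")
  if (nrow(x) < 1) stop("quantile normalization needs at least 1 feature")
  if (any(!is.finite(x))) stop("non-finite values in input")
  out <- limma::normalizeQuantiles(x, ties = TRUE)
  dimnames(out) <- dimnames(x)
  out
}

#' Median-polish summarization of a probe-level block
#'
#' Alternately sweeps row (probe) and column (array) medians out of the
#' residuals until the largest change is below `tol` or `max_iter` sweeps
#' have run, starting with rows. The per-array summary is the overall effect
#' plus the array (column) effect.
#'
#' @param block numeric matrix, probes x arrays.
#' @param max_iter sweep cap.
#' @param tol convergence tolerance on the total absolute residual change.
#' @return named numeric vector, one summary value per array.
#' @export
median_polish_summarize <- function(block, max_iter = 10, tol = 0.01) {
  if (!is.matrix(block) || !is.numeric(block))
    stop("block must be a numeric matrix")
  if (nrow(block) < 1 || ncol(block) < 1) stop("empty probe block")
  if (any(!is.finite(block))) stop("non-finite values in block")
  fit <- stats::medpolish(block, eps = tol, maxiter = max_iter,
                          trace.iter = FALSE, na.rm = FALSE)
  stats::setNames(fit$overall + fit$col, colnames(block))
}

#' Summarize a probe-level collection into a probe-set expression matrix
#'
#' Stacks all blocks, quantile-normalizes across arrays, then median-polishes
#' each probe-set block.
#'
#' @param probes probe collection (see [simulate_cohort()]).
#' @param normalize quantile-normalize across arrays first.
#' @param max_iter,tol passed to [median_polish_summarize()].
#' @return matrix, probe-sets x arrays.
#' @export
summarize_collection <- function(probes, normalize = TRUE, max_iter = 10,
                                 tol = 0.01) {
  blocks <- probes$blocks
  if (length(blocks) == 0) stop("empty probe collection")
  arrays <- colnames(blocks[[1]])
  sizes <- vapply(blocks, nrow, integer(1))
  if (normalize) {
    stacked <- do.call(rbind, blocks)
    stacked <- quantile_normalize(stacked)
    ends <- cumsum(sizes)
    starts <- ends - sizes + 1
    blocks <- lapply(seq_along(blocks), function(i)
      stacked[starts[i]:ends[i], , drop = FALSE])
    names(blocks) <- names(probes$blocks)
  }
  out <- t(vapply(blocks, median_polish_summarize, numeric(length(arrays)),
                  max_iter = max_iter, tol = tol))
  colnames(out) <- arrays
  out
}
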