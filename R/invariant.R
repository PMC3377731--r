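## Rank-invariant set normalization against a pseudo-reference array.

#' Rank-invariant set normalization
#'
#' Builds a reference pseudo-array (row-wise median across samples), finds
#' the set of miRNAs whose rank barely moves between samples (rank spread
#' below `rank_tolerance`, as a fraction of the row count) and, per sample,
#' maps all values through a loess curve fitted on (sample value, reference
#' value) over that invariant set. This assumes a subpopulation of expressed
#' miRNAs that does not change between conditions, which makes the method
#' appropriate even when a large fraction of miRNAs is differentially
#' expressed.
#'
#' @param m An `ExpressionMatrix` with >= 2 columns.
#' @param rank_tolerance Maximum allowed rank spread (max rank - min rank
#'   across samples, divided by the row count) for a miRNA to be called
#'   invariant (default 0.15).
#' @param bins Number of equal-count intensity bins of the reference the
#'   invariant set must span (>= 3 of them; default 10 bins).
#' @param span Loess span for the per-sample calibration curve (default 0.5).
#' @return A `NormalizedMatrix` (`method = "inv"`) carrying the
#'   `$invariant_set` (an object of class `"InvariantSet"` with member ids,
#'   per-row rank spreads and the reference pseudo-array).
#' @export
normalize_invariant <- function(m, rank_tolerance = 0.15, bins = 10L,
                                span = 0.5) {
  x <- m$values
  if (ncol(x) < 2L) stop("invariant normalization needs >= 2 columns",
                         call. = FALSE)
  n <- nrow(x)
  ref <- apply(x, 1, stats::median)
  ranks <- apply(x, 2, rank, ties.method = "average")
  spread <- (apply(ranks, 1, max) - apply(ranks, 1, min)) / n
  inv <- spread < rank_tolerance
  if (!any(inv))
    stop("invariant set is empty; increase rank_tolerance", call. = FALSE)
  br <- unique(stats::quantile(ref, seq(0, 1, length.out = bins + 1)))
  covered <- unique(cut(ref[inv], br, include.lowest = TRUE))
  if (length(covered) < 3L)
    stop("invariant set spans fewer than 3 intensity bins; increase ",
         "rank_tolerance", call. = FALSE)
  vals <- x
  for (j in seq_len(ncol(x))) {
    use <- inv & !m$flagged[, j]
    if (sum(use) < 5L) use <- inv
    fit <- stats::loess(r ~ v,
                        data = data.frame(v = x[use, j], r = ref[use]),
                        span = span, degree = 1, family = "symmetric",
                        surface = "direct")
    pred <- stats::predict(fit, newdata = data.frame(v = x[, j]))
    if (anyNA(pred)) {
      known <- !is.na(pred)
      pred[!known] <- stats::approx(x[known, j], pred[known],
                                    xout = x[!known, j], rule = 2,
                                    ties = mean)$y
    }
    vals[, j] <- pred
  }
  inv_set <- structure(
    list(members = rownames(x)[inv],
         rank_spread = stats::setNames(spread, rownames(x)),
         reference = stats::setNames(ref, rownames(x)),
         bins_covered = length(covered)),
    class = "InvariantSet"
  )
  new_normalized(m, vals, "inv",
                 parameters = list(rank_tolerance = rank_tolerance,
                                   bins = bins, span = span,
                                   n_invariant = sum(inv)),
                 extra = list(invariant_set = inv_set))
}

#' @export
print.InvariantSet <- function(x, ...) {
  cat(sprintf("InvariantSet: %d members spanning %d intensity bins\n",
              length(x$members), x$bins_covered))
  invisible(x)
}
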