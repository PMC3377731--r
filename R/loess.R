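## Cyclic loess normalization and its loessM variant for one-color data.

## Local-linear fit of M on A over the unflagged rows, evaluated for all
## rows; outside the fitted range the curve is extended flat.
fit_ma_trend <- function(M, A, ok, span, subset_size, family) {
  idx <- which(ok)
  ## rank-stratified subset: evenly spaced points along the A ordering
  if (length(idx) > subset_size) {
    ord <- idx[order(A[idx])]
    idx <- ord[unique(round(seq(1, length(ord), length.out = subset_size)))]
  }
  ## an (almost) constant M needs no smoother, and a zero-residual fit
  ## breaks the robust ("symmetric") iterations
  if (diff(range(M[idx])) < 1e-9) return(rep(stats::median(M[idx]),
                                             length(M)))
  fit <- stats::loess(M ~ A, data = data.frame(A = A[idx], M = M[idx]),
                      span = span, degree = 1, family = family,
                      surface = "direct")
  pred <- stats::predict(fit, newdata = data.frame(A = A))
  if (anyNA(pred)) {
    known <- !is.na(pred)
    pred[!known] <- stats::approx(A[known], pred[known], xout = A[!known],
                                  rule = 2, ties = mean)$y
  }
  pred
}

#' Cyclic (pairwise) loess normalization
#'
#' Removes smooth intensity-dependent differences between samples. For every
#' column pair (j, k) the difference `M = x_j - x_k` is regressed locally on
#' the average intensity `A = (x_j + x_k)/2`; half the fitted trend is
#' charged to each column. Corrections from all pairs are averaged and
#' applied once per cycle, and cycles repeat until the largest per-cell
#' adjustment drops below `tol` or `iterations` is reached. Flagged cells
#' are excluded from the smoother fits (but still corrected).
#'
#' @param m An `ExpressionMatrix` with >= 2 columns, each with >= 10
#'   distinct values.
#' @param span Loess span (default 2/3).
#' @param iterations Maximum number of full pairwise cycles (default 3).
#' @param subset_size Number of rank-stratified points each smoother is
#'   fitted on before interpolation (default 400).
#' @param tol Convergence tolerance on the largest per-cycle adjustment.
#' @param family Loess fitting family; `"symmetric"` (default) is robust to
#'   the differentially expressed minority.
#' @return A `NormalizedMatrix` (`method = "loess"`); the accumulated
#'   per-cell adjustment (input minus output) is stored in `$adjustments`.
#' @export
normalize_loess <- function(m, span = 2/3, iterations = 3L,
                            subset_size = 400L, tol = 1e-3,
                            family = c("symmetric", "gaussian")) {
  family <- match.arg(family)
  x <- m$values
  J <- ncol(x)
  if (J < 2L) stop("cyclic loess needs >= 2 columns", call. = FALSE)
  ndist <- apply(x, 2, function(v) length(unique(v)))
  if (any(ndist < 10L))
    stop("column(s) with fewer than 10 distinct values (smoother ",
         "underdetermined): ",
         paste(colnames(x)[ndist < 10L], collapse = ", "), call. = FALSE)
  fl <- m$flagged
  total <- matrix(0, nrow(x), J)
  iters_used <- 0L
  for (it in seq_len(iterations)) {
    corr <- matrix(0, nrow(x), J)
    for (j in seq_len(J - 1L)) {
      for (k in seq(j + 1L, J)) {
        Mv <- x[, j] - x[, k]
        Av <- (x[, j] + x[, k]) / 2
        ok <- !(fl[, j] | fl[, k])
        if (sum(ok) < 10L) ok <- rep(TRUE, length(ok))
        pred <- fit_ma_trend(Mv, Av, ok, span, subset_size, family)
        corr[, j] <- corr[, j] + pred / 2
        corr[, k] <- corr[, k] - pred / 2
      }
    }
    corr <- corr / (J - 1L)
    x <- x - corr
    total <- total + corr
    iters_used <- it
    if (max(abs(corr)) < tol) break
  }
  dimnames(total) <- dimnames(m$values)
  new_normalized(m, x, "loess",
                 parameters = list(span = span, iterations = iterations,
                                   iterations_used = iters_used,
                                   subset_size = subset_size, tol = tol,
                                   family = family),
                 extra = list(adjustments = total))
}

#' loessM normalization
#'
#' Cyclic loess followed by adding back a single global constant: the median
#' of the accumulated loess adjustment over all cells. The constant keeps
#' normalized values bounded away from zero and relaxes the symmetry
#' assumption on up-/down-regulation; because it is one additive shift,
#' every shift-invariant downstream statistic (standard deviations,
#' d-statistics, t-values, AUC, differential-expression lists) is identical
#' to plain cyclic loess.
#'
#' @inheritParams normalize_loess
#' @return A `NormalizedMatrix` (`method = "loessm"`); the constant is
#'   recorded as `$parameters$delta`.
#' @export
normalize_loessM <- function(m, span = 2/3, iterations = 3L,
                             subset_size = 400L, tol = 1e-3,
                             family = c("symmetric", "gaussian")) {
  base <- normalize_loess(m, span = span, iterations = iterations,
                          subset_size = subset_size, tol = tol,
                          family = family)
  delta <- stats::median(base$adjustments)
  out <- new_normalized(m, base$values + delta, "loessm",
                        parameters = c(base$parameters, list(delta = delta)),
                        extra = list(adjustments = base$adjustments))
  out
}
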