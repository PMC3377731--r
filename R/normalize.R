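## Scale/shift normalization methods and the common dispatcher.

## Wrap normalized values, preserving identifiers and metadata.
new_normalized <- function(m, values, method, parameters = list(),
                           offsets = NULL, extra = list()) {
  stopifnot(identical(dim(values), dim(m$values)))
  dimnames(values) <- dimnames(m$values)
  out <- m
  out$values <- values
  out$method <- method
  out$parameters <- parameters
  out$offsets <- offsets
  for (nm in names(extra)) out[[nm]] <- extra[[nm]]
  class(out) <- c("NormalizedMatrix", "ExpressionMatrix")
  out
}

#' @export
print.NormalizedMatrix <- function(x, ...) {
  cat(sprintf("NormalizedMatrix (method = %s)\n", x$method))
  NextMethod()
}

#' Identity (no) normalization
#'
#' @param m An `ExpressionMatrix`.
#' @return A `NormalizedMatrix` with `method = "none"` and values identical
#'   to the input.
#' @export
normalize_none <- function(m) {
  new_normalized(m, m$values, "none")
}

#' Reference gene index (RGI) normalization
#'
#' Subtracts, per sample, the arithmetic mean of two stably expressed
#' reference miRNAs, then adds back the grand mean of that reference index
#' so the output stays on the original scale. After normalization the
#' reference index is constant across samples. When `refs` is omitted the
#' pair is chosen by geNorm stepwise exclusion over all candidates that are
#' unflagged in every sample.
#'
#' @param m An `ExpressionMatrix` on a log-like scale.
#' @param refs Character vector of exactly two reference miRNA identifiers,
#'   or `NULL` to select them with [stability_genorm()].
#' @return A `NormalizedMatrix` (`method = "rgi"`); per-sample additive
#'   corrections are stored in `$offsets`.
#' @export
normalize_rgi <- function(m, refs = NULL) {
  if (is.null(refs)) {
    complete <- rownames(m$values)[rowSums(m$flagged) == 0]
    if (length(complete) < 3L)
      stop("too few fully detected miRNAs to select references",
           call. = FALSE)
    refs <- stability_genorm(m, complete)$final_pair
  }
  refs <- as.character(refs)
  if (length(refs) != 2L)
    stop("RGI needs exactly two reference miRNAs", call. = FALSE)
  miss <- setdiff(refs, rownames(m$values))
  if (length(miss))
    stop("reference miRNA(s) missing: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(m$flagged[refs, ]))
    stop("reference miRNA(s) flagged undetected in some sample",
         call. = FALSE)
  ref_j <- colMeans(m$values[refs, , drop = FALSE])
  c0 <- mean(ref_j)
  offsets <- c0 - ref_j
  vals <- sweep(m$values, 2, offsets, "+")
  new_normalized(m, vals, "rgi",
                 parameters = list(refs = refs, center = c0),
                 offsets = offsets)
}

#' Global (geometric) mean normalization
#'
#' On log scale the geometric mean of raw signals is the arithmetic column
#' mean, so every column is shifted to share the grand mean of all cells.
#'
#' @param m An `ExpressionMatrix` on a log-like scale.
#' @return A `NormalizedMatrix` (`method = "geomean"`); per-sample shifts in
#'   `$offsets`.
#' @export
normalize_geomean <- function(m) {
  g <- mean(m$values)
  offsets <- g - colMeans(m$values)
  vals <- sweep(m$values, 2, offsets, "+")
  new_normalized(m, vals, "geomean", parameters = list(grand_mean = g),
                 offsets = offsets)
}

#' Quantile normalization
#'
#' Classic order-statistic substitution: each column's sorted values are
#' replaced by the mean of the sorted values across columns, so all columns
#' share one empirical distribution afterwards. Ties receive the mean of
#' their rank positions (average ranks, interpolated in the mean-quantile
#' vector).
#'
#' @param m An `ExpressionMatrix` with >= 2 columns.
#' @return A `NormalizedMatrix` (`method = "quantile"`).
#' @export
normalize_quantile <- function(m) {
  x <- m$values
  if (ncol(x) < 2L) stop("quantile normalization needs >= 2 columns",
                         call. = FALSE)
  n <- nrow(x)
  mu <- rowMeans(apply(x, 2, sort))
  vals <- x
  for (j in seq_len(ncol(x))) {
    r <- rank(x[, j], ties.method = "average")
    vals[, j] <- if (n == 1L) mu else
      stats::approx(seq_len(n), mu, xout = r)$y
  }
  new_normalized(m, vals, "quantile")
}

#' Apply a normalization method by name
#'
#' Single entry point over the seven compared strategies plus the identity.
#' Method names follow the field's shorthand: `"rgi"`, `"geomean"`,
#' `"quantile"`, `"inv"` (rank-invariant selection), `"loess"` (cyclic
#' loess), `"loessm"` (cyclic loess plus a global median offset), `"gpa"`
#' (generalized Procrustes analysis over replicate groups) and `"none"`.
#'
#' @param m An `ExpressionMatrix`.
#' @param method One of the method names above.
#' @param design A `StudyDesign`; required for `"gpa"` and for automatic
#'   reference selection variants.
#' @param ... Passed to the specific `normalize_*` function.
#' @return A `NormalizedMatrix`.
#' @export
normalize_matrix <- function(m,
                             method = c("none", "rgi", "geomean", "quantile",
                                        "inv", "loess", "loessm", "gpa"),
                             design = NULL, ...) {
  method <- match.arg(method)
  switch(method,
         none = normalize_none(m),
         rgi = normalize_rgi(m, ...),
         geomean = normalize_geomean(m),
         quantile = normalize_quantile(m),
         inv = normalize_invariant(m, ...),
         loess = normalize_loess(m, ...),
         loessm = normalize_loessM(m, ...),
         gpa = {
           if (is.null(design))
             stop("GPA normalization needs a study design", call. = FALSE)
           normalize_gpa(m, design, ...)
         })
}
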