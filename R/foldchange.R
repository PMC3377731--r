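## Relative quantification: delta-delta (Livak) arithmetic and t-values.

#' Relative quantification between two groups
#'
#' Computes per-miRNA group means, their difference on the working scale
#' (delta-delta), the fold change and the pooled-variance two-sample
#' t-value. On a Cq matrix the Livak rule `FC = 2^(-ddCq)` applies; on a
#' log2/expression matrix `FC = 2^(ddlog2)`. Both agree exactly after
#' [to_expression_scale()] because that transform only flips orientation.
#' `log2fc` is always oriented "positive = up in the treated group".
#'
#' @param m A `NormalizedMatrix` or `ExpressionMatrix`.
#' @param design A `StudyDesign` covering the columns of `m`.
#' @param contrast Character pair `c(control, treated)`.
#' @return A data frame of class `"FoldChangeTable"` with columns `id`,
#'   `mean_control`, `mean_treated`, `ddelta` (working scale), `log2fc`,
#'   `fold_change`, `t`, and `t_undefined` flagging rows with zero variance
#'   in both groups. The working scale and contrast are kept as attributes.
#' @export
delta_delta <- function(m, design, contrast) {
  stopifnot(length(contrast) == 2L)
  d <- design_for(m, design)
  i1 <- which(d$group == contrast[1])
  i2 <- which(d$group == contrast[2])
  if (!length(i1) || !length(i2))
    stop("contrast group(s) absent from design", call. = FALSE)
  x <- m$values
  m1 <- rowMeans(x[, i1, drop = FALSE])
  m2 <- rowMeans(x[, i2, drop = FALSE])
  dd <- m2 - m1
  log2fc <- if (m$scale == "cq") -dd else dd
  n1 <- length(i1)
  n2 <- length(i2)
  v1 <- apply(x[, i1, drop = FALSE], 1, stats::var)
  v2 <- apply(x[, i2, drop = FALSE], 1, stats::var)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  undef <- se == 0
  tval <- ifelse(undef, NA_real_, dd / se)
  out <- data.frame(id = rownames(x),
                    mean_control = m1, mean_treated = m2,
                    ddelta = dd, log2fc = log2fc,
                    fold_change = 2^log2fc,
                    t = tval, t_undefined = undef,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "scale") <- m$scale
  attr(out, "contrast") <- contrast
  class(out) <- c("FoldChangeTable", "data.frame")
  out
}
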