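## Reference-gene stability scoring for the reference gene index (RGI).

#' geNorm stability scoring
#'
#' For each candidate j the geNorm measure is
#' `M_j = mean_k sd_samples(x_j - x_k)` over the other candidates k: a gene
#' whose log-expression tracks every other candidate up to a constant has
#' M = 0. Candidates are then removed stepwise (highest M first, M
#' recomputed on the shrinking panel) until two remain; that final pair is
#' the usual reference-gene choice.
#'
#' @param m An `ExpressionMatrix` (log2/expression scale).
#' @param candidates Character vector of candidate miRNA identifiers
#'   (>= 3) present in `m`.
#' @return A `"StabilityScores"` object with the full-panel `M` values,
#'   the stepwise `exclusion_order` (ending with the final pair) and
#'   `final_pair`.
#' @export
stability_genorm <- function(m, candidates) {
  candidates <- as.character(candidates)
  if (length(candidates) < 3L)
    stop("geNorm needs >= 3 candidates", call. = FALSE)
  miss <- setdiff(candidates, rownames(m$values))
  if (length(miss))
    stop("candidate(s) absent from matrix: ", paste(miss, collapse = ", "),
         call. = FALSE)
  x <- m$values[candidates, , drop = FALSE]
  if (ncol(x) < 2L) stop("geNorm needs >= 2 samples", call. = FALSE)
  ## sd(x_j - x_k) from the candidate covariance matrix:
  ## var(x_j - x_k) = v_j + v_k - 2 cov_jk
  cv <- stats::cov(t(x))
  v <- diag(cv)
  sdmat <- sqrt(pmax(outer(v, v, "+") - 2 * cv, 0))
  diag(sdmat) <- 0
  k <- length(candidates)
  M_full <- rowSums(sdmat) / (k - 1)
  names(M_full) <- candidates

  remain <- candidates
  S <- sdmat
  excluded <- character(0)
  while (length(remain) > 2L) {
    Mr <- rowSums(S) / (length(remain) - 1)
    worst <- which.max(Mr)
    excluded <- c(excluded, remain[worst])
    remain <- remain[-worst]
    S <- S[-worst, -worst, drop = FALSE]
  }
  ## final pair appended in order of decreasing full-panel M so the
  ## exclusion order is a complete permutation of the candidates
  pair_order <- remain[order(-M_full[remain])]
  structure(
    list(method = "genorm",
         M = M_full,
         exclusion_order = c(excluded, pair_order),
         final_pair = remain),
    class = "StabilityScores"
  )
}

#' NormFinder stability scoring
#'
#' Variance-decomposition model: sample effects are removed by subtracting
#' the per-sample mean over the candidate panel; for each gene the
#' group-specific deviation from its grand mean (inter-group bias) and the
#' within-group residual variance (intra-group variation) are estimated.
#' The bias is shrunk towards zero by its sampling variance and the
#' stability value combines absolute shrunken bias with the intra-group
#' standard error; lower = more stable.
#'
#' @param m An `ExpressionMatrix` (log2/expression scale).
#' @param design A `StudyDesign` covering the columns of `m`.
#' @param candidates Candidate miRNA identifiers present in `m`.
#' @return A `"StabilityScores"` object with per-gene `stability`,
#'   `intra_sd`, the inter-group bias matrix `bias`, and a `ranking`.
#' @export
stability_normfinder <- function(m, design, candidates) {
  candidates <- as.character(candidates)
  miss <- setdiff(candidates, rownames(m$values))
  if (length(miss))
    stop("candidate(s) absent from matrix: ", paste(miss, collapse = ", "),
         call. = FALSE)
  d <- design_for(m, design)
  x <- m$values[candidates, , drop = FALSE]
  groups <- unique(d$group)
  single_group <- length(groups) < 2L
  if (single_group)
    warning("single group: stability reduces to intra-group variance only")
  ## remove sample effects with the candidate-panel column means
  z <- sweep(x, 2, colMeans(x))
  mu <- rowMeans(z)
  k <- length(candidates)
  bias <- matrix(0, k, length(groups),
                 dimnames = list(candidates, groups))
  s2 <- matrix(0, k, length(groups), dimnames = list(candidates, groups))
  n_g <- stats::setNames(integer(length(groups)), groups)
  for (g in groups) {
    cols <- which(d$group == g)
    n_g[g] <- length(cols)
    zg <- z[, cols, drop = FALSE]
    bias[, g] <- rowMeans(zg) - mu
    s2[, g] <- apply(zg, 1, stats::var)
  }
  samp_var <- sweep(s2, 2, n_g, "/")     # sampling variance of the bias
  if (single_group) {
    stab <- sqrt(samp_var[, 1])
  } else {
    ## shrink the bias: gamma^2 = between-gene variance of the bias in
    ## excess of its average sampling variance (0 if none)
    gamma2 <- pmax(apply(bias, 2, stats::var) - colMeans(samp_var), 0)
    G2 <- matrix(gamma2, nrow = k, ncol = length(groups), byrow = TRUE)
    shrink <- ifelse(G2 == 0, 0, G2 / (G2 + samp_var))
    bias_sh <- bias * shrink
    stab <- rowMeans(abs(bias_sh) + sqrt(samp_var))
  }
  names(stab) <- candidates
  structure(
    list(method = "normfinder",
         stability = stab,
         intra_sd = sqrt(rowMeans(s2)),
         bias = bias,
         ranking = candidates[order(stab)]),
    class = "StabilityScores"
  )
}

#' @export
print.StabilityScores <- function(x, ...) {
  cat("StabilityScores (", x$method, ")\n", sep = "")
  if (x$method == "genorm") {
    cat("  final pair:", paste(x$final_pair, collapse = ", "), "\n")
    print(round(sort(x$M), 4))
  } else {
    print(round(sort(x$stability), 4))
  }
  invisible(x)
}
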