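## Evaluation metrics: inter-replicate SD, ROC/AUC, Jaccard concordance,
## fold-change compression regressions and symmetry statistics.

#' Mean inter-replicate standard deviation per group
#'
#' For each biological group the sample standard deviation (n - 1) across
#' replicates is computed per miRNA and averaged over miRNAs — the paper's
#' table-level measure of residual technical variation. Results from
#' several matrices (e.g. both species) can be pooled with
#' [combine_variability()].
#'
#' @param m A `NormalizedMatrix` or `ExpressionMatrix`.
#' @param design A `StudyDesign` covering the columns of `m`.
#' @return A `"VariabilitySummary"`: `$cells` (one row per group with the
#'   mean per-miRNA SD), plus the overall `$mean` and `$sd` across cells.
#' @export
inter_replicate_sd <- function(m, design) {
  d <- design_for(m, design)
  groups <- unique(d$group)
  cells <- do.call(rbind, lapply(groups, function(g) {
    cols <- which(d$group == g)
    sds <- apply(m$values[, cols, drop = FALSE], 1, stats::sd)
    data.frame(group = g, species = m$species, platform = m$platform,
               method = if (!is.null(m$method)) m$method else "none",
               n_mirnas = nrow(m$values), mean_sd = mean(sds),
               stringsAsFactors = FALSE)
  }))
  structure(list(cells = cells,
                 mean = mean(cells$mean_sd),
                 sd = stats::sd(cells$mean_sd)),
            class = "VariabilitySummary")
}

#' Pool variability summaries across matrices
#'
#' @param ... `"VariabilitySummary"` objects (or one list of them).
#' @return A `"VariabilitySummary"` over the concatenated cells; the overall
#'   mean is the arithmetic mean of the group-level means.
#' @export
combine_variability <- function(...) {
  args <- list(...)
  if (length(args) == 1L && !inherits(args[[1]], "VariabilitySummary"))
    args <- args[[1]]
  cells <- do.call(rbind, lapply(args, `[[`, "cells"))
  structure(list(cells = cells,
                 mean = mean(cells$mean_sd),
                 sd = stats::sd(cells$mean_sd)),
            class = "VariabilitySummary")
}

#' @export
print.VariabilitySummary <- function(x, ...) {
  cat(sprintf("VariabilitySummary: mean %.3f +/- %.3f over %d cells\n",
              x$mean, x$sd, nrow(x$cells)))
  invisible(x)
}

#' ROC curve and AUC by the rank (Mann-Whitney) estimator
#'
#' The AUC is the probability that a randomly chosen true positive scores
#' above a randomly chosen true negative, with ties counted 1/2 — computed
#' from average ranks. The curve is built by thresholding scores in
#' descending order (tied scores move together).
#'
#' @param scores Numeric vector of per-miRNA scores (e.g. `abs(d)` from
#'   SAM).
#' @param truth Logical vector: `TRUE` for truly differential miRNAs.
#' @return A `"RocResult"` with `$auc`, `$curve` (data frame of `fpr`,
#'   `tpr`), and the class counts.
#' @export
roc_auc <- function(scores, truth) {
  stopifnot(length(scores) == length(truth))
  truth <- as.logical(truth)
  n_pos <- sum(truth)
  n_neg <- sum(!truth)
  if (n_pos == 0L || n_neg == 0L)
    stop("both classes must be non-empty", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[truth]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  ord <- order(scores, decreasing = TRUE)
  sc <- scores[ord]
  tr <- truth[ord]
  grp_last <- !duplicated(sc, fromLast = TRUE)  # last index of each tie group
  tpr <- cumsum(tr)[grp_last] / n_pos
  fpr <- cumsum(!tr)[grp_last] / n_neg
  curve <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
  structure(list(auc = auc, curve = curve, n_pos = n_pos, n_neg = n_neg),
            class = "RocResult")
}

#' @export
print.RocResult <- function(x, ...) {
  cat(sprintf("RocResult: AUC = %.3f (%d positive / %d negative)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' Jaccard index of two identifier sets
#'
#' `|A n B| / |A u B|`. Two empty sets are defined to have index 1 (flagged
#' via `attr(, "both_empty")`) so averages over contrasts stay defined.
#'
#' @param a,b Character vectors (treated as sets).
#' @return A number in `[0, 1]`.
#' @export
jaccard_index <- function(a, b) {
  a <- unique(as.character(a))
  b <- unique(as.character(b))
  u <- length(union(a, b))
  if (u == 0L) {
    out <- 1
    attr(out, "both_empty") <- TRUE
    return(out)
  }
  length(intersect(a, b)) / u
}

#' Concordance matrix of differential-expression lists
#'
#' Builds pairwise Jaccard matrices over normalization methods, averaged
#' over the contrast x species cells. In `"intra"` mode all lists must come
#' from one platform and the result is the method x method matrix; in
#' `"inter"` mode lists from two platforms form a method-on-platform-1 x
#' method-on-platform-2 grid. Mean intersection and union sizes are kept
#' alongside.
#'
#' @param de_lists A list of records, each a list with elements `method`,
#'   `platform`, `contrast` (a string tag), `species`, and `ids` (character
#'   vector of significant miRNAs).
#' @param mode `"intra"` or `"inter"`.
#' @return A `"ConcordanceMatrix"` with `$jaccard`, `$n_intersection`,
#'   `$n_union` matrices, `$mode` and `$platforms`.
#' @export
concordance_table <- function(de_lists, mode = c("intra", "inter")) {
  mode <- match.arg(mode)
  if (length(de_lists) < 2L) stop("need >= 2 lists", call. = FALSE)
  meta <- data.frame(
    method = vapply(de_lists, `[[`, "", "method"),
    platform = vapply(de_lists, `[[`, "", "platform"),
    contrast = vapply(de_lists, `[[`, "", "contrast"),
    species = vapply(de_lists, `[[`, "", "species"),
    stringsAsFactors = FALSE)
  combos <- unique(paste(meta$contrast, meta$species, sep = "|"))
  key <- paste(meta$contrast, meta$species, sep = "|")

  grab <- function(platform, method, combo) {
    i <- which(meta$platform == platform & meta$method == method &
                 key == combo)
    if (length(i) != 1L)
      stop("mismatched contrast coverage: ", method, " on ", platform,
           " misses ", combo, call. = FALSE)
    de_lists[[i]]$ids
  }
  pair_stats <- function(p1, m1, p2, m2) {
    js <- is <- us <- numeric(length(combos))
    for (ci in seq_along(combos)) {
      A <- grab(p1, m1, combos[ci])
      B <- grab(p2, m2, combos[ci])
      js[ci] <- as.numeric(jaccard_index(A, B))
      is[ci] <- length(intersect(unique(A), unique(B)))
      us[ci] <- length(union(unique(A), unique(B)))
    }
    c(j = mean(js), i = mean(is), u = mean(us))
  }

  if (mode == "intra") {
    platforms <- unique(meta$platform)
    if (length(platforms) != 1L)
      stop("intra mode expects lists from a single platform", call. = FALSE)
    methods <- unique(meta$method)
    row_p <- col_p <- platforms
    row_m <- col_m <- methods
  } else {
    platforms <- unique(meta$platform)
    if (length(platforms) != 2L)
      stop("inter mode expects lists from exactly two platforms",
           call. = FALSE)
    row_p <- platforms[1]
    col_p <- platforms[2]
    row_m <- unique(meta$method[meta$platform == row_p])
    col_m <- unique(meta$method[meta$platform == col_p])
  }
  J <- N <- U <- matrix(NA_real_, length(row_m), length(col_m),
                        dimnames = list(row_m, col_m))
  for (a in seq_along(row_m)) {
    for (b in seq_along(col_m)) {
      st <- pair_stats(row_p, row_m[a], col_p, col_m[b])
      J[a, b] <- st["j"]
      N[a, b] <- st["i"]
      U[a, b] <- st["u"]
    }
  }
  structure(list(jaccard = J, n_intersection = N, n_union = U,
                 mode = mode, platforms = platforms, combos = combos),
            class = "ConcordanceMatrix")
}

#' @export
print.ConcordanceMatrix <- function(x, ...) {
  cat(sprintf("ConcordanceMatrix (%s, platforms: %s; %d contrast cells)\n",
              x$mode, paste(x$platforms, collapse = " vs "),
              length(x$combos)))
  print(round(x$jaccard, 3))
  invisible(x)
}

#' Cross-platform fold-change compression regression
#'
#' Ordinary least squares of platform A's log2 fold changes on platform B's
#' over the common miRNA subset; a slope below 1 indicates fold-change
#' compression on platform A. The analogous regression of t-values is
#' returned alongside, plus 95% confidence and prediction bands over the
#' fitted range.
#'
#' @param fc_a,fc_b `"FoldChangeTable"` objects sharing >= 3 miRNA ids.
#' @return A list with `slope`, `intercept`, `slope_t`, `intercept_t`, `n`,
#'   the fitted `model` and `model_t`, and a `bands` data frame.
#' @export
regress_platform_fc <- function(fc_a, fc_b) {
  ids <- intersect(fc_a$id, fc_b$id)
  if (length(ids) < 3L)
    stop("fewer than 3 common miRNAs", call. = FALSE)
  a <- fc_a[match(ids, fc_a$id), ]
  b <- fc_b[match(ids, fc_b$id), ]
  fit <- stats::lm(y ~ x, data = data.frame(x = b$log2fc, y = a$log2fc))
  co <- stats::coef(fit)
  ok_t <- !(a$t_undefined | b$t_undefined)
  fit_t <- if (sum(ok_t) >= 3L)
    stats::lm(y ~ x, data = data.frame(x = b$t[ok_t], y = a$t[ok_t]))
  else NULL
  grid <- data.frame(x = seq(min(b$log2fc), max(b$log2fc),
                             length.out = 50L))
  cb <- stats::predict(fit, grid, interval = "confidence")
  pb <- stats::predict(fit, grid, interval = "prediction")
  bands <- data.frame(x = grid$x, fit = cb[, "fit"],
                      conf_lo = cb[, "lwr"], conf_hi = cb[, "upr"],
                      pred_lo = pb[, "lwr"], pred_hi = pb[, "upr"])
  list(slope = unname(co[2]), intercept = unname(co[1]),
       compressed = unname(co[2]) < 1,
       slope_t = if (!is.null(fit_t)) unname(stats::coef(fit_t)[2])
       else NA_real_,
       intercept_t = if (!is.null(fit_t)) unname(stats::coef(fit_t)[1])
       else NA_real_,
       n = length(ids), model = fit, model_t = fit_t, bands = bands)
}

#' Symmetry statistics of regulations
#'
#' Mean and standard deviation of the per-miRNA delta-delta values on the
#' working scale — the paper's check that up- and down-regulation are
#' roughly balanced (a prerequisite for quantile and plain loess).
#'
#' @param fc A `"FoldChangeTable"`.
#' @return A list with `mean`, `sd` and `n`.
#' @export
symmetry_stats <- function(fc) {
  if (nrow(fc) == 0L) stop("empty fold-change table", call. = FALSE)
  list(mean = mean(fc$ddelta),
       sd = if (nrow(fc) > 1L) stats::sd(fc$ddelta) else 0,
       n = nrow(fc))
}
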