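## Significance analysis of microarrays (SAM), two-class unpaired.

## Per-row numerator (mean2 - mean1) and pooled standard error given column
## index sets for the two groups.
sam_stats <- function(x, i1, i2) {
  n1 <- length(i1)
  n2 <- length(i2)
  m1 <- rowMeans(x[, i1, drop = FALSE])
  m2 <- rowMeans(x[, i2, drop = FALSE])
  ss1 <- rowSums((x[, i1, drop = FALSE] - m1)^2)
  ss2 <- rowSums((x[, i2, drop = FALSE] - m2)^2)
  s <- sqrt((1 / n1 + 1 / n2) * (ss1 + ss2) / (n1 + n2 - 2))
  list(num = m2 - m1, s = s)
}

#' Choose the SAM fudge factor s0
#'
#' Tusher-style selection: candidate values are percentiles of the scatter
#' vector `s` (0, 5, ..., 100). For each candidate the d-statistics are
#' recomputed and the median absolute d is taken within windows defined by
#' percentile bins of `s`; the candidate minimizing the coefficient of
#' variation of those window medians (i.e. making the spread of d
#' independent of expression level) is chosen. Ties resolve to the smallest
#' candidate.
#'
#' @param s Per-miRNA pooled scatter values (>= 20 of them).
#' @param d_num Per-miRNA numerators (mean difference).
#' @param probs Candidate percentile grid (default every 5%).
#' @param n_windows Number of scatter-percentile windows (default 10).
#' @return The selected s0 (a single non-negative number).
#' @export
choose_s0 <- function(s, d_num, probs = seq(0, 1, by = 0.05),
                      n_windows = 10L) {
  if (length(s) < 20L) stop("s0 selection needs >= 20 miRNAs", call. = FALSE)
  if (diff(range(s)) < .Machine$double.eps^0.5) {
    warning("all scatter values are equal; s0 not identifiable")
    return(unname(min(s)))
  }
  candidates <- unname(stats::quantile(s, probs))
  br <- unique(stats::quantile(s, seq(0, 1, length.out = n_windows + 1)))
  win <- cut(s, br, include.lowest = TRUE)
  cv <- vapply(candidates, function(a) {
    dd <- abs(d_num / (s + a))
    med <- tapply(dd, win, stats::median)
    mu <- mean(med)
    if (!is.finite(mu) || mu == 0) return(Inf)
    stats::sd(med) / mu
  }, numeric(1))
  cv[!is.finite(cv)] <- Inf
  candidates[which.min(cv)]
}

#' Two-class SAM with permutation null
#'
#' For each miRNA the moderated statistic `d = (mean2 - mean1) / (s + s0)`
#' is computed with `s` the pooled standard error and `s0` the fudge factor
#' from [choose_s0()]. The null distribution comes from permuting the group
#' labels: when at most `n_perm` distinct assignments exist (20 for the 3v3
#' design) all of them are enumerated, otherwise `n_perm` seeded draws are
#' taken. The expected order statistics `d_E` are the per-rank means over
#' permutations; genes whose ordered d deviates from its expectation by more
#' than a threshold Delta are called, and the false discovery rate at Delta
#' is the median permutation call count divided by the observed call count.
#'
#' @param m A `NormalizedMatrix` or `ExpressionMatrix`.
#' @param design A `StudyDesign` covering the columns of `m`.
#' @param contrast Character pair `c(control, treated)`; d > 0 means higher
#'   in the second (treated) group.
#' @param n_perm Maximum number of permutations (default 1000; the 3v3
#'   design enumerates its 20 exactly).
#' @param seed Seed for permutation draws (ignored when enumerating).
#' @param fdr_target FDR level at which the significant set stored in the
#'   result is selected (default 0.05).
#' @param s0 Optional fixed fudge factor (bypasses [choose_s0()]).
#' @return A `"SamResult"`: per-miRNA `d` and `s`, global `s0`, the expected
#'   order statistics `d_expected`, the sorted permutation statistics, the
#'   chosen `delta`, estimated `fdr`, and the `significant` id set with
#'   `direction`.
#' @export
sam_two_class <- function(m, design, contrast, n_perm = 1000L, seed = 1L,
                          fdr_target = 0.05, s0 = NULL) {
  stopifnot(length(contrast) == 2L)
  d <- design_for(m, design)
  i1 <- which(d$group == contrast[1])
  i2 <- which(d$group == contrast[2])
  if (length(i1) < 2L || length(i2) < 2L)
    stop("both contrast groups need >= 2 replicates", call. = FALSE)
  x <- m$values[, c(i1, i2), drop = FALSE]
  n1 <- length(i1)
  n <- n1 + length(i2)
  j1 <- seq_len(n1)
  j2 <- seq(n1 + 1L, n)

  obs <- sam_stats(x, j1, j2)
  if (is.null(s0)) s0 <- choose_s0(obs$s, obs$num)
  d_obs <- obs$num / (obs$s + s0)
  names(d_obs) <- rownames(x)

  n_distinct <- choose(n, n1)
  if (n_distinct < 2L) stop("fewer than 2 distinct permutations",
                            call. = FALSE)
  if (n_distinct <= n_perm) {
    asn <- utils::combn(n, n1)
  } else {
    asn <- local({
      set.seed(seed)
      replicate(n_perm, sort(sample.int(n, n1)))
    })
  }
  B <- ncol(asn)
  d_perm_sorted <- matrix(0, nrow(x), B)
  all_idx <- seq_len(n)
  for (b in seq_len(B)) {
    g1 <- asn[, b]
    st <- sam_stats(x, g1, setdiff(all_idx, g1))
    d_perm_sorted[, b] <- sort(st$num / (st$s + s0))
  }
  d_expected <- rowMeans(d_perm_sorted)

  res <- structure(
    list(d = d_obs, s = stats::setNames(obs$s, rownames(x)), s0 = s0,
         d_expected = d_expected, d_perm_sorted = d_perm_sorted,
         n_perm = B, enumerated = n_distinct <= n_perm,
         contrast = contrast, fdr_target = fdr_target,
         delta = NA_real_, fdr = NA_real_,
         significant = character(0), direction = character(0)),
    class = "SamResult"
  )
  sig <- select_significant(res, fdr_target)
  res$delta <- attr(sig, "delta")
  res$fdr <- attr(sig, "fdr")
  res$significant <- as.character(sig)
  res$direction <- attr(sig, "direction")
  res
}

## Calls and FDR estimate at a given Delta under the ordered-statistic rule.
sam_calls_at <- function(r, delta) {
  ord <- order(r$d)
  ds <- r$d[ord]
  diff <- ds - r$d_expected
  up <- diff > delta
  down <- diff < -delta
  called <- up | down
  ids <- names(ds)[called]
  dirs <- ifelse(ds[called] > 0, "up", "down")
  if (!any(called)) {
    return(list(ids = character(0), direction = character(0), fdr = 0))
  }
  cut_up <- if (any(up)) min(ds[up]) else Inf
  cut_lo <- if (any(down)) max(ds[down]) else -Inf
  false_b <- colSums(r$d_perm_sorted >= cut_up) +
    colSums(r$d_perm_sorted <= cut_lo)
  fdr <- min(1, stats::median(false_b) / sum(called))
  list(ids = ids, direction = stats::setNames(dirs, ids), fdr = fdr)
}

#' Select the significant set at a target FDR
#'
#' Scans candidate thresholds Delta (just below each observed deviation of
#' the ordered d from its permutation expectation) and returns the calls at
#' the smallest Delta whose estimated FDR is at or below `fdr_target`. If no
#' threshold achieves the target an empty set is returned with a diagnostic
#' attribute.
#'
#' @param r A `"SamResult"`.
#' @param fdr_target FDR level in (0, 1].
#' @return Character vector of significant miRNA ids with attributes
#'   `direction` (named "up"/"down"), `delta`, and `fdr`.
#' @export
select_significant <- function(r, fdr_target = 0.05) {
  stopifnot(inherits(r, "SamResult"),
            fdr_target > 0, fdr_target <= 1)
  ord <- order(r$d)
  dev <- abs(r$d[ord] - r$d_expected)
  cand <- sort(unique(dev))
  cand <- cand[cand > 0]
  deltas <- cand - max(1e-12, min(cand) * 1e-9)
  for (delta in deltas) {
    at <- sam_calls_at(r, delta)
    if (at$fdr <= fdr_target) {
      out <- at$ids
      attr(out, "direction") <- at$direction
      attr(out, "delta") <- delta
      attr(out, "fdr") <- at$fdr
      return(out)
    }
  }
  out <- character(0)
  attr(out, "direction") <- character(0)
  attr(out, "delta") <- if (length(cand)) max(cand) else Inf
  attr(out, "fdr") <- 0
  attr(out, "diagnostic") <- "no threshold achieved the FDR target"
  out
}

#' @export
print.SamResult <- function(x, ...) {
  cat(sprintf(
    "SamResult: %s vs %s, %d miRNAs, %d permutations%s, s0 = %.4g\n",
    x$contrast[2], x$contrast[1], length(x$d), x$n_perm,
    if (x$enumerated) " (all enumerated)" else "", x$s0))
  cat(sprintf("  Delta = %.4g, est. FDR = %.3f, %d significant (%d up)\n",
              x$delta, x$fdr, length(x$significant),
              sum(x$direction == "up")))
  invisible(x)
}
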