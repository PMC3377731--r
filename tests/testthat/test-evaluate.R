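# Evaluation metrics: SD summaries, ROC/AUC, Jaccard, regressions, symmetry.

test_that("inter-replicate SD reproduces direct nested-loop recomputation", {
  d <- mk_design(groups = "MB", reps = 3, samples = c("s01", "s02", "s03"))
  m <- mk_matrix(rbind(c(1, 2, 3), c(2, 2, 2)), samples = d$sample)
  vs <- inter_replicate_sd(m, d)
  expect_equal(vs$cells$mean_sd, mean(c(1, 0)))  # per-miRNA SDs {1, 0}

  # identical replicates -> all zero
  m0 <- mk_matrix(matrix(rep(c(5, 7), 3), 2), samples = d$sample)
  expect_equal(inter_replicate_sd(m0, d)$cells$mean_sd, 0)

  # 50 x 9 seeded fixture against a brute-force oracle
  m9 <- rand_matrix(n = 50, seed = 14)
  d9 <- mk_design()
  vs9 <- inter_replicate_sd(m9, d9)
  for (g in unique(d9$group)) {
    cols <- which(d9$group == g)
    sds <- numeric(50)
    for (i in 1:50) sds[i] <- sd(m9$values[i, cols])
    expect_equal(vs9$cells$mean_sd[vs9$cells$group == g], mean(sds),
                 tolerance = 1e-12)
  }
  expect_equal(vs9$mean, mean(vs9$cells$mean_sd))
})

test_that("AUC equals the O(n^2) pair-counting oracle, including ties", {
  auc_oracle <- function(scores, truth) {
    pos <- scores[truth]; neg <- scores[!truth]
    tot <- 0
    for (p in pos) for (q in neg)
      tot <- tot + (p > q) + 0.5 * (p == q)
    tot / (length(pos) * length(neg))
  }
  for (seed in 1:6) {
    set.seed(seed)
    n <- 40
    scores <- sample(round(rnorm(n, 0, 2), 1))  # rounded -> ties occur
    truth <- runif(n) < 0.3
    if (!any(truth) || all(truth)) next
    expect_equal(roc_auc(scores, truth)$auc, auc_oracle(scores, truth),
                 tolerance = 1e-12)
  }
})

test_that("AUC endpoints and complements behave as expected", {
  truth <- c(rep(TRUE, 5), rep(FALSE, 5))
  expect_equal(roc_auc(10:1, truth)$auc, 1)          # perfect separation
  expect_equal(roc_auc(rep(1, 10), truth)$auc, 0.5)  # all ties
  set.seed(30)
  sc <- rnorm(10)
  expect_equal(roc_auc(sc, truth)$auc + roc_auc(-sc, truth)$auc, 1,
               tolerance = 1e-12)
  expect_error(roc_auc(sc, rep(TRUE, 10)), "non-empty")
  # curve is monotone in both coordinates
  cv <- roc_auc(sc, truth)$curve
  expect_true(all(diff(cv$fpr) >= 0) && all(diff(cv$tpr) >= 0))
})

test_that("AUC agrees with pROC on a random fixture", {
  set.seed(31)
  scores <- rnorm(100)
  truth <- runif(100) < 0.4
  expect_equal(roc_auc(scores, truth)$auc,
               as.numeric(pROC::auc(pROC::roc(truth, scores,
                                              quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-10)
})

test_that("Jaccard index satisfies its set identities", {
  expect_equal(jaccard_index(c("a", "b", "c"), c("b", "c", "d")), 0.5)
  expect_equal(jaccard_index(c("a", "b"), c("a", "b")), 1)
  expect_equal(jaccard_index(c("a"), c("b")), 0)
  j <- jaccard_index(character(0), character(0))
  expect_equal(as.numeric(j), 1)
  expect_true(attr(j, "both_empty"))
  # symmetry
  set.seed(32)
  A <- sample(letters, 10); B <- sample(letters, 8)
  expect_equal(jaccard_index(A, B), jaccard_index(B, A))
})

test_that("concordance tables average Jaccard over contrast cells", {
  mk <- function(method, platform, contrast, ids)
    list(method = method, platform = platform, contrast = contrast,
         species = "human", ids = ids)
  lists <- list(
    mk("m1", "array", "c1", c("a", "b")),
    mk("m1", "array", "c2", c("a")),
    mk("m2", "array", "c1", c("a", "b")),   # J = 1 on c1
    mk("m2", "array", "c2", c("x")))        # J = 0 on c2
  ct <- concordance_table(lists, mode = "intra")
  expect_equal(ct$jaccard["m1", "m2"], 0.5)
  expect_equal(ct$jaccard["m1", "m1"], 1)
  expect_equal(ct$jaccard, t(ct$jaccard))

  # mismatched coverage is refused
  expect_error(concordance_table(lists[1:3], mode = "intra"), "coverage")

  # inter mode: method-on-A x method-on-B grid
  lists2 <- c(lists, list(
    mk("m1", "qpcr", "c1", c("a")), mk("m1", "qpcr", "c2", c("a"))))
  ci <- concordance_table(lists2, mode = "inter")
  expect_identical(dim(ci$jaccard), c(2L, 1L))
  expect_equal(ci$jaccard["m1", "m1"], mean(c(1 / 2, 1)))
})

test_that("fold-change regression recovers exact linear relations", {
  set.seed(33)
  mkfc <- function(l2fc, ids = sprintf("mir-%03d", seq_along(l2fc))) {
    out <- data.frame(id = ids, mean_control = 0, mean_treated = l2fc,
                      ddelta = l2fc, log2fc = l2fc,
                      fold_change = 2^l2fc, t = l2fc * 2,
                      t_undefined = FALSE, stringsAsFactors = FALSE)
    class(out) <- c("FoldChangeTable", "data.frame")
    out
  }
  fc <- rnorm(50, 0, 1.5)
  r1 <- regress_platform_fc(mkfc(fc), mkfc(fc))
  expect_equal(r1$slope, 1, tolerance = 1e-10)
  expect_equal(r1$intercept, 0, tolerance = 1e-10)
  r2 <- regress_platform_fc(mkfc(0.5 * fc), mkfc(fc))
  expect_equal(r2$slope, 0.5, tolerance = 1e-10)
  expect_true(r2$compressed)
  expect_error(regress_platform_fc(mkfc(fc[1:2]), mkfc(fc[1:2])), "3")
  expect_named(r1$bands,
               c("x", "fit", "conf_lo", "conf_hi", "pred_lo", "pred_hi"))
})

test_that("symmetry statistics match direct mean/SD recomputation", {
  mkfc <- function(dd) {
    out <- data.frame(id = sprintf("m%d", seq_along(dd)), mean_control = 0,
                      mean_treated = dd, ddelta = dd, log2fc = dd,
                      fold_change = 2^dd, t = NA, t_undefined = TRUE,
                      stringsAsFactors = FALSE)
    class(out) <- c("FoldChangeTable", "data.frame")
    out
  }
  expect_equal(symmetry_stats(mkfc(c(1, -1)))$mean, 0)
  z <- symmetry_stats(mkfc(rep(0, 5)))
  expect_equal(z$mean, 0)
  expect_equal(z$sd, 0)
  set.seed(34)
  dd <- rnorm(30, 0.1, 0.3)
  s <- symmetry_stats(mkfc(dd))
  expect_equal(s$mean, mean(dd))
  expect_equal(s$sd, sd(dd))
})
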