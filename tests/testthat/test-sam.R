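# SAM two-class permutation test, s0 selection and significance selection.

sam_fixture <- function(n = 60, seed = 1, effect_rows = integer(0),
                        effect = 2, noise = 0.5) {
  set.seed(seed)
  x <- matrix(rnorm(n * 6, 10, noise), n, 6)
  x[effect_rows, 4:6] <- x[effect_rows, 4:6] + effect
  m <- mk_matrix(x, samples = sprintf("s%02d", 1:6))
  d <- mk_design(groups = c("MB", "MT"), reps = 3,
                 samples = colnames(x <- m$values))
  list(m = m, d = d)
}

test_that("the d statistic matches the hand-computed two-sample formula", {
  x <- rbind(c(1, 2, 3, 4, 5, 6))
  x <- x[rep(1, 25), ]  # >= 20 rows for s0 selection; use fixed s0 = 0
  m <- mk_matrix(x, samples = sprintf("s%02d", 1:6))
  d <- mk_design(groups = c("MB", "MT"), reps = 3,
                 samples = colnames(m$values))
  r <- sam_two_class(m, d, c("MB", "MT"), s0 = 0)
  # pooled se: sp = 1, se = sqrt(2/3); d = 3 / se
  expect_equal(unname(r$d[1]), 3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(unname(r$s[1]), sqrt(2 / 3), tolerance = 1e-12)
})

test_that("all 20 label permutations are enumerated for the 3v3 design", {
  f <- sam_fixture()
  r <- sam_two_class(f$m, f$d, c("MB", "MT"))
  expect_identical(r$n_perm, 20L)
  expect_true(r$enumerated)
})

test_that("SAM is shift-invariant and reproducible under a fixed seed", {
  f <- sam_fixture(effect_rows = 1:8)
  r1 <- sam_two_class(f$m, f$d, c("MB", "MT"), seed = 7)
  m2 <- f$m
  m2$values <- m2$values + 3.14
  r2 <- sam_two_class(m2, f$d, c("MB", "MT"), seed = 7)
  expect_equal(r1$d, r2$d, tolerance = 1e-12)
  expect_identical(r1$significant, r2$significant)
  r3 <- sam_two_class(f$m, f$d, c("MB", "MT"), seed = 7)
  expect_identical(r1$d, r3$d)
  expect_identical(r1$d_perm_sorted, r3$d_perm_sorted)
})

test_that("swapping the contrast negates d and flips directions", {
  f <- sam_fixture(effect_rows = 1:10, seed = 3)
  r1 <- sam_two_class(f$m, f$d, c("MB", "MT"))
  r2 <- sam_two_class(f$m, f$d, c("MT", "MB"))
  expect_equal(r1$d, -r2$d, tolerance = 1e-12)
  expect_setequal(r1$significant, r2$significant)
  common <- intersect(r1$significant, r2$significant)
  expect_true(all(r1$direction[common] != r2$direction[common]))
})

test_that("s0 selection matches an exhaustive grid-search oracle", {
  set.seed(17)
  n <- 200
  s <- exp(rnorm(n, -1, 0.7))          # heteroscedastic scatters
  num <- rnorm(n, 0, 1) * (s + 0.2)
  picked <- choose_s0(s, num)
  # independent re-computation over the same candidate set
  cand <- unname(quantile(s, seq(0, 1, by = 0.05)))
  br <- unique(quantile(s, seq(0, 1, length.out = 11)))
  win <- cut(s, br, include.lowest = TRUE)
  cv <- sapply(cand, function(a) {
    med <- tapply(abs(num / (s + a)), win, median)
    sd(med) / mean(med)
  })
  expect_equal(picked, cand[which.min(cv)], tolerance = 1e-12)
})

test_that("s0 is invariant to miRNA order and handles degenerate scatters", {
  set.seed(18)
  s <- runif(50, 0.1, 1)
  num <- rnorm(50)
  perm <- sample(50)
  expect_equal(choose_s0(s, num), choose_s0(s[perm], num[perm]))
  expect_warning(s0 <- choose_s0(rep(0.5, 30), rnorm(30)), "equal")
  expect_equal(s0, 0.5)  # smallest candidate = the common value
  expect_warning(s00 <- choose_s0(rep(0, 30), rnorm(30) * 0), "equal")
  expect_equal(s00, 0)
  expect_error(choose_s0(runif(10), rnorm(10)), ">= 20")
})

test_that("significance selection is monotone in the FDR target", {
  f <- sam_fixture(effect_rows = 1:12, seed = 5)
  r <- sam_two_class(f$m, f$d, c("MB", "MT"))
  s01 <- select_significant(r, 0.01)
  s10 <- select_significant(r, 0.10)
  expect_true(all(s01 %in% s10))
  # vacuous threshold: everything with any deviation is callable
  s100 <- select_significant(r, 1.0)
  expect_gte(length(s100), length(s10))
})

test_that("clear effects are detected with direction labels", {
  f <- sam_fixture(effect_rows = 1:10, effect = 3, noise = 0.3, seed = 6)
  r <- sam_two_class(f$m, f$d, c("MB", "MT"))
  hits <- sprintf("mir-%03d", 1:10)
  expect_gte(length(intersect(r$significant, hits)), 8)
  expect_true(all(r$direction[intersect(r$significant, hits)] == "up"))
})

test_that("null data yields few or no calls at FDR 0.05", {
  f <- sam_fixture(seed = 8, n = 300)
  r <- sam_two_class(f$m, f$d, c("MB", "MT"))
  expect_lte(length(r$significant), 0.05 * 300)
})

test_that("delta-delta arithmetic follows the Livak rule on both scales", {
  cq <- rbind(c(30, 30, 30, 29, 29, 29),   # ddCq = -1 -> FC 2
              c(28, 28, 28, 28, 28, 28))   # ddCq = 0  -> FC 1
  mq <- mk_matrix(cq, scale = "cq", platform = "qpcr",
                  ids = c("up2", "flat"), samples = sprintf("s%02d", 1:6))
  d <- mk_design(groups = c("MB", "MT"), reps = 3, platform = "qpcr",
                 samples = colnames(mq$values))
  fc <- delta_delta(mq, d, c("MB", "MT"))
  expect_equal(fc$fold_change[fc$id == "up2"], 2)
  expect_equal(fc$fold_change[fc$id == "flat"], 1)
  expect_true(fc$t_undefined[fc$id == "flat"])
  # identical result after re-orienting to the expression scale
  fce <- delta_delta(to_expression_scale(mq), d, c("MB", "MT"))
  expect_equal(fce$fold_change, fc$fold_change, tolerance = 1e-12)
  expect_equal(fce$log2fc, fc$log2fc, tolerance = 1e-12)
  # a group against itself has ddelta 0, fold change 1
  fcs <- delta_delta(mq, d, c("MB", "MB"))
  expect_equal(fcs$fold_change, c(1, 1))
})
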