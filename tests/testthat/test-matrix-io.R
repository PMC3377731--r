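# Reading, validation, detection filtering, cross-matching, scale transform.

test_that("TSV round-trip preserves values and rejects malformed input", {
  v <- matrix(c(1.5, 2, 3, 4, 5, 6.25), 3, 2)
  m <- mk_matrix(v, ids = c("miR-1", "miR-2", "miR-3"))
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_expression_matrix(m, tf)
  m2 <- read_expression_matrix(tf, "log2_intensity", "array", "human")
  expect_equal(m2$values, m$values)
  expect_equal(dim(m2), c(3L, 2L))

  # duplicated miRNA ID named in the error
  writeLines(c("mirna\ts1\ts2", "miR-1\t1\t2", "miR-1\t3\t4"), tf)
  expect_error(read_expression_matrix(tf, "log2_intensity", "array", "human"),
               "miR-1")

  # empty file -> no data rows
  writeLines("mirna\ts1\ts2", tf)
  expect_error(read_expression_matrix(tf, "log2_intensity", "array", "human"),
               "no data rows")

  # non-numeric cell named by row and column
  writeLines(c("mirna\ts1\ts2", "miR-1\t1\tabc"), tf)
  expect_error(read_expression_matrix(tf, "log2_intensity", "array", "human"),
               "miR-1.*s2")
})

test_that("NA cells are imputed at the detection bound and flagged", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("mirna\ts1\ts2", "miR-1\tNA\t30"), tf)
  m <- read_expression_matrix(tf, "cq", "qpcr", "human")
  expect_true(m$flagged["miR-1", "s1"])
  expect_equal(m$values["miR-1", "s1"], 35)  # human Cq cutoff
  mm <- read_expression_matrix(tf, "cq", "qpcr", "mouse")
  expect_equal(mm$values["miR-1", "s1"], 32)
})

test_that("constructor enforces the container invariants", {
  v <- matrix(1:4, 2, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(expression_matrix(v * NA, "log2_intensity", "array", "human"),
               "non-finite")
  expect_error(expression_matrix(v, "cq", "array", "human"), "implies")
  rownames(v) <- c("a", "a")
  expect_error(expression_matrix(v, "log2_intensity", "array", "human"),
               "duplicate")
})

test_that("detection filter applies the platform- and species-specific rule", {
  d <- mk_design(groups = "MB", reps = 3, platform = "qpcr",
                 samples = c("s01", "s02", "s03"))
  q <- mk_matrix(rbind(c(34, 36, 33),   # two < 35 -> retained
                       c(36, 36, 34)),  # one < 35 -> dropped
                 scale = "cq", platform = "qpcr",
                 ids = c("keep", "drop"), samples = d$sample)
  f <- filter_detected(q, d)
  expect_identical(rownames(f$values), "keep")
  expect_identical(attr(f, "dropped"), "drop")

  # mouse cutoff is 32: the same values all fail
  qm <- mk_matrix(q$values, scale = "cq", platform = "qpcr",
                  species = "mouse", ids = c("a", "b"), samples = d$sample)
  dm <- mk_design(groups = "MB", reps = 3, species = "mouse",
                  platform = "qpcr", samples = d$sample)
  expect_equal(nrow(filter_detected(qm, dm)$values), 0L)

  # array rule: signal > 0 in >= 2 replicates of >= 1 group
  da <- mk_design(groups = c("MB", "MT"), reps = 3)
  a <- mk_matrix(rbind(c(0, 5, 7, 0, 0, 0),    # 2 positives in MB
                       c(0, 0, 1, 0, 2, 0),    # never 2 in one group
                       c(0, 0, 0, 3, 2, 1)),   # MT only -> retained
                 ids = c("mb", "spread", "mt"), samples = da$sample)
  f <- filter_detected(a, da)
  expect_setequal(rownames(f$values), c("mb", "mt"))
})

test_that("detection filtering is idempotent and flagged cells never count", {
  m <- rand_matrix(n = 40, seed = 7)
  m$values[1, 1:8] <- 0            # row 1: only one positive signal
  d <- mk_design()
  f1 <- filter_detected(m, d)
  f2 <- filter_detected(f1, d)
  expect_identical(f1$values, f2$values)
  # flagging the positive cells drops the row even though values are > 0
  m2 <- m
  m2$flagged[2, ] <- TRUE
  expect_false("mir-002" %in% rownames(filter_detected(m2, d)$values))
})

test_that("common-subset matching intersects canonical identifiers", {
  a <- mk_matrix(matrix(1:6, 3), ids = c("hsa-miR-1", "hsa-miR-2", "miR-5"))
  b <- mk_matrix(matrix(1:6, 3), ids = c("miR-2", "miR-3", "MIR-5"),
                 platform = "qpcr")
  mc <- match_common_subset(a, b)
  expect_identical(rownames(mc$a$values), rownames(mc$b$values))
  expect_setequal(rownames(mc$a$values), c("mir-2", "mir-5"))

  # identical row sets pass through in identical order
  m1 <- mk_matrix(matrix(1:4, 2), ids = c("miR-9", "miR-10"))
  m2 <- mk_matrix(matrix(5:8, 2), ids = c("miR-9", "miR-10"),
                  platform = "qpcr")
  mc2 <- match_common_subset(m1, m2)
  expect_identical(rownames(mc2$a$values), c("mir-9", "mir-10"))
  expect_identical(mc2$a$values[, 1], setNames(c(1L, 2L),
                                               c("mir-9", "mir-10")))

  # synonym mapping applied before intersecting
  s <- mk_matrix(matrix(1:2, 1), ids = "miR-133a-3p")
  t <- mk_matrix(matrix(3:4, 1), ids = "miR-133a", platform = "qpcr")
  expect_error(match_common_subset(s, t), "empty")
  mc3 <- match_common_subset(s, t,
                             synonym_table = c("miR-133a-3p" = "miR-133a"))
  expect_identical(rownames(mc3$a$values), "mir-133a")

  # species mismatch refused
  u <- mk_matrix(matrix(1:2, 1), ids = "miR-1", species = "mouse")
  expect_error(match_common_subset(a, u), "species")
})

test_that("expression-scale transform reverses Cq order and guards reapplication", {
  q <- mk_matrix(matrix(c(30, 25, 33, 28), 2), scale = "cq",
                 platform = "qpcr")
  e <- to_expression_scale(q)
  expect_equal(e$values[1, 1], 10)       # 40 - 30
  expect_equal(e$scale, "expression")
  # order-reversing bijection: lower Cq -> higher expression
  expect_equal(order(q$values[, 1]), rev(order(e$values[, 1])))
  expect_error(to_expression_scale(e), "already")
  # log2 matrices pass through unchanged
  a <- mk_matrix(matrix(1:4, 2))
  expect_identical(to_expression_scale(a), a)
})
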