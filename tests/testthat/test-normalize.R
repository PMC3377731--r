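# RGI, geomean, quantile normalization and shared method properties.

test_that("RGI centres the reference index and preserves row patterns", {
  x <- rbind(ref1 = c(20, 21, 19), ref2 = c(22, 23, 21),
             t1 = c(25, 26, 27), t2 = c(8, 9, 10))
  m <- mk_matrix(x, ids = rownames(x))
  nr <- normalize_rgi(m, refs = c("ref1", "ref2"))
  ref_after <- colMeans(nr$values[c("ref1", "ref2"), ])
  expect_equal(unname(diff(range(ref_after))), 0, tolerance = 1e-12)
  expect_equal(unname(ref_after[1]), 21)  # grand mean of the index
  # per-sample shift: ref_j = 21, 22, 20 -> offsets 0, -1, +1
  expect_equal(unname(nr$offsets), c(0, -1, 1))
  # pure per-column shift: row differences within a column preserved
  expect_equal(nr$values["t1", ] - nr$values["t2", ],
               m$values["t1", ] - m$values["t2", ])
  # both refs constant across samples -> identity
  x2 <- rbind(ref1 = rep(20, 3), ref2 = rep(22, 3), t1 = c(1, 5, 9))
  m2 <- mk_matrix(x2, ids = rownames(x2))
  expect_equal(normalize_rgi(m2, c("ref1", "ref2"))$values, m2$values)
  # missing or flagged reference is refused
  expect_error(normalize_rgi(m, c("ref1", "nope")), "missing")
  mf <- m
  mf$flagged["ref1", 2] <- TRUE
  expect_error(normalize_rgi(mf, c("ref1", "ref2")), "flagged")
})

test_that("geomean normalization equalizes column means at the grand mean", {
  m <- mk_matrix(cbind(c(2, 4, 6), c(3, 5, 7)))
  ng <- normalize_geomean(m)
  expect_equal(unname(ng$values[, 1]), c(2.5, 4.5, 6.5))
  expect_equal(unname(ng$values[, 2]), c(2.5, 4.5, 6.5))
  expect_equal(unname(colMeans(ng$values)), rep(4.5, 2))
  # already equal-mean columns are untouched
  m2 <- mk_matrix(cbind(c(1, 2, 3), c(3, 2, 1)))
  expect_equal(normalize_geomean(m2)$values, m2$values)
  # random case: all column means equal the grand mean afterwards
  m3 <- rand_matrix(n = 30, seed = 3)
  n3 <- normalize_geomean(m3)
  expect_equal(unname(colMeans(n3$values)),
               rep(mean(m3$values), ncol(m3$values)))
})

# Independent sort/average oracle for quantile normalization (no ties).
quantile_oracle <- function(x) {
  mu <- rowMeans(apply(x, 2, sort))
  apply(x, 2, function(col) mu[rank(col)])
}

test_that("quantile normalization matches the sort/average oracle", {
  m <- mk_matrix(cbind(c(1, 2, 3), c(3, 4, 5)))
  nq <- normalize_quantile(m)
  expect_equal(unname(nq$values), cbind(c(2, 3, 4), c(2, 3, 4)))
  # identical columns unchanged
  m2 <- mk_matrix(cbind(c(5, 1, 3), c(5, 1, 3)))
  expect_equal(normalize_quantile(m2)$values, m2$values)
  # seeded random 5x3 matrices against the oracle, exactly
  for (seed in 1:5) {
    set.seed(seed)
    x <- matrix(rnorm(15, 10), 5, 3)
    mm <- mk_matrix(x)
    expect_equal(unname(normalize_quantile(mm)$values),
                 quantile_oracle(x), tolerance = 1e-14)
  }
  # post-normalization columns share identical sorted values
  m3 <- rand_matrix(n = 40, seed = 9)
  s <- apply(normalize_quantile(m3)$values, 2, sort)
  expect_true(all(abs(s - s[, 1]) < 1e-12))
})

test_that("quantile agrees with limma's implementation on tie-free data", {
  set.seed(21)
  x <- matrix(rnorm(60, 10), 20, 3)
  m <- mk_matrix(x)
  expect_equal(unname(normalize_quantile(m)$values),
               unname(limma::normalizeQuantiles(x)), tolerance = 1e-10)
})

test_that("ties receive the mean of their rank positions", {
  x <- cbind(c(1, 1, 5), c(2, 3, 4))
  m <- mk_matrix(x)
  nq <- normalize_quantile(m)
  mu <- rowMeans(apply(x, 2, sort))
  expect_equal(unname(nq$values[1:2, 1]), rep(mean(mu[1:2]), 2))
})

test_that("every method preserves shape and identifiers; none is identity", {
  m <- rand_matrix(n = 60, seed = 4)
  d <- mk_design()
  for (meth in c("none", "rgi", "geomean", "quantile", "inv", "loess",
                 "loessm", "gpa")) {
    nm <- normalize_matrix(m, meth, design = d)
    expect_identical(dimnames(nm$values), dimnames(m$values))
    expect_s3_class(nm, "NormalizedMatrix")
    expect_identical(nm$method, meth)
  }
  expect_identical(normalize_matrix(m, "none")$values, m$values)
})
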