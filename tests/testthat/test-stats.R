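test_that("pair extraction matches exhaustive enumeration on complete trees", {
  ps2 <- extractPairs(completeTreeTable(2))
  expect_identical(pairCounts(ps2), c(dd = 3L, md = 6L, cc = 4L))
  ps3 <- extractPairs(completeTreeTable(3))
  expect_identical(pairCounts(ps3), c(dd = 7L, md = 14L, cc = 12L))

  ## a lone completed founder yields no pairs at all
  ps0 <- extractPairs(completeTreeTable(0))
  expect_identical(unname(pairCounts(ps0)), c(0L, 0L, 0L))

  ## M-D pairs are ordered mother-first
  tab <- completeTreeTable(1, durations = c(30, 21, 22))
  md <- extractPairs(tab)@md
  expect_true(all(md[, 1] == 30))
})

test_that("pair extraction equals a brute-force ancestry scan on random trees", {
  set.seed(41)
  for (i in 1:60) {
    tab <- randomTreeTable()
    expect_identical(pairCounts(extractPairs(tab)), bruteForcePairs(tab))
  }
})

test_that("malformed forests are rejected", {
  tab <- completeTreeTable(1)
  dup <- rbind(tab, tab[2, ])
  expect_error(extractPairs(dup), "duplicate")
  self <- tab; self$parent_id[2] <- 2
  expect_error(extractPairs(self), "own parent")
})

test_that("pearsonR implements the sample-covariance definition", {
  expect_equal(pearsonR(1:10, 2 * (1:10) + 1), 1)
  expect_equal(pearsonR(1:10, -(1:10)), -1)
  expect_equal(pearsonR(c(1, 2, 3, 4), c(2, 1, 4, 3)), 0.6)
  set.seed(42)
  for (i in 1:20) {
    x <- rnorm(50); y <- rnorm(50)
    expect_equal(pearsonR(x, y), cor(x, y), tolerance = 1e-12)
    ## affine invariance and sign flip
    expect_equal(pearsonR(3 * x + 2, y), pearsonR(x, y))
    expect_equal(pearsonR(-x, y), -pearsonR(x, y))
  }
  expect_error(pearsonR(1:3, 1:4), "length")
  r <- pearsonR(c(1, 1, 1), c(1, 2, 3))
  expect_true(is.na(r))
  expect_identical(attr(r, "reason"), "zero variance")
  r2 <- pearsonR(1:2, 2:1)
  expect_identical(attr(r2, "reason"), "fewer than 3 pairs")
})

test_that("correlation summaries flag undefined cases and recover known rho", {
  ## identical durations: every class undefined, never silently numeric
  tab <- completeTreeTable(2, durations = rep(24, 7))
  cs <- correlationSummary(extractPairs(tab))
  expect_true(all(is.na(correlations(cs))))
  expect_true(all(!cs@defined))
  expect_true(is.na(cmiScore(cs)))

  ## pairs with known correlation 0.8 are recovered within sampling error
  set.seed(43)
  n <- 300; rho <- 0.8
  z <- rnorm(n)
  lam <- sqrt(1 / rho - 1)   # corr(z + lam*e1, z + lam*e2) = 1/(1 + lam^2)
  a <- z + lam * rnorm(n)
  b <- z + lam * rnorm(n)
  ps <- new("LineagePairSet", dd = cbind(a, b),
            md = matrix(numeric(0), ncol = 2),
            cc = matrix(numeric(0), ncol = 2), durationKind = "T_cc")
  cs2 <- correlationSummary(ps)
  expect_equal(cs2@r[["dd"]], rho, tolerance = 0.075)

  ## the symmetrized estimator is orientation-free
  psFlip <- new("LineagePairSet", dd = cbind(b, a)[sample(n), ],
                md = matrix(numeric(0), ncol = 2),
                cc = matrix(numeric(0), ncol = 2), durationKind = "T_cc")
  expect_equal(correlationSummary(psFlip)@r[["dd"]], cs2@r[["dd"]],
               tolerance = 1e-12)
})

test_that("population statistics use N-1 sample moments", {
  tab <- data.frame(cell_id = 1:3, parent_id = NA, completed = TRUE,
                    T_cc = c(20, 24, 28))
  ps <- populationStats(tab)
  expect_equal(ps$mean, 24)
  expect_equal(ps$sd, 4)
  expect_equal(ps$cv, 1 / 6)
  one <- tab[1, ]
  expect_error(populationStats(one), "at least 2")
})

test_that("bootstrap comparison is seed-reproducible and two-sided", {
  set.seed(44)
  n <- 100
  z <- rnorm(n)
  A <- cbind(z, z + 0.3 * rnorm(n))          # strong correlation
  B <- cbind(rnorm(n), rnorm(n))             # none
  r1 <- bootstrapFisherTest(A, B, nBoot = 500, seed = 99)
  r2 <- bootstrapFisherTest(A, B, nBoot = 500, seed = 99)
  expect_identical(r1$p.value, r2$p.value)
  expect_lt(r1$p.value, 0.05)
  ## two-sided: the label order does not change the conclusion
  r3 <- bootstrapFisherTest(B, A, nBoot = 500, seed = 99)
  expect_lt(r3$p.value, 0.05)
  expect_equal(r3$rB, r1$rA, tolerance = 0.05)
})

test_that("replicate aggregation averages defined correlations with SEM", {
  mk <- function(r) new("LineageCorrelations",
    r = c(dd = r, md = r / 2, cc = NA_real_),
    n = c(dd = 10L, md = 10L, cc = 2L),
    defined = c(dd = TRUE, md = TRUE, cc = FALSE),
    cmi = NA_real_, durationKind = "T_cc", replicate = NA_real_)
  agg <- replicateAggregate(list(mk(0.5), mk(0.6), mk(0.7)))
  expect_equal(agg$mean[agg$class == "dd"], 0.6)
  expect_equal(agg$sem[agg$class == "dd"], 0.1 / sqrt(3), tolerance = 1e-6)
  expect_equal(agg$nUndefined[agg$class == "cc"], 3)
})
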