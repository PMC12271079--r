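test_that("lognormal parameterisation gives the requested mean and CV", {
  expect_equal(lognormalParams(2, 0)[["sigma"]], 0)
  set.seed(31)
  for (cv in c(0.05, 0.10)) {
    lp <- lognormalParams(1, cv)
    x <- rlnorm(1e6, lp[["mu"]], lp[["sigma"]])
    expect_equal(mean(x), 1, tolerance = 0.002)
    expect_equal(sd(x) / mean(x), cv, tolerance = 0.02 * cv + 0.001)
  }
  expect_error(lognormalParams(0, 0.05), "mean")
})

test_that("founder multipliers have unit mean, target CV and independence", {
  set.seed(32)
  expect_identical(drawInitialMultipliers(0), c(1, 1, 1))
  draws <- t(replicate(1e4, drawInitialMultipliers(0.05)))
  expect_equal(colMeans(draws), rep(1, 3), tolerance = 0.01)
  cvs <- apply(draws, 2, sd) / colMeans(draws)
  expect_equal(cvs, rep(0.05, 3), tolerance = 0.1)
  cors <- cor(draws)[upper.tri(diag(3))]
  expect_true(all(abs(cors) < 0.05))
})

test_that("mitotic resetting applies the +/-10% rule", {
  expect_equal(applyMitoticResetting(1, 0.1, u = 0.7), 1.1)
  expect_equal(applyMitoticResetting(1, 0.1, u = 0.3), 0.9)
  expect_equal(applyMitoticResetting(1, 0.1, u = 0.5), 0.9)  # tie = decrease
  expect_equal(applyMitoticResetting(c(2, 3, 4), 0), c(2, 3, 4))
  set.seed(33)
  f <- replicate(1e4, applyMitoticResetting(1, 0.1))
  expect_equal(mean(f), 1, tolerance = 0.003)
  expect_equal(mean(f > 1), 0.5, tolerance = 0.03)
  expect_error(applyMitoticResetting(1, 1.2), "magnitude")
})

test_that("noise-free propagation reproduces the deterministic cycle", {
  m <- testBaseline()
  dp <- deterministicPeriod(m)
  cfg <- simConfig(D = 0, initCV = 0, resetEnabled = FALSE, ouInit = "zero",
                   nLineages = 3)
  ## a cell born at the division point of the converged generational orbit
  gen <- lineageCycle:::.generationCycle(m, lead = 2)
  y <- gen$y_div
  iep <- y[["IEP"]]; y <- y / 2; y[["IEP"]] <- iep
  res <- propagateCell(m, y, cfg = cfg, t0 = 0, cellIndex = 1L)
  expect_equal(res$t_div, dp$period, tolerance = cfg$dt)
  expect_equal(res$t_g1, dp$g1, tolerance = 2 * cfg$dt)
  expect_equal(res$t_g1, 10, tolerance = 0.05 * 10)
})

test_that("identical seeds give bit-identical forests; seeds matter", {
  m <- testBaseline()
  cfg <- simConfig(nLineages = 10, maxCellsUsed = 50, masterSeed = 7)
  f1 <- simulateLineages(m, cfg)
  f2 <- simulateLineages(m, cfg)
  expect_identical(cellTable(f1), cellTable(f2))
  cfg2 <- simConfig(nLineages = 10, maxCellsUsed = 50, masterSeed = 8)
  f3 <- simulateLineages(m, cfg2)
  expect_false(identical(cellTable(f1)$t_division, cellTable(f3)$t_division))
})

test_that("daughters inherit the mother's post-reset multipliers exactly", {
  m <- testBaseline()
  f <- simulateLineages(m, simConfig(nLineages = 8, maxCellsUsed = 40,
                                     masterSeed = 5))
  cells <- cellTable(f)
  kids <- cells[!is.na(cells$parent_id), ]
  moms <- cells[match(kids$parent_id, cells$cell_id), ]
  ## sisters share multipliers bit-exactly (mother-level resetting)
  for (pid in unique(kids$parent_id)) {
    sibs <- kids[kids$parent_id == pid, ]
    expect_equal(nrow(sibs), 2)
    expect_identical(sibs$mult_cycb[1], sibs$mult_cycb[2])
    expect_identical(sibs$mult_cdh1[1], sibs$mult_cdh1[2])
  }
  ## each multiplier is the mother's times exactly 0.9 or 1.1
  ratio <- kids$mult_cycb / moms$mult_cycb
  expect_true(all(abs(ratio - 1.1) < 1e-12 | abs(ratio - 0.9) < 1e-12))

  ## with resetting disabled the multipliers pass through unchanged
  f0 <- simulateLineages(m, simConfig(nLineages = 5, maxCellsUsed = 20,
                                      masterSeed = 5, resetEnabled = FALSE))
  c0 <- cellTable(f0)
  k0 <- c0[!is.na(c0$parent_id), ]
  m0 <- c0[match(k0$parent_id, c0$cell_id), ]
  expect_identical(k0$mult_cycb, m0$mult_cycb)
})

test_that("division semantics: content halves, the IEP fraction carries over", {
  m <- testBaseline()
  cfg <- simConfig(D = 0, initCV = 0, resetEnabled = FALSE, ouInit = "zero",
                   nLineages = 1, maxCellsUsed = 4)
  gen <- lineageCycle:::.generationCycle(m, lead = 2)
  y <- gen$y_div
  iep <- y[["IEP"]]; yHalf <- y / 2; yHalf[["IEP"]] <- iep
  res <- propagateCell(m, yHalf, cfg = cfg, t0 = 0, cellIndex = 1L)
  ## the division state returned equals the converged orbit's division state
  expect_equal(res$y_div, gen$y_div, tolerance = 1e-4)
})

test_that("horizon truncation and completion counting follow the protocol", {
  m <- testBaseline()
  ## horizon shorter than one full cycle: founders divide (partial segment)
  ## but no full-cycle cell completes
  f <- suppressWarnings(simulateLineages(m, simConfig(horizon = 12,
    nLineages = 10, maxCellsUsed = 30, masterSeed = 2)))
  cells <- cellTable(f)
  expect_equal(sum(cells$completed & cells$full_cycle), 0)
  expect_equal(sum(cells$in_analysis), 0)
  expect_true(any(grepl("available", f@notes)))

  ## founders carry no duration statistics
  expect_true(all(is.na(cells$T_cc[cells$generation == 0])))
})

test_that("the analysis set takes whole lineages up to the cell budget", {
  m <- testBaseline()
  f <- simulateLineages(m, simConfig(nLineages = 60, maxCellsUsed = 120,
                                     masterSeed = 9))
  cells <- cellTable(f, analysisOnly = TRUE)
  expect_equal(nrow(cells), 120)
  expect_true(all(cells$completed))
  expect_true(all(cells$full_cycle))
  ## lineages enter in order; all analysis lineages precede excluded ones
  full <- cellTable(f)
  usedL <- unique(cells$lineage_id)
  expect_true(max(usedL) <= min(setdiff(unique(full$lineage_id), usedL)))
})

test_that("lineage trees export as phylo objects with duration branches", {
  m <- testBaseline()
  f <- simulateLineages(m, simConfig(nLineages = 2, maxCellsUsed = 10,
                                     masterSeed = 4))
  trees <- forestToPhylo(f)
  expect_gt(length(trees), 0)
  tr <- trees[[1]]
  expect_s3_class(tr, "phylo")
  expect_true(all(tr$edge.length >= 0))
  nwk <- ape::write.tree(tr)
  expect_match(nwk, "^\\(")
})
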