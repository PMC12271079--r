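test_that("crossover location interpolates the first sign change", {
  fake <- function(tau, md, cc) {
    data.frame(tau = tau, D = 0.03, replicate = 1, r_dd = 0.5, r_md = md,
               r_cc = cc, defined_dd = TRUE, defined_md = TRUE,
               defined_cc = TRUE)
  }
  ## symmetric bracket: md-cc goes -0.02 at 12 to +0.02 at 14 -> 13.0
  tab <- rbind(fake(12, 0.30, 0.32), fake(14, 0.32, 0.30))
  cx <- findCrossover(tab, "md", "cc", "tau")
  expect_equal(cx$coordinate, 13.0)
  expect_equal(cx$bracket, c(12, 14))

  ## all-positive difference: explicit no-crossover result, not an error
  tab2 <- rbind(fake(5, 0.4, 0.3), fake(10, 0.45, 0.3), fake(15, 0.5, 0.3))
  cx2 <- findCrossover(tab2, "md", "cc", "tau")
  expect_true(is.na(cx2$coordinate))

  ## a known linear difference model is recovered within grid resolution
  taus <- seq(4, 20, by = 2)
  root <- 11.35
  tabs <- do.call(rbind, lapply(taus, function(t)
    fake(t, 0.3 + 0.01 * (t - root), 0.3)))
  cx3 <- findCrossover(tabs, "md", "cc", "tau")
  expect_equal(cx3$coordinate, root, tolerance = 1e-9)
})

test_that("sweeps produce one row per grid point and replicate", {
  m <- testBaseline()
  cfg <- simConfig(nLineages = 12, maxCellsUsed = 40)
  tab <- suppressWarnings(
    sweepCorrelations(m, taus = 10, Ds = 0.03, cfg, nReplicates = 3,
                      baseSeed = 50))
  expect_equal(nrow(tab), 3)
  expect_true(all(tab$defined_dd & tab$defined_md & tab$defined_cc))
  expect_true(all(abs(tab$r_dd) <= 1))
  ## deterministic given seeds
  tab2 <- suppressWarnings(
    sweepCorrelations(m, taus = 10, Ds = 0.03, cfg, nReplicates = 3,
                      baseSeed = 50))
  expect_identical(tab, tab2)
})

test_that("the degenerate grid point is flagged undefined, not numeric", {
  m <- testBaseline()
  cfg <- simConfig(nLineages = 10, maxCellsUsed = 30, initCV = 0,
                   resetEnabled = FALSE, ouInit = "zero")
  tab <- suppressWarnings(
    sweepCorrelations(m, taus = 10, Ds = 0, cfg, nReplicates = 2,
                      baseSeed = 51))
  expect_true(all(!tab$defined_dd & !tab$defined_md & !tab$defined_cc))
  expect_true(all(is.na(tab$cmi)))
  expect_lt(max(tab$cv_tcc), 1e-5)
})

test_that("the study suite writes tables, configs and a manifest", {
  out <- file.path(tempdir(), "suite-test")
  man <- suppressWarnings(runStudySuite(out, preset = "fast", seed = 3,
    experiments = c("no_reset", "gf_variants")))
  expect_true(file.exists(file.path(out, "manifest.json")))
  expect_identical(man$experiments$no_reset$status, "ok")
  expect_identical(man$experiments$gf_variants$status, "ok")
  tab <- read.csv(man$experiments$gf_variants$table)
  expect_true(all(c(2, 5, 10) %in% tab$GF))
  expect_true(file.exists(man$experiments$no_reset$config))
  unlink(out, recursive = TRUE)
})
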