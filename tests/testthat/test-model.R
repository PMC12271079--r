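test_that("right-hand side matches the reaction scheme term by term", {
  m <- defaultModel()
  p <- modelParams(m)

  ## zero state, zero noise: only zeroth-order terms survive
  y0 <- initialState(m); y0[] <- 0
  dy <- modelRHS(y0, m)
  g <- p[["GF"]] / (p[["Kmm"]] + p[["keff"]] * p[["GF"]])
  expect_equal(dy[["CycBm"]], p[["k1m"]] * g)
  expect_gt(dy[["CycBm"]], 0)
  expect_equal(dy[["IEP"]], 0)
  expect_equal(dy[["X"]], p[["k11"]])

  ## Cdh1 = 0 removes the Cdh1-mediated CycB degradation term
  y <- initialState(m)
  y[["Cdh1"]] <- 0
  dy <- modelRHS(y, m)
  expect_equal(dy[["CycB"]],
               p[["k1"]] * y[["CycBm"]] - p[["k2a"]] * y[["CycB"]])

  ## random admissible states against the independent oracle, with noise
  ## and multipliers
  set.seed(11)
  for (i in 1:25) {
    y <- randomState()
    eps <- rnorm(4, 0, 0.3)
    mult <- exp(rnorm(3, 0, 0.1))
    expect_equal(as.numeric(modelRHS(y, m, eps, mult)),
                 as.numeric(oracleRHS(y, p, eps, mult)), tolerance = 1e-12)
  }
  expect_error(modelRHS(replace(y, 1, NaN), m), "non-finite")
})

test_that("protein-noise variant drops the mRNA layer and matches its oracle", {
  m <- proteinNoiseModel(defaultModel())
  expect_identical(modelVariant(m), "protein")
  expect_length(initialState(m), 7)
  expect_false(any(c("CycBm", "Cdc20m", "Cdhm") %in% names(initialState(m))))
  p <- modelParams(m)
  set.seed(12)
  for (i in 1:25) {
    y <- randomState("protein")
    eps <- rnorm(4, 0, 0.05)
    mult <- exp(rnorm(3, 0, 0.1))
    expect_equal(as.numeric(modelRHS(y, m, eps, mult)),
                 as.numeric(oracleRHSProtein(y, p, eps, mult)),
                 tolerance = 1e-12)
  }
  ## production constants are the quasi-steady fluxes of the mRNA variant
  d <- modelParams(defaultModel())
  expect_equal(p[["k1m"]], d[["k1"]] * d[["k1m"]] / d[["k1dm"]])
})

test_that("deterministic integration is periodic, convergent and nonnegative", {
  m <- defaultModel()
  guess <- 2.2 / modelParams(m)[["k2a"]]
  traj <- integrateDeterministic(m, horizon = 12 * guess)
  expect_true(all(traj[, -1] >= 0))
  iep <- traj[, "IEP"]
  expect_true(all(iep >= 0 & iep <= 1 + 1e-9))

  ## after the transient the trajectory returns to itself one period later
  dp <- deterministicPeriod(m, division = "intensive")
  dt <- guess / 2400
  lag <- round(dp$period / dt)
  n <- nrow(traj)
  late <- (n - lag - 100):(n - lag)
  expect_equal(traj[late + lag, "CycB"], traj[late, "CycB"], tolerance = 5e-3)

  ## halving the step changes the trajectory negligibly
  tr1 <- integrateDeterministic(m, horizon = 2 * guess, dt = dt)
  tr2 <- integrateDeterministic(m, horizon = 2 * guess, dt = dt / 2)
  expect_equal(tr1[nrow(tr1), "CycB"], tr2[nrow(tr2), "CycB"],
               tolerance = 1e-4)

  ## the stiff backend agrees with the fixed-step integrator
  tr3 <- integrateDeterministic(m, horizon = 2 * guess, dt = dt,
                                method = "lsoda")
  expect_equal(tr1[nrow(tr1), "CycB"], tr3[nrow(tr3), "CycB"],
               tolerance = 1e-3)
})

test_that("time-rescaling symmetry: doubled rates halve the period", {
  m <- defaultModel()
  dp <- deterministicPeriod(m)
  p2 <- modelParams(m)
  rates <- lineageCycle:::.rateNames
  p2[rates] <- p2[rates] * 2
  m2 <- cellCycleModel(p2)
  dp2 <- deterministicPeriod(m2)
  expect_equal(dp2$period, dp$period / 2, tolerance = 1e-3)
  expect_equal(dp2$g1 / dp2$period, dp$g1 / dp$period, tolerance = 5e-3)
})

test_that("oscillations disappear below a growth-factor onset", {
  low <- cellCycleModel(c(GF = 0.2))
  expect_error(deterministicPeriod(low), class = "noOscillationError")
  high <- cellCycleModel(c(GF = 2))
  expect_silent(dp <- deterministicPeriod(high))
  expect_gt(dp$period, 0)
})

test_that("calibration hits target period and G1 and is a fixed point", {
  m24 <- testBaseline()
  cal <- attr(m24, "calibration")
  expect_equal(cal$period, 24, tolerance = 1e-3)
  expect_equal(cal$g1, 10, tolerance = 0.01)

  ## recalibrating an already calibrated model changes nothing material
  m24b <- calibrateModel(m24, 24, 10)
  expect_equal(modelParams(m24b), modelParams(m24), tolerance = 1e-3)

  ## same phase fractions: pure time rescaling, all rates exactly doubled
  m12 <- calibrateModel(m24, 12, 5)
  rates <- lineageCycle:::.rateNames
  expect_equal(modelParams(m12)[rates] / modelParams(m24)[rates],
               setNames(rep(2, length(rates)), rates), tolerance = 1e-3)

  ## a different phase split, verified by re-measurement
  m28 <- calibrateModel(defaultModel(), 28, 9)
  dp <- deterministicPeriod(m28)
  expect_equal(dp$period, 28, tolerance = 0.01 * 28)
  expect_equal(dp$g1, 9, tolerance = 0.05 * 9)

  ## unreachable phase fraction fails with the achievable ranges listed
  expect_error(calibrateModel(defaultModel(), 16, 9),
               class = "calibrationError")
})

test_that("parameter files round-trip through the flat key-value format", {
  m <- cellCycleModel(c(GF = 3.21))
  path <- tempfile(fileext = ".cfg")
  writeParamsFile(m, path)
  m2 <- readParamsFile(path)
  expect_equal(modelParams(m2), modelParams(m))
  expect_identical(modelVariant(m2), "mrna")

  shipped <- readParamsFile(system.file("extdata", "baseline_24h.cfg",
                                        package = "lineageCycle"))
  dp <- deterministicPeriod(shipped)
  expect_equal(dp$period, 24, tolerance = 0.02 * 24)
  expect_equal(dp$g1, 10, tolerance = 0.05 * 10)
})

test_that("model validity catches inadmissible parameters", {
  expect_error(cellCycleModel(c(k1m = -1)), "rate constants")
  expect_error(cellCycleModel(c(n = 0.5)), "Hill")
  expect_error(cellCycleModel(c(J5 = 0)), "Michaelis")
  expect_error(cellCycleModel(c(nonsense = 1)), "unknown parameter")
})
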