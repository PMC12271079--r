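test_that("noise-strength conversion follows D = 4 D' dt", {
  expect_equal(noiseStrengthToDprime(0.03, 0.01), 0.75)
  expect_equal(noiseStrengthToDprime(0, 0.01), 0)
  ## round trip is exact
  D <- c(0.001, 0.0192, 0.03, 0.035)
  expect_identical(4 * noiseStrengthToDprime(D, 0.01) * 0.01, D)
  expect_error(noiseStrengthToDprime(0.03, 0), "dt")
})

test_that("noise-free channel decays exponentially toward zero", {
  p <- ouProcess(tau = 5, D = 0, dt = 0.01, value = 1.3)
  p <- ouStep(p)
  expect_equal(p@value, 1.3 * exp(-0.01 / 5))
  s <- ouSeries(1000, tau = 5, D = 0, value0 = 1.3, seed = 3)
  expect_equal(s[1000], 1.3 * exp(-1000 * 0.01 / 5), tolerance = 1e-12)
})

test_that("stationary moments and autocorrelation match the OU law", {
  tau <- 2; D <- 0.03; dt <- 0.01
  Dp <- noiseStrengthToDprime(D, dt)
  n <- 5e5
  s <- ouSeries(n, tau, D, dt, seed = 17)
  varTarget <- Dp / tau
  se <- sqrt(varTarget / (n * dt / (2 * tau)))  # effective sample size n*dt/2tau
  expect_lt(abs(mean(s)), 3 * se)
  expect_equal(var(s), varTarget, tolerance = 0.05)
  lag <- round(tau / dt)
  ac <- cor(s[1:(n - lag)], s[(lag + 1):n])
  expect_equal(ac, exp(-1), tolerance = 0.10 * exp(-1) + 0.02)
})

test_that("exact and Euler updates share stationary moments as dt shrinks", {
  tau <- 5; D <- 0.03
  for (dt in c(0.01, 0.005, 0.0025)) {
    Dp <- noiseStrengthToDprime(D, dt)
    sE <- ouSeries(2e5, tau, D, dt, seed = 23, mode = "exact")
    sU <- ouSeries(2e5, tau, D, dt, seed = 23, mode = "euler")
    expect_equal(var(sE), Dp / tau, tolerance = 0.07)
    expect_equal(var(sU), Dp / tau, tolerance = 0.07)
  }
})

test_that("streams are reproducible and mutually independent", {
  a1 <- ouSeries(5000, 10, 0.03, seed = 5, stream = 1)
  a2 <- ouSeries(5000, 10, 0.03, seed = 5, stream = 1)
  expect_identical(a1, a2)
  b <- ouSeries(5000, 10, 0.03, seed = 5, stream = 2)
  expect_false(identical(a1, b))
  expect_lt(abs(cor(a1, b)), 0.1)
})

test_that("the OUProcess object enforces its invariants", {
  expect_error(ouProcess(tau = -1, D = 0.03), "tau")
  expect_error(ouProcess(tau = 5, D = -0.1), "D must")
  p <- ouProcess(10, 0.03, 0.01)
  expect_equal(p@Dprime, 0.75)
})
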