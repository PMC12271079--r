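## ou_noise: exponentially correlated (Ornstein-Uhlenbeck) fluctuations of
## the transcription rates, with the D = 4 D' dt noise-strength convention.

#' Convert quoted noise strength to white-noise intensity
#'
#' The noise strength \code{D} is quoted under the convention
#' \eqn{D = 4 D' \Delta t}, where \eqn{\Delta t} is the simulation step, so
#' the underlying white-noise intensity is \eqn{D' = D / (4 \Delta t)}.
#' The stationary variance of the resulting OU process is \eqn{D'/\tau}.
#'
#' @param D noise strength (dimensionless).
#' @param dt simulation step (h).
#' @return \eqn{D'} (a.u.^2/h).
#' @examples
#' noiseStrengthToDprime(0.03, 0.01)  # 0.75
#' @export
noiseStrengthToDprime <- function(D, dt) {
  if (any(dt <= 0)) stop("dt must be > 0")
  if (any(D < 0)) stop("D must be >= 0")
  D / (4 * dt)
}

#' Create an OU noise channel
#'
#' @param tau autocorrelation time (h).
#' @param D noise strength under the \eqn{D = 4 D' \Delta t} convention.
#' @param dt simulation step (h).
#' @param value initial value; by default a draw from the stationary
#'   distribution \eqn{N(0, D'/\tau)} (0 when \code{D = 0}).
#' @param mode \code{"exact"} for the unconditionally stable discrete OU
#'   update or \code{"euler"} for the literal Euler-Maruyama form.
#' @return an \linkS4class{OUProcess}.
#' @export
ouProcess <- function(tau, D, dt = 0.01, value = NULL,
                      mode = c("exact", "euler")) {
  mode <- match.arg(mode)
  if (tau <= 0) stop("tau must be > 0")
  Dprime <- noiseStrengthToDprime(D, dt)
  if (is.null(value))
    value <- if (D > 0) rnorm(1, 0, sqrt(Dprime / tau)) else 0
  new("OUProcess", tau = tau, D = D, Dprime = Dprime, dt = dt,
      value = value, mode = mode)
}

#' Advance an OU channel by one step
#'
#' Exact mode uses the discrete OU update
#' \eqn{v' = v e^{-\Delta t/\tau} + \sigma\sqrt{1 - e^{-2\Delta t/\tau}} g}
#' with stationary s.d. \eqn{\sigma = \sqrt{D'/\tau}}; Euler mode applies
#' the Euler-Maruyama discretisation of
#' \eqn{d\varepsilon/dt = -\varepsilon/\tau + \varepsilon_{gn}/\tau}.
#' The Gaussian draw comes from R's RNG stream.
#'
#' @param p an \linkS4class{OUProcess}.
#' @return the updated \code{OUProcess}.
#' @export
ouStep <- function(p) {
  stopifnot(is(p, "OUProcess"))
  g <- rnorm(1)
  p@value <- .cc_ou_step(p@value, p@tau, p@Dprime, p@dt,
                         if (p@mode == "exact") 0L else 1L, g)
  p
}

#' Simulate an OU series
#'
#' Generates \code{n} consecutive values of one OU channel using the
#' package's own deterministic per-stream generator (independent of R's
#' RNG), as used for the per-cell noise streams of the lineage simulator.
#'
#' @param n number of steps.
#' @param tau,D,dt,mode as in \code{\link{ouProcess}}.
#' @param value0 initial value (default 0).
#' @param seed integer master seed.
#' @param stream integer substream identifier; distinct streams are
#'   statistically independent.
#' @return numeric vector of length \code{n}.
#' @export
ouSeries <- function(n, tau, D, dt = 0.01, value0 = 0, seed = 1L,
                     stream = 0L, mode = c("exact", "euler")) {
  mode <- match.arg(mode)
  .cc_ou_series(as.numeric(n), value0, tau, noiseStrengthToDprime(D, dt),
                dt, if (mode == "exact") 0L else 1L,
                as.integer(seed), as.integer(stream))
}
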