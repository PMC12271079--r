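#' @useDynLib lineageCycle, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom methods new validObject is slot
#' @importFrom stats rnorm runif rlnorm uniroot sd var cor t.test qnorm
#' @importFrom utils write.csv head tail
NULL

.paramNames <- c(
  "k1m", "Kmm", "keff", "k1dm", "k1", "k2a", "k2b",
  "k5am", "k5bm", "k5cm", "J5c", "J5", "n", "k5dm",
  "k5a", "k6", "k7", "J7", "k8", "J8", "Mad",
  "k3m", "k3dm", "k3a", "k3dt", "k3", "k3b", "J3", "J4", "k4",
  "k9", "k10", "k11", "k12", "k13", "GF", "cycb_div_threshold"
)

## first-order rate constants (units involve 1/h): the set rescaled by the
## time-rescaling stage of calibration
.rateNames <- c(
  "k1m", "k1dm", "k1", "k2a", "k2b", "k5am", "k5bm", "k5dm",
  "k5a", "k6", "k7", "k8", "k3m", "k3dm", "k3a", "k3dt",
  "k3", "k3b", "k4", "k9", "k10", "k11", "k12", "k13"
)

.stateNamesMrna <- c("CycBm", "CycB", "Cdc20m", "Cdc20T", "Cdc20A",
                     "Cdhm", "Cdht", "Cdh1", "IEP", "X")
.stateNamesProtein <- c("CycB", "Cdc20T", "Cdc20A", "Cdht", "Cdh1", "IEP", "X")

#' Cell-cycle network model
#'
#' An S4 container for one parameterization of the growth-factor-driven
#' CycB/Cdh1/Cdc20 cell-cycle oscillator.  The \code{"mrna"} variant carries
#' explicit mRNA species for the three regulators, with Ornstein-Uhlenbeck
#' noise entering the transcription rates; the \code{"protein"} variant drops
#' the mRNA layer and applies the same noise directly to the protein
#' production rates (a control used to show that explicit mRNA dynamics are
#' needed for the cousin-mother inequality).
#'
#' @slot params named numeric vector of kinetic constants, growth-factor
#'   level \code{GF} (a.u.) and the CycB division threshold
#'   \code{cycb_div_threshold} (a.u.); all rates in 1/h or a.u./h.
#' @slot variant \code{"mrna"} or \code{"protein"}.
#' @export
setClass("CellCycleModel",
  representation(params = "numeric", variant = "character"),
  prototype(variant = "mrna"))

setValidity("CellCycleModel", function(object) {
  p <- object@params
  if (!identical(names(p), .paramNames))
    return("params must be a named vector with the canonical parameter names")
  if (any(!is.finite(p))) return("all parameters must be finite")
  if (any(p[.rateNames] < 0)) return("rate constants must be >= 0")
  if (p[["n"]] < 1) return("Hill coefficient n must be >= 1")
  if (any(p[c("J3", "J4", "J5", "J7", "J8")] <= 0))
    return("Michaelis/Hill constants must be > 0")
  if (p[["cycb_div_threshold"]] <= 0)
    return("division threshold must be > 0")
  if (!object@variant %in% c("mrna", "protein"))
    return("variant must be 'mrna' or 'protein'")
  TRUE
})

#' Ornstein-Uhlenbeck noise channel
#'
#' One exponentially correlated noise process applied additively to a
#' transcription rate.  The noise strength \code{D} follows the
#' \eqn{D = 4 D' \Delta t} convention, so the underlying white-noise
#' intensity is \eqn{D' = D / (4 \Delta t)} and the stationary variance is
#' \eqn{D'/\tau}.
#'
#' @slot tau autocorrelation time (h).
#' @slot D noise strength (dimensionless, \eqn{D = 4 D' \Delta t}).
#' @slot Dprime underlying white-noise intensity \eqn{D' = D/(4\Delta t)}.
#' @slot dt simulation step (h).
#' @slot value current noise value (a.u./h).
#' @slot mode \code{"exact"} (unconditionally stable discrete OU update) or
#'   \code{"euler"} (literal Euler-Maruyama discretisation).
#' @export
setClass("OUProcess",
  representation(tau = "numeric", D = "numeric", Dprime = "numeric",
                 dt = "numeric", value = "numeric", mode = "character"))

setValidity("OUProcess", function(object) {
  if (object@tau <= 0) return("tau must be > 0")
  if (object@D < 0) return("D must be >= 0")
  if (object@dt <= 0) return("dt must be > 0")
  if (abs(object@Dprime - object@D / (4 * object@dt)) >
      1e-12 * max(1, object@Dprime))
    return("Dprime must equal D / (4 * dt)")
  if (!object@mode %in% c("exact", "euler"))
    return("mode must be 'exact' or 'euler'")
  TRUE
})

#' Simulated lineage forest
#'
#' The result of a lineage population simulation: one row per cell with
#' identity, ancestry, birth/division/G1 times, durations and inherited
#' transcription-rate multipliers, plus the resolved configuration.
#'
#' @slot cells data.frame with one row per simulated cell.
#' @slot config resolved simulation configuration (list).
#' @slot model the \linkS4class{CellCycleModel} that was simulated.
#' @slot clampCount number of transcription-term clamping events (the
#'   nonnegativity clamp \code{max(0, k + eps)}).
#' @slot notes character vector of warnings accumulated during the run.
#' @export
setClass("LineageForest",
  representation(cells = "data.frame", config = "list",
                 model = "CellCycleModel", clampCount = "numeric",
                 notes = "character"))

#' Duration pairs by lineage relationship
#'
#' Daughter-daughter (sister), mother-daughter and cousin-cousin duration
#' pairs extracted from a lineage forest.  D-D and C-C pairs are unordered
#' (stored once each); M-D pairs are ordered mother-first.
#'
#' @slot dd,md,cc two-column numeric matrices of duration pairs (h).
#' @slot durationKind \code{"T_cc"}, \code{"T_G1"} or \code{"T_SG2M"}.
#' @export
setClass("LineagePairSet",
  representation(dd = "matrix", md = "matrix", cc = "matrix",
                 durationKind = "character"))

#' Pearson correlations of lineage pairs
#'
#' Pearson correlation coefficients per relationship class together with the
#' pair counts and the cousin-mother-inequality score
#' \eqn{R_{CC} - R_{MD}}.  Undefined correlations (fewer than 3 pairs or zero
#' variance) are carried explicitly as \code{NA} with \code{defined = FALSE},
#' never silently coerced to a number.
#'
#' @slot r named numeric: Pearson R for \code{dd}, \code{md}, \code{cc}.
#' @slot n named integer pair counts.
#' @slot defined named logical; FALSE where the correlation is undefined.
#' @slot cmi \eqn{R_{CC} - R_{MD}} (NA unless both are defined).
#' @slot durationKind the duration the pairs were built from.
#' @slot replicate replicate index (NA outside replicate designs).
#' @export
setClass("LineageCorrelations",
  representation(r = "numeric", n = "integer", defined = "logical",
                 cmi = "numeric", durationKind = "character",
                 replicate = "numeric"))

setValidity("LineageCorrelations", function(object) {
  cls <- c("dd", "md", "cc")
  if (!identical(names(object@r), cls)) return("r must be named dd, md, cc")
  if (!identical(names(object@n), cls)) return("n must be named dd, md, cc")
  ok <- is.na(object@r) | (object@r >= -1 & object@r <= 1)
  if (!all(ok)) return("correlations must lie in [-1, 1]")
  if (any(object@n < 0)) return("pair counts must be >= 0")
  if (any(is.na(object@r) & object@defined))
    return("defined correlations cannot be NA")
  TRUE
})

setMethod("show", "CellCycleModel", function(object) {
  p <- object@params
  cat("CellCycleModel (", object@variant, " variant)\n", sep = "")
  cat("  GF = ", format(p[["GF"]]),
      ", division threshold = ", format(p[["cycb_div_threshold"]]), "\n", sep = "")
  cat("  ", length(p), " parameters; k1m = ", signif(p[["k1m"]], 4),
      ", k4 = ", signif(p[["k4"]], 4), ", k9 = ", signif(p[["k9"]], 4),
      "\n", sep = "")
})

setMethod("show", "OUProcess", function(object) {
  cat("OUProcess: tau = ", object@tau, " h, D = ", object@D,
      " (D' = ", signif(object@Dprime, 4), "), dt = ", object@dt,
      " h, mode = ", object@mode, "\n  value = ",
      signif(object@value, 4), "\n", sep = "")
})

setMethod("show", "LineageForest", function(object) {
  cells <- object@cells
  cat("LineageForest: ", length(unique(cells$lineage_id)), " lineages, ",
      nrow(cells), " cells (", sum(cells$completed), " completed, ",
      sum(cells$in_analysis), " in analysis set)\n", sep = "")
  cat("  horizon = ", object@config$horizon, " h, tau = ",
      object@config$tau, " h, D = ", object@config$D, "\n", sep = "")
})

setMethod("show", "LineagePairSet", function(object) {
  cat("LineagePairSet (", object@durationKind, "): ",
      nrow(object@dd), " D-D, ", nrow(object@md), " M-D, ",
      nrow(object@cc), " C-C pairs\n", sep = "")
})

setMethod("show", "LineageCorrelations", function(object) {
  fmt <- function(i) {
    if (object@defined[i]) sprintf("%.3f (n=%d)", object@r[i], object@n[i])
    else sprintf("undefined (n=%d)", object@n[i])
  }
  cat("LineageCorrelations (", object@durationKind, ")\n", sep = "")
  cat("  R_dd = ", fmt("dd"), "\n  R_md = ", fmt("md"),
      "\n  R_cc = ", fmt("cc"), "\n", sep = "")
  cat("  CMI score (R_cc - R_md) = ",
      if (is.na(object@cmi)) "undefined" else sprintf("%.3f", object@cmi),
      "\n", sep = "")
})
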