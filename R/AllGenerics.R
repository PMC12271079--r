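#' @rdname modelParams
#' @export
setGeneric("modelParams", function(object) standardGeneric("modelParams"))

#' @rdname modelParams
#' @export
setGeneric("modelParams<-", function(object, value) standardGeneric("modelParams<-"))

#' @rdname modelParams
#' @export
setGeneric("modelVariant", function(object) standardGeneric("modelVariant"))

#' @rdname cellTable
#' @export
setGeneric("cellTable", function(object, ...) standardGeneric("cellTable"))

#' @rdname pairCounts
#' @export
setGeneric("pairCounts", function(object) standardGeneric("pairCounts"))

#' @rdname correlations
#' @export
setGeneric("correlations", function(object) standardGeneric("correlations"))

#' @rdname correlations
#' @export
setGeneric("cmiScore", function(object) standardGeneric("cmiScore"))

#' Model parameter access
#'
#' Accessors for the parameter vector and variant of a
#' \linkS4class{CellCycleModel}.
#'
#' @param object a \code{CellCycleModel}.
#' @param value replacement named numeric vector.
#' @return \code{modelParams} returns the named parameter vector;
#'   \code{modelVariant} the variant string.
#' @name modelParams
#' @aliases modelParams,CellCycleModel-method
#' @export
setMethod("modelParams", "CellCycleModel", function(object) object@params)

#' @rdname modelParams
#' @export
setMethod("modelParams<-", "CellCycleModel", function(object, value) {
  object@params[names(value)] <- value
  validObject(object)
  object
})

#' @rdname modelParams
#' @export
setMethod("modelVariant", "CellCycleModel", function(object) object@variant)

#' Cell table of a lineage forest
#'
#' Returns the per-cell table of a \linkS4class{LineageForest}: identity,
#' ancestry, birth/G1-end/division times, durations (\code{T_cc},
#' \code{T_G1}, \code{T_SG2M}), inherited rate multipliers, completion flag
#' and analysis-set membership.
#'
#' @param object a \code{LineageForest}.
#' @param analysisOnly if TRUE, only the completed cells belonging to the
#'   analysis subset (the first \code{maxCellsUsed} completed cells).
#' @param ... unused.
#' @return a data.frame.
#' @name cellTable
#' @export
setMethod("cellTable", "LineageForest", function(object, analysisOnly = FALSE, ...) {
  cells <- object@cells
  if (analysisOnly) cells <- cells[cells$in_analysis, , drop = FALSE]
  cells
})

#' Pair counts per relationship class
#'
#' @param object a \code{LineagePairSet} or \code{LineageCorrelations}.
#' @return named integer vector (dd, md, cc).
#' @name pairCounts
#' @export
setMethod("pairCounts", "LineagePairSet", function(object) {
  c(dd = nrow(object@dd), md = nrow(object@md), cc = nrow(object@cc))
})

#' @rdname pairCounts
#' @export
setMethod("pairCounts", "LineageCorrelations", function(object) object@n)

#' Correlation values and CMI score
#'
#' @param object a \code{LineageCorrelations} result.
#' @return \code{correlations}: named numeric vector of Pearson coefficients
#'   (NA where undefined); \code{cmiScore}: the cousin-mother-inequality
#'   score \eqn{R_{CC} - R_{MD}}.
#' @name correlations
#' @export
setMethod("correlations", "LineageCorrelations", function(object) object@r)

#' @rdname correlations
#' @export
setMethod("cmiScore", "LineageCorrelations", function(object) object@cmi)
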