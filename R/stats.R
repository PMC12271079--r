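## lineage_stats: D-D / M-D / C-C pair extraction, Pearson correlations,
## the cousin-mother-inequality score, population heterogeneity, and
## bootstrap significance of correlation differences.

.durationColumn <- function(kind) {
  switch(kind, T_cc = "T_cc", T_G1 = "T_G1", T_SG2M = "T_SG2M",
         stop("durationKind must be one of T_cc, T_G1, T_SG2M"))
}

#' Extract lineage duration pairs
#'
#' Separates all daughter-daughter (sister), mother-daughter and
#' cousin-cousin pairs among the eligible cells of a lineage forest.
#' Sisters are the two daughters of one division; M-D pairs are ordered
#' mother-first; cousins are cells sharing a completed grandmother but
#' having different mothers (all cross-family combinations).  A cell enters
#' a pair only if it is eligible (completed, in the analysis set when
#' \code{analysisOnly}, and with a non-missing requested duration); the
#' shared grandmother of a cousin pair only needs to have completed —
#' her own duration does not enter the pair.
#'
#' @param forest a \linkS4class{LineageForest}, or a data.frame with columns
#'   \code{cell_id}, \code{parent_id}, \code{completed} and the duration
#'   columns (an externally supplied lineage table).
#' @param durationKind \code{"T_cc"}, \code{"T_G1"} or \code{"T_SG2M"}.
#' @param analysisOnly restrict pair members to the analysis subset
#'   (forest input only).
#' @return a \linkS4class{LineagePairSet}.
#' @export
extractPairs <- function(forest, durationKind = "T_cc", analysisOnly = TRUE) {
  col <- .durationColumn(durationKind)
  isForest <- is(forest, "LineageForest")
  cells <- if (isForest) cellTable(forest) else as.data.frame(forest)
  if (!all(c("cell_id", "parent_id", "completed", col) %in% names(cells)))
    stop("malformed lineage table: missing required columns")
  if (anyDuplicated(cells$cell_id)) stop("malformed forest: duplicate cell ids")
  if (any(!is.na(cells$parent_id) & cells$parent_id == cells$cell_id))
    stop("malformed forest: cell is its own parent")
  if (isForest &&
      any(!is.na(cells$parent_id) & !(cells$parent_id %in% cells$cell_id)))
    stop("malformed forest: orphan ancestry")

  eligible <- cells$completed & !is.na(cells[[col]])
  if (isForest && analysisOnly) eligible <- eligible & cells$in_analysis
  dur <- cells[[col]]
  names(dur) <- as.character(cells$cell_id)
  parent <- cells$parent_id
  names(parent) <- as.character(cells$cell_id)
  completedIds <- cells$cell_id[cells$completed]
  elig <- cells$cell_id[eligible]
  eligSet <- as.character(elig)

  dd <- md <- cc <- list()
  if (length(elig)) {
    momOf <- parent[eligSet]
    ## sisters: both daughters of one division eligible
    byParent <- split(elig, momOf)
    for (kids in byParent) {
      if (length(kids) == 2)
        dd[[length(dd) + 1]] <- c(dur[[as.character(kids[1])]],
                                  dur[[as.character(kids[2])]])
    }
    ## mother-daughter: eligible mother with each eligible child
    for (i in seq_along(elig)) {
      pm <- momOf[[i]]
      if (!is.na(pm) && as.character(pm) %in% eligSet)
        md[[length(md) + 1]] <- c(dur[[as.character(pm)]], dur[[eligSet[i]]])
    }
    ## cousins: shared completed grandmother, different mothers
    gm <- vapply(seq_along(elig), function(i) {
      pm <- momOf[[i]]
      if (is.na(pm) || !(as.character(pm) %in% names(parent))) return(NA_real_)
      as.numeric(parent[[as.character(pm)]])
    }, numeric(1))
    ok <- !is.na(gm) & gm %in% completedIds
    for (g in unique(gm[ok])) {
      ids <- elig[ok & gm == g]
      moms <- as.numeric(momOf[as.character(ids)])
      for (m1 in unique(moms)) for (m2 in unique(moms)) {
        if (m1 < m2) {
          for (a in ids[moms == m1]) for (b in ids[moms == m2])
            cc[[length(cc) + 1]] <- c(dur[[as.character(a)]],
                                      dur[[as.character(b)]])
        }
      }
    }
  }
  toMat <- function(l) {
    if (length(l)) do.call(rbind, l) else matrix(numeric(0), ncol = 2)
  }
  new("LineagePairSet", dd = toMat(dd), md = toMat(md), cc = toMat(cc),
      durationKind = durationKind)
}

#' Pearson correlation coefficient
#'
#' Sample covariance (N-1 denominator) over the product of sample standard
#' deviations.  With fewer than 3 pairs or (numerically) zero variance in
#' either argument the correlation is undefined and \code{NA} is returned
#' with a \code{"reason"} attribute — never a silent number.  Variance below
#' \code{(1e-6 |mean|)^2} counts as zero, so that degenerate populations
#' whose durations agree to integration accuracy are flagged rather than
#' correlated on roundoff noise.
#'
#' @param xs,ys numeric vectors of equal length.
#' @return the correlation in [-1, 1], or NA with attribute \code{"reason"}.
#' @examples
#' pearsonR(c(1, 2, 3, 4), c(2, 1, 4, 3))  # 0.6
#' @export
pearsonR <- function(xs, ys) {
  if (length(xs) != length(ys)) stop("length mismatch")
  n <- length(xs)
  if (n < 3)
    return(structure(NA_real_, reason = "fewer than 3 pairs"))
  mx <- mean(xs); my <- mean(ys)
  vx <- sum((xs - mx)^2) / (n - 1)
  vy <- sum((ys - my)^2) / (n - 1)
  degenerate <- function(v, m) v <= 0 || v < (1e-6 * (abs(m) + 1e-12))^2
  if (degenerate(vx, mx) || degenerate(vy, my))
    return(structure(NA_real_, reason = "zero variance"))
  r <- sum((xs - mx) * (ys - my)) / (n - 1) / sqrt(vx * vy)
  max(-1, min(1, r))
}

.classR <- function(mat, ordered, orientation) {
  n <- nrow(mat)
  if (!ordered && orientation == "symmetrized" && n > 0) {
    x <- c(mat[, 1], mat[, 2]); y <- c(mat[, 2], mat[, 1])
  } else {
    x <- mat[, 1]; y <- mat[, 2]
  }
  r <- pearsonR(x, y)
  list(r = as.numeric(r), defined = !is.na(r), n = n)
}

#' Correlation summary of a pair set
#'
#' Pearson correlation per relationship class and the CMI score
#' \eqn{R_{CC} - R_{MD}}.  For the unordered D-D and C-C classes the default
#' enters each pair in both orientations (symmetrized estimator, which is
#' orientation-free); \code{orientation = "single"} uses one random,
#' seeded orientation per pair instead.
#'
#' @param pairs a \linkS4class{LineagePairSet}.
#' @param orientation \code{"symmetrized"} or \code{"single"}.
#' @param seed seed for the random orientation (single mode only).
#' @param replicate replicate index carried through to the result.
#' @return a \linkS4class{LineageCorrelations}.
#' @export
correlationSummary <- function(pairs, orientation = c("symmetrized", "single"),
                               seed = 1L, replicate = NA_real_) {
  orientation <- match.arg(orientation)
  stopifnot(is(pairs, "LineagePairSet"))
  flip <- function(mat) {
    if (orientation == "single" && nrow(mat) > 1) {
      sw <- runif(nrow(mat)) > 0.5
      mat[sw, ] <- mat[sw, c(2, 1)]
    }
    mat
  }
  if (orientation == "single") set.seed(seed)
  dd <- .classR(flip(pairs@dd), FALSE, orientation)
  md <- .classR(pairs@md, TRUE, orientation)
  cc <- .classR(flip(pairs@cc), FALSE, orientation)
  r <- c(dd = dd$r, md = md$r, cc = cc$r)
  defined <- c(dd = dd$defined, md = md$defined, cc = cc$defined)
  cmi <- if (defined[["cc"]] && defined[["md"]]) r[["cc"]] - r[["md"]] else NA_real_
  new("LineageCorrelations", r = r,
      n = c(dd = dd$n, md = md$n, cc = cc$n),
      defined = defined, cmi = cmi,
      durationKind = pairs@durationKind, replicate = as.numeric(replicate))
}

#' Population-level duration statistics
#'
#' Sample mean, sample SD (N-1) and coefficient of variation of a duration
#' across the completed cells of the analysis set.
#'
#' @param forest a \linkS4class{LineageForest} or cell table.
#' @param durationKind \code{"T_cc"}, \code{"T_G1"} or \code{"T_SG2M"}.
#' @return list with \code{mean}, \code{sd} (h) and \code{cv}.
#' @export
populationStats <- function(forest, durationKind = "T_cc") {
  col <- .durationColumn(durationKind)
  cells <- if (is(forest, "LineageForest"))
    cellTable(forest, analysisOnly = TRUE) else as.data.frame(forest)
  d <- cells[[col]][cells$completed]
  d <- d[!is.na(d)]
  if (length(d) < 2) stop("need at least 2 completed cells")
  m <- mean(d); s <- sd(d)
  list(mean = m, sd = s, cv = s / m, n = length(d))
}

#' Bootstrap comparison of two correlations
#'
#' Resamples each pair set with replacement \code{nBoot} times (pairs
#' resampled jointly), Fisher-z-transforms the per-resample Pearson
#' coefficients and compares the two z samples with a two-sided Student's
#' t-test.  Resamples with undefined or degenerate (|R| = 1) correlations
#' are redrawn and counted.  Note that bootstrap replicates are not
#' independent samples, so the returned p-value is the protocol's
#' comparison statistic rather than an exact test level.
#'
#' @param pairsA,pairsB two-column matrices of duration pairs (h).
#' @param nBoot number of bootstrap resamples (default 500).
#' @param seed RNG seed; fixing it makes the p-value reproducible.
#' @return list with \code{p.value}, the mean bootstrap correlations
#'   \code{rA}, \code{rB}, and \code{nRedrawn}.
#' @export
bootstrapFisherTest <- function(pairsA, pairsB, nBoot = 500L, seed = 1L) {
  pairsA <- as.matrix(pairsA); pairsB <- as.matrix(pairsB)
  stopifnot(ncol(pairsA) == 2, ncol(pairsB) == 2, nBoot >= 2)
  set.seed(seed)
  nRedrawn <- 0L
  bootZ <- function(mat) {
    n <- nrow(mat)
    z <- numeric(nBoot)
    for (b in seq_len(nBoot)) {
      r <- NA_real_
      for (try in 1:1000) {
        idx <- sample.int(n, n, replace = TRUE)
        r <- pearsonR(mat[idx, 1], mat[idx, 2])
        if (!is.na(r) && abs(r) < 1 - 1e-12) break
        nRedrawn <<- nRedrawn + 1L
        r <- NA_real_
      }
      if (is.na(r)) stop("bootstrap resampling failed: degenerate pair set")
      z[b] <- atanh(r)
    }
    z
  }
  zA <- bootZ(pairsA)
  zB <- bootZ(pairsB)
  tt <- t.test(zA, zB, var.equal = TRUE)
  list(p.value = tt$p.value, rA = mean(tanh(zA)), rB = mean(tanh(zB)),
       nRedrawn = nRedrawn)
}

#' Aggregate correlations across replicates
#'
#' Mean and standard error of the mean per relationship class over a list
#' of replicate correlation results; undefined correlations are excluded
#' and counted.
#'
#' @param results list of \linkS4class{LineageCorrelations}.
#' @return data.frame with one row per class (dd, md, cc): mean, sem,
#'   number of replicates used, number undefined.
#' @export
replicateAggregate <- function(results) {
  stopifnot(length(results) >= 2)
  cls <- c("dd", "md", "cc")
  out <- lapply(cls, function(cl) {
    vals <- vapply(results, function(x) {
      if (x@defined[[cl]]) x@r[[cl]] else NA_real_
    }, numeric(1))
    used <- sum(!is.na(vals))
    data.frame(class = cl,
               mean = if (used) mean(vals, na.rm = TRUE) else NA_real_,
               sem = if (used >= 2) sd(vals, na.rm = TRUE) / sqrt(used) else NA_real_,
               nUsed = used, nUndefined = sum(is.na(vals)))
  })
  do.call(rbind, out)
}
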