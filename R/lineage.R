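## lineage_simulator: the four-step protocol — founder rate draws, noisy
## propagation, mitotic resetting, division with inheritance — producing
## lineage forests with per-cell cycle and phase durations.

#' Log-scale parameters of a lognormal with given mean and CV
#'
#' Returns \code{(mu, sigma)} such that the lognormal has mean exactly
#' \code{mean} and coefficient of variation exactly \code{cv}:
#' \eqn{\sigma^2 = \log(1 + cv^2)}, \eqn{\mu = \log(mean) - \sigma^2/2}.
#'
#' @param mean distribution mean (> 0).
#' @param cv coefficient of variation (>= 0).
#' @return named numeric vector \code{c(mu, sigma)}.
#' @export
lognormalParams <- function(mean, cv) {
  if (any(mean <= 0)) stop("mean must be > 0")
  if (any(cv < 0)) stop("cv must be >= 0")
  s2 <- log(1 + cv^2)
  c(mu = log(mean) - s2 / 2, sigma = sqrt(s2))
}

#' Draw founder transcription-rate multipliers
#'
#' Three independent lognormal draws (CycB, Cdc20, Cdh1 transcripts), each
#' with mean 1 and CV \code{initCV}, applied multiplicatively to the
#' transcript's baseline transcription constant(s); the two Cdc20
#' transcription terms share one multiplier.  Draws use R's RNG.
#'
#' @param initCV coefficient of variation of the founder rate distribution.
#' @return numeric length-3 multiplier vector.
#' @export
drawInitialMultipliers <- function(initCV = 0.05) {
  if (initCV == 0) return(c(1, 1, 1))
  lp <- lognormalParams(1, initCV)
  rlnorm(3, lp[["mu"]], lp[["sigma"]])
}

#' Apply mitotic transcription-rate resetting
#'
#' For each transcript independently, the multiplier is increased by the
#' reset magnitude if a uniform draw exceeds 0.5 and decreased otherwise
#' (a draw of exactly 0.5, a measure-zero event, counts as a decrease).
#'
#' @param multipliers numeric length-3 multiplier vector.
#' @param magnitude reset magnitude (fraction in [0, 1)).
#' @param u optional uniform draws (length 3); drawn from R's RNG when
#'   missing.
#' @return the reset multiplier vector.
#' @export
applyMitoticResetting <- function(multipliers, magnitude = 0.10, u = NULL) {
  if (magnitude < 0 || magnitude >= 1) stop("magnitude must be in [0, 1)")
  if (is.null(u)) u <- runif(length(multipliers))
  multipliers * ifelse(u > 0.5, 1 + magnitude, 1 - magnitude)
}

#' Simulation configuration
#'
#' Resolved configuration for a lineage population run.  Defaults follow the
#' reference protocol: 100 lineages followed for 72 h over at most 3
#' divisions, founder transcription rates drawn with 5% CV, +/-10% mitotic
#' resetting, correlations computed from the first 300 completed cells.
#'
#' @param horizon simulation end time (h).
#' @param nLineages number of independent founder cells.
#' @param maxCellsUsed size of the analysis set (completed cells).
#' @param initCV CV of the founder lognormal rate distributions.
#' @param resetMagnitude mitotic resetting magnitude (fraction).
#' @param resetEnabled logical; disable for the no-resetting control.
#' @param resetMode \code{"mother"} (one reset at division, shared by both
#'   daughters; the default, which leaves sister correlations untouched) or
#'   \code{"daughter"} (independent resets per daughter).
#' @param tau OU autocorrelation time (h).
#' @param D OU noise strength (\eqn{D = 4 D' \Delta t} convention).
#' @param dt noise/integration step (h).  The D values quoted from the
#'   reference protocol assume dt = 0.01 h.
#' @param nsub RK4 substeps per dt.
#' @param GF growth-factor level override (NA = use the model's).
#' @param maxGenerations number of division rounds simulated.
#' @param masterSeed integer seed; together with the config it fully
#'   determines the run.
#' @param replicateIndex replicate number (enters the seed derivation).
#' @param ouMode \code{"exact"} or \code{"euler"}.
#' @param ouInit founder noise initialisation: \code{"stationary"} draws
#'   from the stationary distribution, \code{"zero"} starts at 0.
#' @param ouInherit if TRUE daughters start from the mother's current
#'   noise values (fluctuation continuity); the default FALSE restarts the
#'   daughters' fluctuations at zero — the inherited quantity is the
#'   transcription-rate multiplier, and each cell explores its own
#'   fluctuation history.
#' @param inheritance \code{"halved"} (default): all state variables are
#'   halved at division, the literal equal distribution of cellular content
#'   between the daughters; \code{"intensive"}: daughters carry the
#'   mother's concentrations unchanged.
#' @param randomizedInit multiply founder state variables by independent
#'   lognormal factors (CV \code{randomizedInitCV}) as a robustness control.
#' @param randomizedInitCV CV of the founder-state perturbation.
#' @param founderLead founders start on the deterministic limit cycle this
#'   many hours before the division point, so their first (partial) cycle
#'   ends quickly and three full generations fit into the horizon.  The
#'   founder's partial segment is excluded from duration statistics.
#' @param channelWeights length-4 multipliers on the white-noise intensity
#'   D' of the individual noise channels (CycB, Cdc20 basal, Cdc20 induced,
#'   Cdh1), for per-channel overrides of the common noise strength.
#' @param armFactor division is only detected after CycB has exceeded
#'   \code{armFactor * cycb_div_threshold} since birth (guards against
#'   re-triggering on the birth state).
#' @return a list with class \code{"simConfig"}.
#' @export
simConfig <- function(horizon = 72, nLineages = 100, maxCellsUsed = 300,
                      initCV = 0.05, resetMagnitude = 0.10,
                      resetEnabled = TRUE,
                      resetMode = c("mother", "daughter"),
                      tau = 10, D = 0.03, dt = 0.01, nsub = 4L, GF = NA,
                      maxGenerations = 3L, masterSeed = 1L,
                      replicateIndex = 1L,
                      ouMode = c("exact", "euler"),
                      ouInit = c("stationary", "zero"), ouInherit = FALSE,
                      inheritance = c("halved", "intensive"),
                      randomizedInit = FALSE, randomizedInitCV = 0.2,
                      founderLead = 2, armFactor = 3,
                      channelWeights = c(1, 1, 1, 1)) {
  cfg <- list(horizon = horizon, nLineages = as.integer(nLineages),
              maxCellsUsed = as.integer(maxCellsUsed), initCV = initCV,
              resetMagnitude = resetMagnitude, resetEnabled = resetEnabled,
              resetMode = match.arg(resetMode), tau = tau, D = D, dt = dt,
              nsub = as.integer(nsub), GF = GF,
              maxGenerations = as.integer(maxGenerations),
              masterSeed = as.integer(masterSeed),
              replicateIndex = as.integer(replicateIndex),
              ouMode = match.arg(ouMode), ouInit = match.arg(ouInit),
              ouInherit = ouInherit, inheritance = match.arg(inheritance),
              randomizedInit = randomizedInit,
              randomizedInitCV = randomizedInitCV, founderLead = founderLead,
              armFactor = armFactor, channelWeights = channelWeights)
  stopifnot(cfg$horizon > 0, cfg$initCV >= 0,
            cfg$resetMagnitude >= 0, cfg$resetMagnitude < 1,
            cfg$tau > 0, cfg$D >= 0, cfg$dt > 0, cfg$nLineages >= 1,
            cfg$founderLead >= 0)
  class(cfg) <- "simConfig"
  cfg
}

.cfgUpdate <- function(cfg, ...) {
  upd <- list(...)
  cfg[names(upd)] <- upd
  do.call(simConfig, unclass(cfg))
}

#' Propagate one cell to division
#'
#' Advances a single cell from its birth state with operator splitting (OU
#' update once per \code{dt}, four RK4 substeps while the noise is held
#' constant) until the first armed downward crossing of the CycB division
#' threshold, located within the step by linear interpolation, or until the
#' horizon.  The G1 end is the first local maximum of the X reporter.
#'
#' @param model a \code{CellCycleModel}.
#' @param state birth state.
#' @param multipliers per-transcript rate multipliers.
#' @param ou0 initial values of the four noise channels.
#' @param cfg a \code{\link{simConfig}}.
#' @param t0 birth time (h).
#' @param cellIndex integer identifying the cell's private noise stream.
#' @return list with \code{t_div}, \code{t_g1} (NA when not reached),
#'   \code{y_div}, \code{ou_div}, \code{y_end} and the clamp count.
#' @export
propagateCell <- function(model, state, multipliers = c(1, 1, 1),
                          ou0 = c(0, 0, 0, 0), cfg = simConfig(), t0 = 0,
                          cellIndex = 1L) {
  Dp <- noiseStrengthToDprime(cfg$D, cfg$dt) * channelDprimeScale(model) *
    cfg$channelWeights
  res <- .cc_propagate(unname(modelParams(model)), as.numeric(state),
                       as.numeric(multipliers), as.numeric(ou0), cfg$tau,
                       Dp, cfg$dt, cfg$nsub, t0, cfg$horizon,
                       cfg$masterSeed, cfg$replicateIndex,
                       as.integer(cellIndex),
                       if (cfg$ouMode == "exact") 0L else 1L,
                       .variantCode(modelVariant(model)), cfg$armFactor)
  names(res$y_div) <- names(res$y_end) <- .stateNames(modelVariant(model))
  res
}

#' Simulate a population of cell lineages
#'
#' Runs the full four-step protocol: founder transcription rates are drawn
#' from lognormal distributions (step i), propagated with colored noise
#' during cycle progression (step ii), reset by +/- \code{resetMagnitude} at
#' mitosis (step iii), and passed on at division, when the mother's state is
#' inherited by both daughters (step iv).  Founders start synchronized at
#' the post-division point of the deterministic limit cycle.  Completed
#' cells (division within the horizon; a division resolved within the
#' integration step containing the horizon counts) form the analysis set:
#' whole lineages are taken in order until \code{maxCellsUsed} completed
#' cells are collected.
#'
#' @param model a \code{CellCycleModel} (typically
#'   \code{\link{baselineModel}()}).
#' @param cfg a \code{\link{simConfig}}.
#' @return a \linkS4class{LineageForest}.
#' @export
simulateLineages <- function(model, cfg = simConfig()) {
  stopifnot(is(model, "CellCycleModel"), inherits(cfg, "simConfig"))
  if (!is.na(cfg$GF)) {
    p <- modelParams(model); p[["GF"]] <- cfg$GF; model@params <- p
  }
  runSeed <- (cfg$masterSeed + 1000003 * cfg$replicateIndex) %% 2147483647L
  set.seed(runSeed)
  y0 <- .founderState(model, lead = cfg$founderLead,
                      division = cfg$inheritance)
  nms <- .stateNames(modelVariant(model))
  Dp1 <- noiseStrengthToDprime(cfg$D, cfg$dt) * channelDprimeScale(model) *
    cfg$channelWeights
  sdStat <- sqrt(Dp1 / cfg$tau)

  notes <- character(0)
  nClamp <- 0
  cap <- 2 * (2^(cfg$maxGenerations + 1) - 1) * cfg$nLineages
  rec <- list(cell_id = integer(cap), lineage_id = integer(cap),
              parent_id = integer(cap), generation = integer(cap),
              t_birth = numeric(cap), t_g1_end = numeric(cap),
              t_division = numeric(cap), mult_cycb = numeric(cap),
              mult_cdc20 = numeric(cap), mult_cdh1 = numeric(cap),
              completed = logical(cap))
  nrow_ <- 0L
  ## FIFO queue of cells awaiting propagation
  queue <- vector("list", cap)
  qhead <- 1L; qtail <- 0L
  nextId <- 1L
  pushCell <- function(lineage, parent, gen, t0, y, mult, ou) {
    qtail <<- qtail + 1L
    queue[[qtail]] <<- list(id = nextId, lineage = lineage, parent = parent,
                            gen = gen, t0 = t0, y = y, mult = mult, ou = ou)
    nextId <<- nextId + 1L
  }
  for (L in seq_len(cfg$nLineages)) {
    mult <- if (cfg$initCV > 0) drawInitialMultipliers(cfg$initCV) else c(1, 1, 1)
    ou <- if (cfg$ouInit == "stationary" && cfg$D > 0) rnorm(4) * sdStat else rep(0, 4)
    yF <- y0
    if (cfg$randomizedInit) {
      lp <- lognormalParams(1, cfg$randomizedInitCV)
      yF <- yF * rlnorm(length(yF), lp[["mu"]], lp[["sigma"]])
      if ("IEP" %in% names(yF)) yF[["IEP"]] <- min(yF[["IEP"]], 1)
    }
    pushCell(L, NA_integer_, 0L, 0, yF, mult, ou)
  }

  while (qhead <= qtail) {
    cell <- queue[[qhead]]; qhead <- qhead + 1L
    res <- propagateCell(model, cell$y, cell$mult, cell$ou, cfg,
                         t0 = cell$t0, cellIndex = cell$id)
    nClamp <- nClamp + res$clamped
    completed <- !is.na(res$t_div) && res$t_div <= cfg$horizon + 0.5 * cfg$dt
    tg1 <- res$t_g1
    if (completed && is.na(tg1))
      notes <- c(notes, sprintf("cell %d: no X peak before division (G1 undetected)",
                                cell$id))
    nrow_ <- nrow_ + 1L
    rec$cell_id[nrow_] <- cell$id
    rec$lineage_id[nrow_] <- cell$lineage
    rec$parent_id[nrow_] <- cell$parent
    rec$generation[nrow_] <- cell$gen
    rec$t_birth[nrow_] <- cell$t0
    rec$t_g1_end[nrow_] <- if (completed) tg1 else NA_real_
    rec$t_division[nrow_] <- if (completed) res$t_div else NA_real_
    rec$mult_cycb[nrow_] <- cell$mult[1]
    rec$mult_cdc20[nrow_] <- cell$mult[2]
    rec$mult_cdh1[nrow_] <- cell$mult[3]
    rec$completed[nrow_] <- completed
    if (completed && cell$gen < cfg$maxGenerations) {
      mult <- cell$mult
      if (cfg$resetEnabled && cfg$resetMode == "mother")
        mult <- applyMitoticResetting(mult, cfg$resetMagnitude)
      m1 <- m2 <- mult
      if (cfg$resetEnabled && cfg$resetMode == "daughter") {
        m1 <- applyMitoticResetting(mult, cfg$resetMagnitude)
        m2 <- applyMitoticResetting(mult, cfg$resetMagnitude)
      }
      yD <- res$y_div
      if (cfg$inheritance == "halved") {
        ## concentrations are halved by equal distribution of content; the
        ## IEP active fraction (total normalised to 1) is carried over
        iep <- yD[["IEP"]]
        yD <- yD / 2
        yD[["IEP"]] <- iep
      }
      ouD <- if (cfg$ouInherit) res$ou_div else rep(0, 4)
      pushCell(cell$lineage, cell$id, cell$gen + 1L, res$t_div, yD, m1, ouD)
      pushCell(cell$lineage, cell$id, cell$gen + 1L, res$t_div, yD, m2, ouD)
    }
  }

  cells <- as.data.frame(lapply(rec, function(v) v[seq_len(nrow_)]))
  cells$T_cc <- cells$t_division - cells$t_birth
  cells$T_G1 <- cells$t_g1_end - cells$t_birth
  cells$T_SG2M <- cells$T_cc - cells$T_G1
  ## founders start mid-cycle: their partial first segment is not a cycle
  ## duration
  founder <- cells$generation == 0L
  cells$full_cycle <- !founder
  cells[founder, c("T_cc", "T_G1", "T_SG2M")] <- NA_real_
  ## analysis set: whole lineages in order until maxCellsUsed completed
  ## full-cycle cells
  cells <- cells[order(cells$lineage_id, cells$t_birth, cells$cell_id), ]
  rownames(cells) <- NULL
  compl <- cells$completed & cells$full_cycle
  cumc <- cumsum(compl)
  cells$in_analysis <- compl & cumc <= cfg$maxCellsUsed
  nAvail <- sum(compl)
  if (nAvail < cfg$maxCellsUsed) {
    msg <- sprintf("only %d completed full-cycle cells available (requested %d)",
                   nAvail, cfg$maxCellsUsed)
    notes <- c(notes, msg)
    warning(msg)
  }
  new("LineageForest", cells = cells, config = unclass(cfg), model = model,
      clampCount = nClamp, notes = notes)
}

#' Export a lineage forest as phylogenetic trees
#'
#' Converts each lineage tree into an \pkg{ape} \code{phylo} object with
#' branch lengths equal to cell-cycle durations (incomplete cells get their
#' observed lifespan up to the horizon) and labels equal to cell ids, e.g.
#' for Newick export with \code{ape::write.tree}.
#'
#' @param forest a \linkS4class{LineageForest}.
#' @return a named list of \code{phylo} objects (one per lineage with at
#'   least one division).
#' @export
forestToPhylo <- function(forest) {
  cells <- cellTable(forest)
  horizon <- forest@config$horizon
  out <- list()
  for (L in unique(cells$lineage_id)) {
    cl <- cells[cells$lineage_id == L, ]
    if (nrow(cl) < 3) next
    len <- ifelse(cl$completed, cl$T_cc, horizon - cl$t_birth)
    newick <- function(id) {
      kids <- cl$cell_id[!is.na(cl$parent_id) & cl$parent_id == id]
      br <- len[match(id, cl$cell_id)]
      if (!length(kids)) sprintf("%d:%.6g", id, br)
      else sprintf("(%s,%s)%d:%.6g", newick(kids[1]), newick(kids[2]), id, br)
    }
    root <- cl$cell_id[is.na(cl$parent_id)]
    out[[as.character(L)]] <- ape::read.tree(text = paste0(newick(root), ";"))
  }
  out
}
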