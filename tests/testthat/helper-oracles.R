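## Shared helpers: an independent hand-coded RHS oracle, synthetic lineage
## tables, and a brute-force pair scan.

## Independent re-implementation of the ODE right-hand sides, written
## directly from the reaction scheme (kept separate from the compiled code
## it checks).
oracleRHS <- function(y, p, eps = c(0, 0, 0, 0), mult = c(1, 1, 1)) {
  g <- p[["GF"]] / (p[["Kmm"]] + p[["keff"]] * p[["GF"]])
  hill <- y[["CycB"]]^p[["n"]] / (p[["J5"]]^p[["n"]] + y[["CycB"]]^p[["n"]])
  mod <- p[["J5c"]] / (p[["k5cm"]] + p[["GF"]])
  tx <- function(base, e) max(0, base + e)
  c(CycBm = tx(mult[1] * p[["k1m"]], eps[1]) * g - p[["k1dm"]] * y[["CycBm"]],
    CycB = p[["k1"]] * y[["CycBm"]] - p[["k2a"]] * y[["CycB"]] -
      p[["k2b"]] * y[["CycB"]] * y[["Cdh1"]],
    Cdc20m = tx(mult[2] * p[["k5am"]], eps[2]) +
      tx(mult[2] * p[["k5bm"]], eps[3]) * mod * hill -
      p[["k5dm"]] * y[["Cdc20m"]],
    Cdc20T = p[["k5a"]] * y[["Cdc20m"]] - p[["k6"]] * y[["Cdc20T"]],
    Cdc20A = p[["k7"]] * y[["IEP"]] * (y[["Cdc20T"]] - y[["Cdc20A"]]) /
      (p[["J7"]] + y[["Cdc20T"]] - y[["Cdc20A"]]) -
      p[["k8"]] * p[["Mad"]] * y[["Cdc20A"]] / (p[["J8"]] + y[["Cdc20A"]]) -
      p[["k6"]] * y[["Cdc20A"]],
    Cdhm = tx(mult[3] * p[["k3m"]], eps[4]) - p[["k3dm"]] * y[["Cdhm"]],
    Cdht = p[["k3a"]] * y[["Cdhm"]] - p[["k3dt"]] * y[["Cdht"]],
    Cdh1 = (p[["k3"]] + p[["k3b"]] * y[["Cdc20A"]]) *
      (y[["Cdht"]] - y[["Cdh1"]]) / (p[["J3"]] + y[["Cdht"]] - y[["Cdh1"]]) -
      p[["k4"]] * y[["CycB"]] * y[["Cdh1"]] / (p[["J4"]] + y[["Cdh1"]]) -
      p[["k3dt"]] * y[["Cdh1"]],
    IEP = p[["k9"]] * y[["CycB"]] * (1 - y[["IEP"]]) - p[["k10"]] * y[["IEP"]],
    X = p[["k11"]] - p[["k12"]] * y[["CycB"]] * y[["X"]] - p[["k13"]] * y[["X"]])
}

oracleRHSProtein <- function(y, p, eps = c(0, 0, 0, 0), mult = c(1, 1, 1)) {
  g <- p[["GF"]] / (p[["Kmm"]] + p[["keff"]] * p[["GF"]])
  hill <- y[["CycB"]]^p[["n"]] / (p[["J5"]]^p[["n"]] + y[["CycB"]]^p[["n"]])
  mod <- p[["J5c"]] / (p[["k5cm"]] + p[["GF"]])
  tx <- function(base, e) max(0, base + e)
  c(CycB = tx(mult[1] * p[["k1m"]], eps[1]) * g - p[["k2a"]] * y[["CycB"]] -
      p[["k2b"]] * y[["CycB"]] * y[["Cdh1"]],
    Cdc20T = tx(mult[2] * p[["k5am"]], eps[2]) +
      tx(mult[2] * p[["k5bm"]], eps[3]) * mod * hill - p[["k6"]] * y[["Cdc20T"]],
    Cdc20A = p[["k7"]] * y[["IEP"]] * (y[["Cdc20T"]] - y[["Cdc20A"]]) /
      (p[["J7"]] + y[["Cdc20T"]] - y[["Cdc20A"]]) -
      p[["k8"]] * p[["Mad"]] * y[["Cdc20A"]] / (p[["J8"]] + y[["Cdc20A"]]) -
      p[["k6"]] * y[["Cdc20A"]],
    Cdht = tx(mult[3] * p[["k3m"]], eps[4]) - p[["k3dt"]] * y[["Cdht"]],
    Cdh1 = (p[["k3"]] + p[["k3b"]] * y[["Cdc20A"]]) *
      (y[["Cdht"]] - y[["Cdh1"]]) / (p[["J3"]] + y[["Cdht"]] - y[["Cdh1"]]) -
      p[["k4"]] * y[["CycB"]] * y[["Cdh1"]] / (p[["J4"]] + y[["Cdh1"]]) -
      p[["k3dt"]] * y[["Cdh1"]],
    IEP = p[["k9"]] * y[["CycB"]] * (1 - y[["IEP"]]) - p[["k10"]] * y[["IEP"]],
    X = p[["k11"]] - p[["k12"]] * y[["CycB"]] * y[["X"]] - p[["k13"]] * y[["X"]])
}

randomState <- function(variant = "mrna") {
  if (variant == "mrna")
    c(CycBm = runif(1, 0, 3), CycB = runif(1, 0, 1), Cdc20m = runif(1, 0, 3),
      Cdc20T = runif(1, 0, 2), Cdc20A = runif(1, 0, 1), Cdhm = runif(1, 0, 3),
      Cdht = runif(1, 0, 1.5), Cdh1 = runif(1, 0, 1), IEP = runif(1),
      X = runif(1, 0, 3))
  else
    c(CycB = runif(1, 0, 1), Cdc20T = runif(1, 0, 2), Cdc20A = runif(1, 0, 1),
      Cdht = runif(1, 0, 1.5), Cdh1 = runif(1, 0, 1), IEP = runif(1),
      X = runif(1, 0, 3))
}

## complete binary lineage table with nDiv division rounds; every cell
## completed with a full-cycle duration
completeTreeTable <- function(nDiv, durations = NULL) {
  nCells <- 2^(nDiv + 1) - 1
  ids <- seq_len(nCells)
  parent <- c(NA, floor(ids[-1] / 2))
  gen <- floor(log2(ids))
  if (is.null(durations)) durations <- 20 + seq_len(nCells)
  data.frame(cell_id = ids, parent_id = parent, generation = gen,
             completed = TRUE, T_cc = durations, T_G1 = durations * 0.4,
             T_SG2M = durations * 0.6)
}

## random lineage table: random subtree of a binary tree, random completion
randomTreeTable <- function(maxCells = 31, pKeep = 0.8, pComplete = 0.85) {
  full <- completeTreeTable(ceiling(log2(maxCells + 1)) - 1)
  keep <- rep(FALSE, nrow(full))
  keep[1] <- TRUE
  for (i in 2:nrow(full)) {
    keep[i] <- keep[full$parent_id[i]] && runif(1) < pKeep
  }
  tab <- full[keep, , drop = FALSE]
  tab$completed <- runif(nrow(tab)) < pComplete
  ## cells with children must be completed (they divided)
  hasKids <- tab$cell_id %in% tab$parent_id
  tab$completed[hasKids] <- TRUE
  tab$T_cc <- round(runif(nrow(tab), 15, 30), 3)
  tab$T_G1 <- tab$T_cc * 0.4
  tab$T_SG2M <- tab$T_cc * 0.6
  tab
}

## brute-force all-pairs ancestry scan (independent of extractPairs)
bruteForcePairs <- function(tab, col = "T_cc") {
  eligible <- tab$completed & !is.na(tab[[col]])
  ids <- tab$cell_id[eligible]
  parentOf <- function(id) tab$parent_id[match(id, tab$cell_id)]
  completedSet <- tab$cell_id[tab$completed]
  counts <- c(dd = 0L, md = 0L, cc = 0L)
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    a <- ids[i]; b <- ids[j]
    if (a == b) next
    pa <- parentOf(a); pb <- parentOf(b)
    if (i < j && !is.na(pa) && !is.na(pb) && pa == pb)
      counts["dd"] <- counts["dd"] + 1L
    if (!is.na(pb) && pb == a)   # a mother of b
      counts["md"] <- counts["md"] + 1L
    if (i < j && !is.na(pa) && !is.na(pb) && pa != pb) {
      ga <- parentOf(pa); gb <- parentOf(pb)
      if (!is.na(ga) && !is.na(gb) && ga == gb && ga %in% completedSet)
        counts["cc"] <- counts["cc"] + 1L
    }
  }
  counts
}

## single cached baseline model for the whole test session
testBaseline <- local({
  m <- NULL
  function() {
    if (is.null(m)) m <<- baselineModel()
    m
  }
})
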