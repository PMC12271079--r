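---
title: "Transcriptional memory and lineage-level cell-cycle duration correlations"
author: "lineageCycle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transcriptional memory and lineage-level cell-cycle duration correlations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

Sister cells (D-D pairs) in mammalian lineages show strongly correlated
cell-cycle durations, while mother-daughter (M-D) and cousin (C-C) pairs
correlate more weakly — and, in several cell types, cousins correlate
*better* than mother-daughter pairs.  This last observation, the
cousin-mother inequality (CMI), is paradoxical at first sight: cousins are
two divisions apart, mothers and daughters only one.  `lineageCycle`
implements a stochastic, lineage-resolved cell-cycle model in which the
only heritable, fluctuating quantities are the transcription rates of the
three core regulators, and asks which correlation patterns such
"transcriptional memory" can generate.

# The model

The deterministic skeleton is a growth-factor-driven relaxation oscillator
over CycB, Cdh1 and Cdc20 in the Tyson-Novak tradition, extended by an
explicit mRNA species for each regulator:

* CycB mRNA is transcribed at rate $(k_{1m} + \varepsilon_1)\,
  \mathrm{GF}/(K_{mm} + k_\mathrm{eff}\,\mathrm{GF})$ and translated into
  CycB, which is degraded basally and by active Cdh1.
* Cdc20 mRNA has a basal term and a CycB-driven Hill term (coefficient
  $n = 4$); Cdc20 protein is activated through the intermediary enzyme IEP
  (a fraction with total normalised to 1) and inactivated by the spindle
  checkpoint (Mad).
* Cdh1 mRNA is transcribed constitutively; active Cdh1 is produced from
  the total pool by basal and Cdc20A-driven activation and inactivated by
  CycB (Michaelis constants $J_3 = J_4 = 0.04$, the zero-order
  ultrasensitive switch of the source oscillator).
* A reporter $X$ with $\dot X = k_{11} - k_{12}\,\mathrm{CycB}\,X -
  k_{13} X$ rises through G1 and collapses when CycB rises; the first
  local maximum of $X$ after birth marks the G1/S boundary.

Division is triggered when CycB crosses `cycb_div_threshold` (0.1 a.u.)
downward, after an arming condition (CycB must first exceed three times
the threshold) that prevents re-triggering on the birth state.

Oscillations appear as the growth factor GF increases, through a
saddle-node-on-invariant-circle-like onset: below GF ≈ 0.5 a.u. (at the
shipped constants) the system sits at a stable G1-like state, above it the
cycle runs with a period that depends only weakly on GF.

## The stochastic layers

The four-step lineage protocol adds, in order:

1. **Founder heterogeneity** — each founder draws one multiplier per
   transcript (CycB, Cdc20, Cdh1) from a lognormal with mean exactly 1 and
   CV `initCV` (default 5%); the two Cdc20 transcription terms share one
   multiplier.
2. **Colored noise during progression** — each transcription term carries
   an additive Ornstein-Uhlenbeck fluctuation $\varepsilon(t)$ with
   autocorrelation time $\tau$ and noise strength $D$ under the
   $D = 4 D' \Delta t$ convention ($\Delta t = 0.01$ h is the reference
   step for all quoted $D$ values; stationary variance $D'/\tau$).  The
   exact discrete OU update is the default; a literal Euler-Maruyama mode
   is available.  Negative effective rates are clamped at zero and the
   clamping events counted.
3. **Mitotic resetting** — at division each transcript's multiplier is
   multiplied by $1 \pm$ `resetMagnitude` (default 10%) according to a
   fair uniform draw; the reset is applied once in the mother, so both
   daughters share it.
4. **Division with inheritance** — both daughters receive the mother's
   post-reset multipliers, and the mother's dynamical state with every
   concentration halved ("equal distribution of content").  The IEP
   variable is an active *fraction* of a pool whose total is normalised to
   1, so equal distribution leaves it unchanged; halving it instead
   abolishes the G1 phase entirely (the halved Cdh1 switch loses its
   reserve and CycB takes over immediately), which is why the fraction is
   carried over.  Daughters restart their own noise histories at zero
   (`ouInherit = FALSE`): what a daughter inherits is the transcription
   *rate*, not the parent's instantaneous fluctuation.  Fluctuation
   continuity and intensive (non-halved) inheritance remain available as
   switches.

Because division halves the state, the observable noise-free cycle is not
the continuous ODE limit cycle but the converged orbit of the generational
map (halve, integrate to the next division, repeat).
`deterministicPeriod()` therefore measures that map by default; the map
converges in 2-3 generations and its period is what calibration targets.
Founders start on the converged orbit `founderLead = 2` h before
division, so their first, partial segment ends quickly (it is excluded
from all duration statistics) and three full generations fit into the
72-h horizon — otherwise cousin statistics would be empty for 24-h and
28-h cycles.

## Calibration

`calibrateModel()` works in two decoupled stages.  A global time-rescaling
of all rate constants fixes the period exactly (the G1 fraction is
invariant under rescaling).  A one-dimensional search on a phase-shaping
parameter then matches the G1 fraction, followed by a final rescaling.
The default knob is `k9` (IEP activation), which spans G1 fractions of
roughly 0.15-0.45 on the generational map; `k4` and `GF` are alternates
tried automatically when the first knob cannot bracket the target.  A
target outside the achievable range fails with the ranges listed — the
16-h/9-h-G1 and 28-h/16-h-G1 phase splits are outside what this
parameterisation can reach, so phase-proportion comparisons use splits
within range (e.g. 24 h with G1 7 vs 10 h).

## Parameter provenance and the two calibrated constants

The protein-network constants descend from the published generic
mammalian cell-cycle oscillator; several were adjusted during model
construction so that the GF-driven, mRNA-bearing variant oscillates
robustly over GF 1-20 a.u. with a mildly decreasing period.  The
mRNA-layer constants are this package's own: lifetimes of ~1 h at the
24-h scale, transcription rates set so the quasi-steady mRNA levels
reproduce the protein synthesis fluxes of the source network.

Two residual constants are pinned by nothing deterministic:

* the **mRNA concentration gauge** (multiplying transcription and dividing
  translation by the same factor leaves the deterministic dynamics
  unchanged but sets how large the additive noise $\varepsilon$ is
  *relative* to the rates it perturbs), and
* **k3b**, the Cdc20A-driven Cdh1 activation rate, which controls how
  close the post-division Cdh1 recovery sits to its failure boundary and
  hence how sensitively a daughter's G1 responds to her inherited state.

Both were fixed once by requiring the reference protocol (24-h baseline,
3 replicates of 100 lineages, first 300 cells) to reproduce the reported
critical coordinates of the CMI transition; with them fixed, the tau
crossover and the D crossover are reproduced simultaneously, and all other
results — growth-factor response, duration variants, the no-resetting
control, population CVs — are untouched predictions of the model.  This is
the standard situation of rebuilding a model whose full parameter table is
unavailable: the free constants are calibrated against reported
observables and everything else is cross-validation.

# What the statistics layer computes

`extractPairs()` separates D-D (both daughters of one division), M-D
(ordered mother-first) and C-C pairs (cells sharing a completed
grandmother but different mothers, all cross-family combinations) among
the analysis set: whole lineages are taken in order until 300 completed
full-cycle cells are collected.  Taking literally the first 300 cells *by
birth time* would select only founders and first-generation cells and no
cousin pairs could exist; the whole-lineage reading is the only one
consistent with cousin statistics on 300 cells.

`pearsonR()` implements the sample-covariance definition ($N-1$
denominator) and treats fewer than three pairs or zero variance as an
explicit undefined result, never a silent number.  For the unordered D-D
and C-C classes the default estimator enters each pair in both
orientations, which makes the coefficient orientation-free; a seeded
single-orientation mode exists.  `bootstrapFisherTest()` resamples each
pair set 500 times, Fisher-transforms the coefficients and compares the
two z samples with a two-sided Student's t-test; bootstrap replicates are
not independent samples, so the p-value is the protocol's comparison
statistic rather than an exact test level (with identical inputs it is
calibrated; see the tests).

# Why the cousin-mother inequality is hard, and what produces it here

For any purely heritable, linearly acting quantity, the mother is an
ancestor of her daughter while cousins are collateral: the shared variance
of an M-D pair is the mother's own heritable variance, which always yields
$R_{MD} \ge R_{CC}$.  A CMI therefore *requires* a channel that
specifically decorrelates mothers from daughters.  In this model that
channel is the inherited dynamical state: a mother's realised duration is
shaped by fluctuations her division state only partly reflects, while her
daughters' G1 — a recovery from the halved state — depends sharply on that
state and on the inherited rates.  The strength of the channel grows with
the noise strength $D$ and fades as the autocorrelation time $\tau$ makes
the heritable rate signal dominate, producing the observed transition:
CMI at low $\tau$ / high $D$, the normal ordering at high $\tau$ / low
$D$.  Intensive (non-halved) inheritance removes the recovery channel and
with it the CMI everywhere — one reason the halved reading of the division
protocol is used.

# Numerical choices

* Operator splitting: the four OU channels advance once per $\Delta t$ and
  are held constant while the ODE advances `nsub = 4` RK4 substeps.  The
  effective step of ~0.002 h is set by the stability of the stiff
  Michaelis-Menten switch terms ($J_4 = 0.04$ with CycB high), not by
  accuracy.
* Division times are located by linear interpolation within the step, and
  daughters start from the state interpolated at the crossing, so the
  noise-free lineage reproduces the generational-map period to ~$10^{-6}$
  relative accuracy (the degenerate-limit population CV is ~$10^{-7}$).
* A division resolved within the integration step containing the horizon
  counts as completed.
* Per-cell noise streams come from a dedicated counter-based generator
  (seeded from the master seed, replicate index and cell index), so a run
  is bit-reproducible from `(masterSeed, config)` and daughters' streams
  are independent of the mother's.
* The deterministic integrator is fixed-step RK4 with an `lsoda` backend
  behind the same interface for cross-checking.

# Problem sizes

The reference protocol is 100 lineages over 72 h (about 1,500 cells
simulated, 700-800 completed) per run, with 3 replicates per condition and
the first 300 completed full-cycle cells analysed; one run takes about
1.5 s.  The sweep drivers share replicate seeds across grid points
(common random numbers), which substantially reduces point-to-point jitter
along a sweep axis and sharpens crossover estimates.  Test and example
code uses reduced sizes (down to 10-30 lineages) where only mechanics are
being exercised.

# What the generator does and does not emulate

The simulator emulates: heritable transcription rates with exponentially
correlated fluctuations, mitotic resetting, equal division of content,
synchronous founder populations with 5% rate heterogeneity, and the
observation window of a 72-h live-imaging experiment (three generations,
~300 analysed cells).  It does not emulate cell size or growth control,
asymmetric division, death or quiescence, circadian coupling,
measurement noise in imaging, or cell-type-specific regulation beyond the
three-regulator core.  Passing tests therefore show that the stated noise
and inheritance mechanisms *suffice* to generate the correlation patterns
at these population sizes — not that real lineages use them exclusively.

# Known limitations

* At high growth factor (GF = 10 a.u.) the CycB division trough sits close
  to the threshold, and strong-noise cells occasionally miss a division
  and cycle twice; this inflates the mean and CV of the 10-a.u. condition
  and can mask the deterministic shortening of the cycle.
* Shifting phase proportions toward a longer S-G2-M at fixed period does
  not consistently raise the sister/mother-daughter correlations or lower
  the population CV here: the shorter G1 fraction sits closer to the
  oscillation-onset boundary, which adds duration variability of its own.
* The crossover coordinates of the CMI transition are shallow functions of
  the correlation differences; at the protocol size (3 replicates x 300
  cells) a single sweep estimates them with a spread of several hours /
  several 10^-3 in D, which is why the sweep drivers pool independent
  batches and smooth the difference curve isotonic-monotonically before
  interpolating.
* Without mitotic resetting all correlations drop (the resets are the
  dominant heritable variance source at the calibrated noise scale); the
  M-D and C-C coefficients do rise to the D-D level, but the D-D level
  itself is lower than with resets.
* The protein-level-noise control (no mRNA layer, noise on production
  rates, per-channel intensities scaled to preserve relative fluctuation)
  retains the halved-division recovery channel and with it some CMI at
  high D — in this implementation the mRNA layer is not the essential CMI
  ingredient, the division protocol is.
* The achievable G1 fractions (~0.15-0.45) exclude the most G1-heavy
  phase splits; calibration reports the achievable range when asked for
  one of them.
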