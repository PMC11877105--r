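---
title: "Methods: quantifying neutrophil function in pneumonia cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying neutrophil function in pneumonia cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neutrofun)
```

`neutrofun` turns the raw outputs of three neutrophil-function assays —
manual-tracking coordinates from migration time-lapses, extracellular-flux
plate time series, and per-cell cytometry event tables — into subject-level
summaries, and runs the two-group statistical workflow such cohort studies
report. This vignette documents the models, the tunable parameters, the
numerical decisions, and what the synthetic-data generators do and do not
emulate.

## Chemotaxis metrics

A track is an ordered list of 2-D positions at a fixed frame interval; the
migration protocol emulated throughout is one image every 20 s for 12 min
(37 frames). From the step vectors $\mathbf{s}_i$ and a unit gradient
direction $\mathbf{g}$:

* **Chemotactic index**: mean of $\cos\angle(\mathbf{s}_i, \mathbf{g})$
  over steps. Zero-length steps have no direction and are *excluded* from
  the mean rather than counted as zeros, which would shrink the index for
  cells that pause; the excluded count is reported (`n_zero_steps`). If
  every step has zero length the index is undefined and returned as `NA`
  with a warning — never silently 0.
* **Directness**: net displacement over total path length, in $[0, 1]$;
  undefined (`NA`) for a cell that never moves.
* **Speed** and **velocity**: total path length, and net displacement
  projected on $\mathbf{g}$, per elapsed minute. The denominator is the
  *observed* $t_{last} - t_{first}$, not the nominal 12 min, so tracks
  truncated by a cell leaving the field are summarised honestly. Velocity
  is signed (positive toward the source): $|velocity| \le speed$ always.

Aggregation is mean-of-steps per cell, then unweighted mean over cells per
subject, so long tracks do not dominate the subject value and each cell
contributes equally — matching assays that report one dot per participant.
Cells with fewer than `min_steps` steps (default 10, about 3 min of
observation) are dropped from the subject mean, as very short tracks carry
almost no directional information; the filtered count is reported.

Two conventions the tracking export does not record are configuration,
not inference: the gradient direction (default $(0, 1)$, "up" toward the
chemoattractant well) and the pixel size (`um_per_pixel`, default 1,
applied at read time so all computation is in µm).

All metrics are translation-invariant and rotation-equivariant (rotating
positions and gradient together changes nothing); the test suite asserts
this to $10^{-9}$ on random tracks, and checks the chemotactic index
against an independent per-step loop to $10^{-12}$.

## Extracellular-flux kinetics

ECAR (mpH/min) is a surrogate of lactate efflux; converting it to a proton
efflux rate corrects for the buffering capacity of the medium:

$$\mathrm{PER\ [pmol\ H^+/min]} = \mathrm{ECAR} \times BF \times V \times K_{vol}$$

with defaults $BF = 2.6$ mmol H⁺/L/pH, $V = 2.28$ µL, $K_{vol} = 1.6$ —
the standard instrument constants for the glycolytic-rate assay medium, all
overridable in the run configuration for other media.

* **Basal glycolysis** is the PER of the *last* measurement strictly before
  the PMA injection — a single measurement, not a baseline-window mean,
  so a drifting baseline contributes its most recent value.
* **Fold change** is the maximum PER in the open window (PMA, oligomycin)
  divided by basal. The peak convention is the default because the response
  plateaus within the window and the peak is insensitive to how much of
  the rising phase the window happens to contain; a mean-over-window switch
  (`method = "mean"`) is provided.
* **QC flags**: the post-oligomycin level is compared with the level
  attained just before oligomycin (the stimulated plateau, not the mean of
  the still-rising PMA window — using the window mean would flag every
  well with a normal rise). A fractional change above `qc_tol` (default
  0.15) flags mitochondrial contribution; mean post-2DG PER above
  `qc_tol` × basal flags incomplete inhibition. Negative rates are flagged
  but never clipped or removed.
* **Burst kinetics**: total O₂ is the trapezoidal integral of OCR from the
  PMA injection to the last timepoint; peak OCR is the post-PMA maximum
  (first maximum on ties); time to peak is reported relative to the PMA
  injection by default, with `time_ref = "absolute"` for the assay clock,
  since published figures are ambiguous between the two (values of
  ~100–151 min suggest absolute time may have been used there). A peak on
  the final timepoint is flagged right-censored. Integration from the PMA
  injection (not assay start) is the default because rotenone/antimycin A
  suppress mitochondrial O₂ uptake beforehand; an optional pre-PMA
  baseline subtraction is available.

## Cytometry summaries

Viability quadrants follow the AnV/PI map (viable AnV−/PI−, early
apoptotic AnV+/PI−, late apoptotic AnV+/PI+, necrotic AnV−/PI+); the four
fractions are mutually exclusive and sum to exactly 1 by construction.
Percent-positive for a surface marker uses a gate at the 99th percentile of
the matched isotype control — an isotype is mandatory, since any default
gate would silently decide the result; MFI is the median fluorescence of
all events. Neutrophil maturity is the fraction of events double-positive
for CD66b and CD10, each gated on its own isotype.

## Cohort statistics

Each continuous variable is gated by Shapiro–Wilk at $\alpha = 0.05$ in
*both* groups: the parametric path uses Student's equal-variance two-sample
t-test and mean (SD) summaries, the nonparametric path Mann–Whitney and
median (IQR). Equal-variance Student is the default (the convention of the
point-and-click workflows these studies use); Welch is available via
`var_equal = FALSE`. Groups too small to test (< 3 values) or with zero
variance fall back to the nonparametric path with a warning; two groups
with all values identical return $p = 1$ by convention. Categorical
variables use the two-sided Fisher's exact test with the probability-mass
ordering (the p-value sums all tables with the observed margins at most as
probable as the observed one); a zero margin gives $p = 1$. Missing values
are excluded pairwise per variable. No multiple-comparison adjustment is
applied by default, matching the planned-comparisons convention of these
cohorts; `adjust = "BH"` adds a Benjamini–Hochberg column.

The sample-size calculator uses the two-sided normal approximation
$n = 2\sigma^2(z_{1-\alpha/2} + z_{power})^2 / \Delta^2$ with
$\Delta = \mu \times$ fractional reduction, returning both the unrounded
value and a nearest-integer rounding (the convention that reproduces the
published 10-per-arm calculation from mean 0.30, SD 0.13, 62% reduction,
$\alpha$ 0.05, power 0.90; ceiling rounding is available).

## Synthetic-data generators

The generators exist so every stage of the pipeline is testable, with known
ground truth, without any deposited data. One root seed expands to
per-component substreams (`substream_seed()`), so adding a generator never
perturbs existing streams; the same seed reproduces output byte-for-byte.

* **Tracks** are biased random walks: step direction von Mises around the
  gradient with concentration $\kappa$, step length gamma (default mean
  1 µm per 20 s step, shape 2, i.e. a realistic ~3 µm/min with
  moderate step-length variability). The expected chemotactic index has
  the closed form $I_1(\kappa)/I_0(\kappa)$, which the tests use for
  parameter recovery; $\kappa = 0$ is the unbiased negative-control
  chamber. The von Mises sampler is the Best–Fisher rejection algorithm,
  implemented in-package and validated against the same closed form. A
  hierarchical variant draws per-subject $\kappa$ from a gamma hyperprior
  (default CV 0.3) so subject-level indices show realistic between-donor
  spread.
* **Glycolysis curves** are piecewise in PER: basal plateau; saturating
  exponential rise after PMA (default rate 0.1/min, a ~10 min time
  constant, rising over several measurement cycles as real wells do)
  normalised to attain exactly basal × fold at the last pre-oligomycin
  measurement, which makes noise-free recovery of the generating fold
  exact; optional mitochondrial component (a fraction of the glycolytic
  signal) removed after oligomycin; exponential collapse after 2-DG;
  Gaussian noise on the PER scale. Defaults sit at the control-group scale
  (basal 114 pmol/min, fold 3.4).
* **Burst curves** are single gamma-shaped OCR pulses with specified peak,
  mode and width after PMA; the pulse area has a closed form
  (`burst_pulse_area()`) used to validate the trapezoidal integral.
* **Cohorts** draw each variable independently per group: normal from mean
  and SD, lognormal parameterised from a printed median and IQR (meanlog
  from the median, sdlog from the IQR ratio — the direct way to match a
  median (IQR) summary), categorical from level probabilities.

What passing tests on these generators shows — and what it does not: the
generators reproduce the *statistical structure* the analysis assumes
(directional bias, assay phases, single-peak bursts, group separations at
published effect sizes), so the tests demonstrate that the estimators
recover known parameters under that structure at the stated rates. Real
data add features the generators deliberately omit: cell–cell collisions
and tracking errors, persistence (correlated step directions), well-to-well
plate effects and injection artefacts, spectral spillover and non-lognormal
fluorescence, and correlated clinical covariates. Conclusions about such
features need real inputs; the package validates the computation, not the
biology.

## Problem sizes and calibration checks

The test suite sizes its simulations for tight closed-form comparisons at
modest cost: 500 tracks for Bessel-ratio recovery (3-SE criterion), 100
seeds for noisy flux recovery, 1 000 replicates at n = 15/arm for the
dispatcher's type-I calibration (observed rejection must fall in 3–7% at
$\alpha = 0.05$), and 100 seeds at the published chemotactic-index
separation (N(0.31, 0.13²) n = 23 vs N(0.14, 0.03²) n = 14, d ≈ 1.8) where
at least 99 of 100 must reject — at that effect size the analytical power
is ≈ 0.997.

## Known limitations

* Tracks arrive as coordinates: no image processing, cell detection or
  track linking, and no modelling of the chamber's gradient shape.
* The flux module does not model instrument calibration or mitochondrial
  stress-test parameters (neutrophils' mitochondrial respiration is too low
  to measure in this assay).
* Cytometry event tables arrive as CSV; FCS parsing and compensation are
  out of scope.
* The statistics harness covers two-group comparisons; survival or
  regression modelling of clinical outcomes is out of scope.
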