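---
title: "Methods: modeling binary and graded cone opsin patterning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modeling binary and graded cone opsin patterning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(conemosaic)
```

## The biological problem

Mouse cone photoreceptors express two photopigments — S-opsin (UV/blue
sensitive) and M-opsin (green sensitive) — in a striking dorsal–ventral
(D-V) pattern. Profiling individual cones along the full D-V axis shows two
distinct subtypes:

* **S-only cones** express S-opsin at a high, position-independent level and
  no M-opsin. They make up roughly 1% of cones at the dorsal edge and
  20–30% ventrally.
* **Co-expression-competent (CEC) cones** express M- and/or S-opsin at
  graded, position-dependent levels: M decreases gradually dorsal to
  ventral, while S switches on extremely sharply at a transition point.
  Fitted as Hill functions of position, the S-expressing fraction has a
  coefficient near 30 and the M-expressing fraction near 2–3.

The package implements both halves of the quantitative story: the
image-analysis/profiling pipeline that measures these patterns from
two-channel fluorescence data, and a multiscale stochastic model that
explains them through a single morphogen input — thyroid hormone (T3) —
read out differently by a binary fate decision and by graded expression.
Because the original image data are not public, a first-class synthetic
generator reproduces the statistical structure of the measurements so every
stage is testable end to end.

## The synthetic retina generator

`generate_cell_table()` emulates a 6,000 × 600 µm strip: a jittered
hexagonal mosaic (8 µm spacing, 15% positional jitter), a binary fate per
cone, and per-channel intensities.

Design choices worth making explicit:

* **The expressing-fraction curves are the primitive.** The parameters
  `s_fraction_hill_n = 30` and `m_fraction_hill_n = 2.5` describe the
  *observable* total expressing fractions, because those are the quantities
  the imaging pipeline measures and fits. The conditional Bernoulli
  probabilities for CEC cones are derived from these targets by removing
  the S-only contribution (`cec_s_probability()` etc.), so profiling a
  default table recovers the stated coefficients rather than a distorted
  composite.
* **S-only probability interpolant.** No functional form is measured for
  the gradual S-only rise, only its endpoints (~1% dorsal, ~20–30%
  ventral) and the ~8–20% observed in a window around the transition. A
  Hill-type curve with coefficient 4 and midpoint at the S transition
  satisfies all three simultaneously; gentler coefficients cannot hold the
  dorsal-most millimetre at 1% while reaching the ventral plateau.
* **Censored-lognormal intensities.** CEC expression presence and level
  come from one latent lognormal draw per channel, censored at the
  detection threshold (20 a.u., matching the default classification
  thresholds): a cone "expresses" a channel exactly when its latent level
  exceeds the threshold, and the latent location parameter is chosen so the
  presence probability equals the Hill-curve target at every position. This
  keeps the fraction curves exact *and* makes intensities pass continuously
  through the detection limit, as real immunofluorescence does. An earlier
  design that drew presence and level independently produced an artificial
  density void between background and expressing intensities, which
  fragmented density-based clustering into spurious sub-clusters — a
  structure real data do not show.
* **What is not emulated:** retinal curvature and whole-mount distortions,
  temporal–nasal gradients (minimal in the data), rods, illumination
  fields, and spatial correlations in fate assignment beyond the mosaic
  geometry. Passing tests therefore demonstrate the pipeline's correctness
  on data with the right marginal statistics, not robustness to every
  artifact of real microscopy.
* The optional `dorsal_s_enhancement` can raise the S-only level dorsally
  (a feature visible in real intensity data) but defaults to off, matching
  the model's assumption of position-independent constitutive S expression.

```{r generator-example}
tab <- generate_cell_table(generator_params(
  strip_length_um = 2000, strip_width_um = 150, seed = 1
))
dplyr::count(tab, fate_truth)
```

## Profiling: classification, fits, clustering

* `classify_cells()` thresholds each channel (default 20 a.u. ≈ background
  mean + 3 SD on default tiles).
* `fit_hill()` fits `base + amplitude · Hill(y; midpoint, n)` by bounded
  Levenberg–Marquardt least squares, multi-started over n ∈ {1, 5, 20, 50}
  with n ∈ [0.3, 150]; the Hill core is evaluated as a logistic in log
  space so n = 150 cannot overflow. Unweighted least squares is used
  throughout. Degenerate (flat) profiles are flagged, never silently
  fitted.
* **Estimator precision.** On tables of the default size (~65,000 cells,
  100 µm bins), binomial sampling noise and bin averaging bias the fitted
  S coefficient slightly downward: repeated draws give roughly 28 ± 1
  against a generative coefficient of 30, and the acceptance tests state
  their tolerances accordingly. The M coefficient (true 2.5) is recovered
  as ~2.5 ± 0.1.
* `cluster_cells()` implements hierarchical density-based clustering
  (k-nearest-neighbour core distances, mutual-reachability single-linkage,
  condensed tree, excess-of-mass selection) because no such clustering
  package is available in this R installation. Three defaults differ from
  common practice and are deliberate, because the CEC manifold is elongated
  with a strong density gradient along the D-V axis and fine-grained
  settings let the excess-of-mass criterion carve stable sub-pockets out of
  a continuous manifold: `min_cluster_size` is 4% of cells,
  `min_samples = 25`, and — the decisive one — `min_split_gap = 15`
  intensity units, a floor below which a density dip never creates
  clusters (the analogue of the selection-epsilon refinement of this
  algorithm family; 15 a.u. is below the S-only/CEC separation, which is
  of order 100 a.u., but above intra-manifold dips, which live at the
  intensity noise scale). At these settings the default table yields the
  two phenotype clusters (S-only band vs CEC manifold) stably across
  subsample seeds. A single-cluster solution is allowed (the tree root is
  selectable), so unimodal data return 1 cluster rather than noise.
* `transition_stats()` evaluates the CEC fraction and its analytic slope at
  the fitted S midpoint. The CEC fraction is computed among **all** cells
  (not only expressing ones), and the slope comes from differentiating the
  fitted four-parameter (decreasing) Hill curve. When ground-truth fates
  are absent, CEC membership falls back to the non-S-only cluster, then to
  a threshold rule.

## Segmentation

The per-channel pipeline is: robust 1st/99.5th-percentile normalization →
grayscale opening at 1/3 of the expected cell radius (removes small bright
debris) → local-maximum seed detection with a minimum separation → an
independent region-based morphological active contour per seed (a
region-competition update toward the half-max level set of the local peak
over the exterior median, alternated with morphological opening/closing
smoothing, initialized as a 3 µm circle, capped at 200 iterations; the
half-max criterion sizes outer segments where a plain interior/exterior
mean competition settles well outside half-max) → validation
(area ∈ [5, 80] µm², solidity ≥ 0.8, interior mean ≥ background mean + 3
SD, no border contact) → cross-channel reconciliation by pixel-set
intersection-over-union (≥ 0.3 merges into one cell).

Background statistics are estimated by iterative sigma clipping because at
mosaic density bright pixels can cover half the tile, which defeats a plain
median/MAD estimate; for the same reason the contour's exterior reference
level is a median, and the seed-peak prominence threshold is derived from
the background (mean + 5 SD) rather than fixed — lognormal-bright cells
would otherwise compress the percentile stretch and push dim outer
segments below a fixed cutoff. Contours touching the image border are
rejected: truncated outer segments would bias both area and intensity.

`density_map()` reproduces the low-resolution binned analysis: 25 × 25 px
bins, per-bin pixel counts of S-only / M-only / co-expressing signal
normalized by expressing pixels.

## The multiscale simulator

A 5,000 × 1,000 × 5 µm strip holds 23,760 cones on a hexagonal lattice
(330 positions along the D-V axis × 72 rows; within-row spacing ≈ 15.2 µm,
row pitch ≈ 13.9 µm — the pitch is 6% wider than the regular hexagonal
value so the stated cell count tiles the stated strip exactly; each interior
cell's nearest neighbour is still at exactly one spacing). T3 diffuses
deterministically (explicit 5-point finite differences, 50 µm node grid)
with constant-concentration dorsal/ventral boundaries — T3 is high dorsally
— and zero-flux sides. Cells exchange T3 molecules stochastically with
their local voxel, and each cone runs an exact Gillespie (direct method)
simulation of the nine-reaction fate/expression network documented in
`?sim_config`.

Numerical and structural choices:

* **Operator splitting.** Each macro step (0.5 s, well inside the
  stability bound h²/4D = 6.25 s) advances the field, then the exchange
  process, then each cell's SSA against a frozen local concentration.
* **Initialization.** The field starts at its analytic steady ramp (the
  adult gradient is maintained; its developmental establishment is out of
  scope). Cells start undifferentiated with zero opsin but at *hormonal
  equilibrium* (Poisson T3, binomial receptor occupancy at the local
  concentration). A cold start with zero T3 everywhere would transiently
  run the U→S propensity at its ceiling in every cell — an artifact of the
  split initial condition, not of the biology — and measurably inflates
  the dorsal S-only fraction above the ~1% target.
* **Extrinsic expression noise.** Opsin production propensities are scaled
  by per-cell lognormal capacity factors (CV 0.5, independent per gene).
  Without them, "expressing" is a hard threshold on a Poisson count and the
  M fraction collapses over a ~100 µm window (an effective Hill
  coefficient far above the S transition's), inverting the observed order
  of sharpness. Broad per-cell expression capacity is the standard
  extrinsic component of gene-expression noise and matches the wide
  per-bin intensity spread in real data. `capacity_cv = 0` restores the
  bare network.
* **Reproducibility.** Every cell derives a counter-based RNG stream from
  (seed, cell id, macro step), so results are bit-reproducible and
  independent of evaluation order; ensembles use seeds `base_seed + run`.
* **Units.** Concentrations are relative (the absolute intracellular T3
  level is unknown); one opsin molecule maps to one intensity unit
  (`intensity_scale`), and rates are per second with `phi = 0.025` setting
  the opsin lifetime (40 s) that low-pass-filters receptor fluctuations.

### Calibration recipe

No rate constants are published for this network; the shipped defaults were
produced by calibrating against the mean-retina target curves (the five
Hill-parameter summaries of the default generator: S/M expressing
fractions, S-only fraction, mean S/M intensities), in this order:

1. Exchange and binding (`k_exchange_in/out`, `k_on/k_off`,
   `thrb2_total = 200`) set the receptor-activation profile A(y): ~50%
   occupancy dorsally falling to ~5% ventrally, with relaxation times
   (~1 s) far below the opsin lifetime so expression averages over the
   fluctuations.
2. Expression rates (`beta_*`, `phi`) set the intensity scales (S-only
   ≈ 600, dorsal M ≈ 400, ventral CEC S ≈ 285 a.u.).
3. `K_Srep` places the emergent S transition midpoint; `h_Srep` is raised
   until the *emergent* S-fraction Hill coefficient matches ≈ 30 (the
   effective value is limited by receptor-noise smearing, which is why the
   microscopic coefficient is much larger than the observed one).
4. The fate stage (`K_fate`, `h_fate`, `k_fateS_max/k_fateC = 1/3`) is set
   so the S-only fraction runs from ~1% (dorsal-most mm) through ~12% at
   the midpoint to ~24% (ventral-most mm).

`calibrate()` automates the final polish: derivative-free Nelder–Mead over
chosen log-rates (±2 decades), each evaluation simulating a width-reduced
strip (the D-V axis carries all structure, so the width — not the length —
is reduced; a shortened strip would relocate every transition) under common
random numbers. `variability_ensemble()` then reproduces the
100-perturbed-runs protocol used for retina-to-retina variability, and
`distribution_overlap()` (kernel densities, shared Silverman bandwidth on
the pooled sample) quantifies the agreement of transition statistics
between simulated and experiment-like ensembles.

### The receptor knockout

`knockout_thrb2()` disables receptor activation (`k_on = 0`). M-opsin
production is then exactly zero everywhere, and the S-expressing fraction
is flat along the axis — both observed in the knockout data. In this
reconstruction the knockout's CEC S level sits at the repression-free
ceiling (the wild-type ventral plateau); where that level falls relative to
the wild-type gradient depends on how the inactive receptor's S-promoting
arm is modeled when the protein is absent, which the available information
does not pin down.

## Problem sizes in the test suite

The tests run the full science at reduced scale: full-length strips at
100–200 µm width (≈ 2,300–4,600 cones) for simulation checks, ~16,000-cell
synthetic strips for profiling, 120 µm tiles for segmentation round trips,
and ensembles of 5–16 runs where distributions are compared. These sizes
keep every emergent feature (both transitions, the fate gradient, the
knockout contrast) measurable; the full 23,760-cone strip differs only by
narrower confidence intervals.

## Known limitations

* The reaction scheme is a reconstruction from the published network
  diagram; rate constants are calibrated, not measured, so only emergent,
  dimensionless features (fractions, transition positions and shapes,
  sharpness ordering) are meaningful — absolute times and counts are not.
* The fitted Hill coefficient of a sharp transition is a noisy, slightly
  downward-biased estimator at realistic cell counts (~28 ± 1 for a
  generative 30); comparisons should use the documented spread.
* The PDE–SSA coupling is first-order (operator splitting); this is
  adequate here because the field is quasi-stationary, but a rapidly
  changing field would warrant a higher-order reconciliation.
* Segmentation assumes well-separated outer segments at the default
  density; heavily overlapping mosaics would need joint (not per-seed)
  inference.
* T4 transport, enzymatic T3 production, retinoic-acid co-gradients, 3D
  geometry, and the developmental time course of the gradient are out of
  scope; the adult steady gradient is taken as given.
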