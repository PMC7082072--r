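# conemosaic

Quantitative analysis and multiscale stochastic modeling of cone
photoreceptor opsin patterning along the dorsal–ventral (D-V) axis of the
mouse retina.

Mouse cones express S-opsin (UV/blue) and M-opsin (green) in opposing D-V
gradients. Profiled at single-cell resolution, the mosaic resolves into two
subtypes: **S-only cones** (high, position-independent S-opsin; ~1% of
cones dorsally rising to ~20–30% ventrally) and **co-expression-competent
(CEC) cones**, whose M-opsin declines gradually dorsal→ventral while their
S-opsin switches on extremely sharply. Written as Hill functions of D-V
position `y`,

```
fraction(y) = base + amplitude · yⁿ / (midpointⁿ + yⁿ)
```

the S-expressing fraction has coefficient n ≈ 30 and the M-expressing
fraction n ≈ 2–3. The package is for computational biologists who want to
(a) measure such patterns from two-channel fluorescence images or per-cell
tables and (b) test mechanistic explanations with a hybrid
deterministic–stochastic tissue model.

It provides four connected layers:

1. **Synthetic retina generator** — ground-truth cell tables
   (`generate_cell_table()`) and rendered two-channel TIFF tiles
   (`render_tiles()`) with the measured statistical structure, so the whole
   pipeline is testable without the (non-public) imaging data.
2. **Segmentation** — per-channel normalization, small-feature suppression,
   seed detection, independent region-based active contours with
   validation, and cross-channel reconciliation (`segment_tile()`), plus
   the binned expression density maps (`density_map()`).
3. **Profiling** — classification (`classify_cells()`), D-V fraction and
   intensity profiles, four-parameter Hill transition fits (`fit_hill()`,
   with broom-style `tidy()`/`glance()` and `autoplot()`), retina alignment
   on the S midpoint (`align_tables()`), joint intensity distributions,
   density-based clustering (`cluster_cells()`), and transition statistics
   (`transition_stats()`).
4. **Simulator + calibration** — a hybrid multiscale model
   (`run_simulation()`): deterministic T3 diffusion over the strip
   (explicit finite differences, constant-concentration D-V boundaries)
   coupled to an exact Gillespie simulation of each of 23,760 cones, whose
   reaction network implements T3–Thrβ2 binding, a repressible binary
   U→S / U→C fate decision, and graded opsin expression (activation of M
   and repression of S by active Thrβ2). `knockout_thrb2()` models the
   receptor knockout; `calibrate()`, `variability_ensemble()` and
   `distribution_overlap()` fit and compare the model against mean-retina
   target curves.

## Worked example

Generate the default mean-retina synthetic strip, classify it, and fit the
two expressing-fraction transitions:

```r
library(conemosaic)

tab <- generate_cell_table(generator_params(seed = 1))
tab <- classify_cells(tab)
tab
#> # A cell_table: 64950 cells (source: synthetic, strip 6000 x 600 um)

s_fit <- fit_hill(fraction_profile(tab, "s"), direction = "increasing")
m_fit <- fit_hill(fraction_profile(tab, "m"), direction = "decreasing")
s_fit
#> <hill_fit: increasing> base=0.03187 amplitude=0.9654 midpoint=3613 n=26.23
m_fit
#> <hill_fit: decreasing> base=0.01064 amplitude=0.9608 midpoint=3028 n=2.416
```

The S transition is an order of magnitude sharper than the M transition
(n ≈ 26 vs ≈ 2.4 here; the fitted S coefficient scatters around 27.5 ± 1
for a generative value of 30 at this table size — pooling retinas, as
`scripts/acceptance.R` does, stabilizes it), and its midpoint (~3,600 µm)
is the alignment reference for comparing retinas. Density-based clustering
resolves the two cone subtypes:

```r
cluster_cells(tab)
#> <cluster_result> 2 cluster(s), 4576/64950 points noise (min size 2598)
```

Run the calibrated simulator on a width-reduced strip and measure the
binary fate gradient it produces:

```r
cfg <- sim_config(domain_um = c(length = 5000, width = 200, depth = 5))
sim <- run_simulation(cfg, seed = 11)
mean(sim$fate_truth[sim$y_um < 1000] == "S_ONLY")   # dorsal-most 1 mm
#> [1] 0.006493506
mean(sim$fate_truth[sim$y_um >= 4000] == "S_ONLY")  # ventral-most 1 mm
#> [1] 0.2662338
```

The model turns one smooth T3 gradient into both a gradual binary fate
gradient (~1% → ~25% S-only; a single narrow strip is binomially noisy —
the ensemble in `scripts/acceptance.R` pins the dorsal value at ~1%) and
the sharp/graded expression transitions,
and `transition_stats()` + `distribution_overlap()` quantify the coupling
of the two transitions through the shared gradient.

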