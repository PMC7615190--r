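# endomargin

Quantification of stochastic endoderm induction at the zebrafish embryo
margin.

Endodermal progenitors arise in the first two cell tiers of the early
zebrafish blastoderm margin when individual cells switch on *sox32* during
a Nodal-dependent competency window. Whether those cells are selected by
their signaling state or switch stochastically is a quantitative question:
it takes whole-embryo nuclear quantification, circular statistics on
progenitor positions, explicit stochastic models, and induction-probability
estimates conditioned on signaling levels to answer it. `endomargin`
packages that machinery for R users working on early-embryo imaging data:

- **3D nuclear segmentation** of multi-channel confocal stacks: slice-wise
  adaptive thresholding intersected across three orientations, seeded
  watershed splitting on the blurred DAPI landscape, morphological opening,
  removal of dim (mean DAPI < 1000) and flat (`1.25 * V < SA`) objects, and
  per-nucleus mean intensities for every channel
  (`segment_nuclei()`, `measure_nuclei()`).
- **Margin geometry**: periodic-spline fit of the blastoderm/YSL boundary,
  angular position phi of every nucleus (dorsal = 0), YSL exclusion
  (beyond-margin or within 5 um of the locally lowest nucleus in Z), dorsal
  forerunner cell exclusion with rescaled positions
  `psi = 180 - 1.25 (180 - phi)` (phi > 0; mirrored for phi < 0), and cell
  tiers (`fit_margin_spline()`, `assign_marginal_position()`, `flag_ysl()`,
  `exclude_and_rescale_dfc()`, `assign_tiers()`).
- **Circular statistics**: per-embryo direction vectors and direction bias
  (mean resultant length), 15-degree angular histograms, and Watson's U2
  test of circular uniformity with Monte-Carlo or asymptotic p-values
  (`direction_summary()`, `watson_u2()`, `bin_angles()`).
- **A stochastic induction simulator**: an array of 500 founder cells over
  500 time steps, one division per random rank (growing to exactly 1000
  cells), per-step induction probability 0.00015, expression maintained and
  inherited, with the analytic oracle
  `E[positives] = N_final (1 - (1 - p)^T)` (`run_simulation()`,
  `simulate_ensemble()`, `expected_positive_count()`).
- **Signaling-conditional analysis**: background thresholds (99th
  percentile of tiers 9-10), elevated-P-Smad2 fractions in tiers 1-2,
  sliding-window (+/- 5% of range) proportions of sox32-positive cells,
  joint P-Smad2/P-Erk maps, and a maximum-likelihood fit of the per-step
  logistic induction hazard under the cumulative model
  `P = 1 - (1 - h)^T` (`background_threshold()`, `sliding_proportion()`,
  `joint_signaling_map()`, `fit_induction_hazard()`).
- **Robustness metrics** for late endoderm phenotypes: gut intensity
  profiles, RMS deviation from the untreated mean, early-vs-late
  dose-response robustness classification (`profile_deviation()`,
  `robustness_curve()`).
- **A seeded synthetic-data generator** (images, cell tables, gut profiles)
  with full ground truth, so the entire pipeline runs end-to-end with no
  external data (`generate_embryo_image()`, `generate_cell_table()`,
  `generate_gut_profiles()`, `run_pipeline()`).

## Worked example

```r
library(endomargin)

# one run of the margin induction simulator with the default scheme
res <- run_simulation(sim_params(seed = 1))
res
#> Margin simulation: 1000 final cells, 67 sox32-positive (p = 0.00015, 500 steps)
expected_positive_count(sim_params())
#> [1] 72.26173

# positions of the induction events around the margin: no spatial bias
ang <- induction_event_angles(res)
direction_summary(ang)
#> Direction summary: n = 52, bias = 0.1884, mean angle = 21.84 deg
watson_u2(ang)
#> Watson U2 test: U2 = 0.1410, p = 0.1229 (n = 52, asymptotic)

# signaling-conditional induction on a synthetic 10,000-cell table
gen <- generate_cell_table(synthetic_embryo_params(n_nuclei = 10000, seed = 1),
                           synthetic_signaling_params(seed = 1))
fit <- fit_induction_hazard(gen$table, n_steps = 100)
c(smad2 = fit$smad2_coef, erk = fit$erk_coef)
#>         smad2           erk
#>  7.596958e-04 -7.490549e-04   # generating truth: +8e-4 / -8e-4
```

The simulated run ends with exactly 1000 cells (500 founders, each dividing
once); 67 are sox32-positive against an expectation of 72.3, and the 52
distinct induction events show no directional bias (direction bias 0.19 for
52 events is typical of uniform placement, and Watson's U2 does not reject
uniformity). The hazard fit recovers both generating coefficients with the
correct sign to within a few percent.

A full synthetic image -> segmentation -> positions -> marker calling ->
circular statistics run, with per-stage CSV/TIFF outputs and a provenance
manifest:

```r
manifest <- run_pipeline(demo_config(seed = 1))
```

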