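# phenocrop

Phenology-based mapping of annual cropping patterns — cropping intensity
(0–3 growing cycles per year) plus the per-season identity of the three
staple cereals (paddy rice, wheat, maize) — from per-pixel 4-band
surface-reflectance time series at an 8-day cadence, the kind delivered by
moderate-resolution satellite composites.

**Who it is for.** Researchers in agricultural remote sensing who want a
self-contained, testable implementation of the operational
knowledge-based mapping chain: no training samples, no external archives —
a seeded scene simulator generates reflectance stacks with known
cropping-pattern ground truth so every stage can be exercised end to end.

## The method

Per pixel, the pipeline:

1. computes three spectral indices from red, NIR and two SWIR bands
   (≈1640 nm, ≈2130 nm):
   - EVI2 = 2.5(ρ_NIR − ρ_Red)/(ρ_NIR + 2.4ρ_Red + 1)
   - LSWI = (ρ_NIR − ρ_SWIR6)/(ρ_NIR + ρ_SWIR6)
   - NMDI = (ρ_NIR − (ρ_SWIR6 − ρ_SWIR7))/(ρ_NIR + (ρ_SWIR6 − ρ_SWIR7))
2. reconstructs daily trajectories from valid composites with a Whittaker
   smoother, (W + λD′D)z = Wy;
3. detects cropping intensity from a Mexican-hat continuous-wavelet
   spectrum of the daily EVI2 (strong brightness centres, skeleton widths
   and scale intervals), and segments the year into season windows;
4. labels each season with purity-stratified decision rules:
   - rice: LSWI_min > θ₁ and RCLE < θ₂, where
     RCLE = (LSWI_max − LSWI_min)/(EVI2_heading − EVI2_tillering);
   - wheat: EVE > θ₃ and EVL > θ₄, the EVI2 variation sums before and
     after a calendar-estimated heading date;
   - maize: RCPN > θ₅, the flowering-window ratio of cumulative positive
     to negative NMDI slopes,
     RCPN = (P_early + P_late)·N_late/(N_early + N_late + σ)·100;
   with θ₂ = {0.42, 0.52, 0.62}, θ₃ = {0.32, 0.24, 0.16},
   θ₅ = {0.45, 0.35, 0.25} for pure (>90% cropland), moderately mixed
   (50–90%) and seriously mixed (30–50%) pixels; θ₁ = 0.1, θ₄ = 0.12;
   pixels under 30% cropland are excluded;
5. encodes intensity + labels as integer pattern codes
   {0, 14, 15, 16, 17, 245, 246, 255, 256, 277, 3} (first digit =
   intensity; crop digits 4 maize, 5 rice, 6 wheat, 7 other), computes
   fraction-weighted sown areas, and assesses accuracy (OA, user's and
   producer's accuracy, F1, kappa) against ground-truth labels.

The methods vignette (`vignettes/cropping-pattern-mapping.Rmd`) documents
the model, every tunable constant, the simulator's design and its limits.

## Worked example

Simulate an 8×8 scene cycling through all eleven pattern codes under
degraded conditions (band noise 0.02, 20% cloud gaps), then map it:

```r
library(phenocrop)
codes <- pattern_code_table()$code
pm <- matrix(rep_len(codes, 64), 8, 8)
scene <- simulate_scene(scene_config(pm, noise_sd = 0.02, gap_rate = 0.2,
                                     seed = 42))
map <- run_pipeline(scene)
map
#> <pheno_map> 8x8 pixels
#> pattern codes: 0(6) 3(5) 14(6) 15(6) 16(6) 17(6) 245(5) 246(5) 255(5) 256(6) 277(8)
#> overall pattern accuracy vs truth: 95.31%
map$area
#>    crop area_ha
#> 1  rice     675
#> 2 wheat     425
#> 3 maize     400
#> 4 other     550
```

95.31% of pixels get their exact pattern code back under these conditions
(with clean input the recovery is exact); the area table applies the
per-season sown-area convention (a double-rice pixel counts twice for
rice) at a nominal 25 ha per pixel.

The accuracy machinery prints reports in the conventional layout; on the
package's benchmark ground-survey confusion matrix (18,379 reference
sites):

```r
accuracy_metrics(reference_site_matrix())
#> Accuracy assessment (18379 samples)
#>        rice wheat maize others Total PA(%)   F1
#> rice   5929    45    56    357  6387 92.83 0.91
#> wheat    78  2220   139    220  2657 83.55 0.87
#> maize   205    90  4216    151  4662 90.43 0.91
#> others  366    85   212   4010  4673 85.81 0.85
#> UA(%): rice=90.13  wheat=90.98  maize=91.2  others=84.63
#> Overall accuracy (%): 89.1   Kappa: 0.85
```

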