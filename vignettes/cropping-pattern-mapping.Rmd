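---
title: "Phenology-based cropping-pattern mapping: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenology-based cropping-pattern mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenocrop)
```

## The problem

Multiple cropping — growing two or three crops on the same field within one
year — is widespread in intensive agricultural regions, and mapping it
requires more than a crop-type map: each pixel needs a cropping *intensity*
(0–3 growing cycles per year) and a per-season crop identity. At moderate
resolution (~500 m, 8-day revisit) there are rarely enough training samples
for supervised classification over national extents, so the operational
approach is *phenology-based*: hand-crafted decision rules on vegetation-
and moisture-index trajectories that encode how each crop's life cycle
looks from space. `phenocrop` implements that whole chain — from raw
4-band reflectance series to coded cropping-pattern rasters and accuracy
reports — together with a simulator that generates reflectance scenes with
known ground truth, so every stage can be tested end to end without any
external archive.

## Spectral indices and daily reconstruction

Three indices are computed from red, NIR and the two shortwave-infrared
bands (≈1640 nm, "SWIR6"; ≈2130 nm, "SWIR7"):

* **EVI2** $= 2.5(\rho_{NIR}-\rho_{Red})/(\rho_{NIR}+2.4\rho_{Red}+1)$ —
  canopy greenness; the basis for intensity detection and season windows.
* **LSWI** $= (\rho_{NIR}-\rho_{SWIR6})/(\rho_{NIR}+\rho_{SWIR6})$ —
  surface water / canopy moisture; elevated while a paddy is flooded.
* **NMDI** $= (\rho_{NIR}-(\rho_{SWIR6}-\rho_{SWIR7}))/(\rho_{NIR}+(\rho_{SWIR6}-\rho_{SWIR7}))$
  — a drought/moisture index whose flowering-stage dynamics single out
  maize.

Valid (cloud-free) 8-day composites are interpolated to a daily grid with a
Whittaker smoother: solve $(W+\lambda D'D)z = Wy$ with observation weights
0/1 and a second-difference penalty. Invalid composites keep their grid
position with zero weight, so the penalty matrix never changes shape.

**Choice of $\lambda$.** No single $\lambda$ suits all three indices.
EVI2 and LSWI use $\lambda = 500$: on a 46-composite year this preserves
the bimodal structure of double cropping (higher values start to merge the
two peaks). NMDI uses $\lambda = 10{,}000$: NMDI is intrinsically far
noisier than the other two indices, because its denominator contains the
small difference $\rho_{SWIR6}-\rho_{SWIR7}$, and its classifier (RCPN,
below) *integrates day-to-day slopes*, so residual wiggle accumulates
directly into the metric. The heavy penalty suppresses slope noise while
the (broad) flowering excursion of maize survives. Both values are
configurable in `pipeline_config()`.

**Padding.** The mapping year is processed with ±~90 days of padding from
the adjacent years, because winter wheat is sown in the previous autumn
and its early-growth metrics need the pre-year trajectory. The daily grid
is `daily_grid()`, about 554 days; composites follow the 8-day calendar
that restarts at day 1 each year. Leap days are ignored.

**Data availability.** The fraction of valid in-season composites
(March–October) is classed good (>70%), medium (50–70%, inclusive at both
boundaries) or low (<50%) and reported per pixel; pixels with fewer than 8
valid composites in total are not classified and carry an explicit reason.

## Cropping intensity from wavelet spectra

The number of growing cycles is read from a Mexican-hat continuous wavelet
transform of the mean-centred daily EVI2 series. Working in the wavelet
plane rather than counting raw peaks makes the count robust to phenology
shifts and amplitude variation: a crop season appears as a compact
"brightness centre" — a local maximum of positive wavelet response — at a
scale matching its duration.

The detector uses declared, configurable constants (the literature the
method descends from does not pin them down, so they are calibrated once
against the simulator and then frozen):

| constant | default | meaning |
|---|---|---|
| scale band | 30–240 d | scales scanned (positive-lobe width of the wavelet) |
| `rel_power_threshold` | 0.2 | centre must exceed this fraction of the global spectrum maximum |
| `min_skeleton_days` | 30 | minimum above-threshold ridge extent in time |
| season band | 60–200 d | a centre's scale interval must intersect this |
| `max_season_scale` | 170 d | cap on the centre's own scale |
| `merge_days` | 45 | centres closer in time merge (double-peaked single crop) |
| `min_amplitude` | 0.15 | overall EVI2 amplitude below this = fallow |

`max_season_scale` deserves a note: between two seasons ~100 days apart
the wavelet produces an *interference* maximum at roughly twice their
separation (~200+ d scale) — a real local maximum of the spectrum that is
not a season. Since a single season's energy concentrates below ~170 d,
capping the centre scale removes exactly these envelope artifacts.
Winter-wheat cycles that span the year boundary are attributed to the
year containing their heading date: only centres with day-of-year 1–365
are counted, which also excludes the autumn establishment bump.

The count is capped at 3 (triple cropping). On noise-free simulated
pixels the wavelet count provably coincides with a brute-force count of
prominent EVI2 peaks (prominence > `min_amplitude`), which the test suite
checks on 200 pixels spanning all eleven patterns.

Season windows are then cut around each detected cycle: heading = day of
the cycle's EVI2 maximum (earliest day on plateaus), season start/harvest
at the 10% amplitude crossings of each flank, tillering at the 30%
crossing of the rising flank.

## Crop decision rules

Each season window is labelled rice, wheat, maize or other by three rules
whose thresholds depend on the pixel-purity stratum (below):

* **Rice** — during tillering→heading a flooded paddy holds LSWI high and
  flat while EVI2 climbs, so with
  $RCLE = (LSWI_{max}-LSWI_{min})/(EVI2_{heading}-EVI2_{tillering})$
  the rule is $LSWI_{min} > \theta_1 \wedge RCLE < \theta_2$,
  $\theta_1 = 0.1$, $\theta_2 \in \{0.42, 0.52, 0.62\}$ for
  pure/moderate/serious pixels.
* **Wheat** — with a calendar-estimated heading date and early growing
  length, $EVE = (EVI2_{heading}-EVI2_{seedling}) + (EVI2_{max1}-EVI2_{min1})$
  over the early stage and
  $EVL = (EVI2_{heading}-EVI2_{harvest}) + (EVI2_{max2}-EVI2_{min2})$ over
  the late stage; rule $EVE > \theta_3 \wedge EVL > \theta_4$,
  $\theta_3 \in \{0.32, 0.24, 0.16\}$, $\theta_4 = 0.12$. The winter-wheat
  dormancy trough makes $EVE$ large; steep post-heading senescence makes
  $EVL$ large.
* **Maize** — across a flowering window centred on heading, split at its
  midpoint, with $P_x$/$N_x$ the summed positive/negative day-to-day NMDI
  differences per half:
  $RCPN = (P_{early}+P_{late})\,N_{late}/(N_{early}+N_{late}+\sigma)\times 100$;
  rule $RCPN > \theta_5$, $\theta_5 \in \{0.45, 0.35, 0.25\}$. Maize's
  flowering moisture pulse produces the rise-then-fall that makes both
  factors of the numerator large.

Notice the direction of the stratification: the rice threshold is a
*ceiling* that loosens with mixing, while the wheat and maize thresholds
are *floors* that drop with mixing — in both cases because the crop signal
is diluted toward the background as the cropland fraction falls.

Design choices the upstream literature leaves open, and what this package
does:

* **$\sigma$ in RCPN** is not published; default 0.01, configurable. On
  the simulated fixtures labels are stable for $\sigma \in [0.001, 0.05]$.
* **Flowering window**: heading ± 36 days. The moisture dynamics around
  maize flowering/grain filling span several weeks on either side of
  tasselling, and at an 8-day cadence a window much narrower than ±30 d
  holds too few observations to carry a slope signal through smoothing.
* **Rule conflicts** (more than one rule fires): resolved by the largest
  relative margin, $(\text{metric}-\theta)/\theta$, taking the minimum
  over a rule's two conditions; exact ties break deterministically
  rice → wheat → maize.
* **Wheat gate**: the wheat rule is evaluated only for seasons whose
  detected heading lies within ±30 d of the calendar-predicted wheat
  heading (the "potential wheat window"); rice and maize take their
  dates from the season segmentation directly.
* **Wheat calendar**: planar trend surfaces (intercept + two predictors:
  latitude and altitude for winter wheat, latitude and accumulated
  temperature for spring wheat) supply heading date and early growing
  length per site; the default coefficients are intercept-only surfaces
  matching the simulator's declared calendar (heading day 115, early
  growing length 160 d).

## Purity stratification

A fine binary cropland mask is block-averaged to a cropland fraction per
coarse pixel (`aggregate_fraction()`), then stratified: >90% pure,
50–90% moderate, 30–50% serious, <30% excluded from classification.
Boundary values 0.90 and 0.50 fall in the moderate stratum and 0.30 in
the serious stratum (the published description leaves the closed ends
unstated; this package fixes and unit-tests one reading). Excluded pixels
are emitted with an explicit no-data code, never dropped, so rasters stay
aligned.

## Pattern codes and sown areas

Intensity plus season labels encode as integer codes: first digit =
intensity; crop digits 4 maize, 5 rice, 6 wheat, 7 other; doubles carry
both digits in ascending numeric order (the code stores the rotation's
composition, not its temporal order, which lives in a sidecar attribute);
triple cropping is the bare code 3. The vocabulary is
`{0, 14, 15, 16, 17, 245, 246, 255, 256, 277, 3}`. Double patterns
pairing a staple with an "other" season have no code of their own and
collapse to 277, with the original labels preserved in the sidecar — a
documented extension for a case the coding scheme does not define.

Sown areas use the per-season convention (each season counts, so
double rice contributes twice to rice), weighted by cropland fraction and
pixel area, matching how census sown areas are tabulated.

## The simulator: what it emulates and what it does not

`simulate_pixel()`/`simulate_scene()` generate 70 composites (the padded
year) of 4-band reflectance. The pure-crop endmember is built in *index*
space — double-logistic EVI2 canopy cycles; an LSWI flood plateau with a
shallow canopy-driven rise for rice; a dormancy trough plus spring
green-up for winter wheat spanning the year boundary; a triangular NMDI
flowering excursion (half-width 40 d, rise 0.18) for maize; canopy-coupled
LSWI/NMDI terms for every crop — and then *back-solved* to bands so that
the index formulas reproduce the target trajectories exactly: red follows
a canopy-coupled profile (bright soil 0.15 → full canopy 0.04), NIR from
EVI2, SWIR6 from LSWI, SWIR7 from NMDI. This one consistent solution
keeps all bands in realistic ranges (background NIR ≈ 0.23, peak-canopy
NIR ≈ 0.55) — which matters, because NMDI's sensitivity to band noise
scales inversely with NIR.

Mixed pixels are linear per-band combinations of the crop endmember and a
constant non-crop background (EVI2 0.15, LSWI 0, NMDI 0.6) weighted by
cropland fraction — exactly linear, so the mixing identity is testable to
machine precision at zero noise.

Observation noise is Gaussian with per-band standard deviation
`noise_sd`, decomposed into a spectrally *correlated* component (share
0.8) and an independent component. Composited surface-reflectance error
is dominated by atmospheric-correction residuals, which move neighbouring
bands together; modelling the noise as fully independent per band would
make band-difference indices (NMDI especially) noisier than any real
archive and would misrepresent what the published rule set can do. Cloud
gaps are i.i.d. Bernoulli per composite, flagged in the validity mask.

Default cycle calendars per pattern code (sowing/peak dates in
`default_pattern_cycles()`) follow the corresponding real systems: winter
wheat sown ~day −80, heading day 115, harvest ~160; summer maize after
wheat peaking ~day 225; early/late double rice peaking ~150/260; a
spring+autumn pair for generic double cropping; three ~95-day cycles for
triple cropping.

What the simulator does *not* emulate: radiative-transfer or BRDF
effects, geolocation error, spatially correlated cloud fields,
within-class phenology variation across a scene, non-crop vegetation with
crop-like seasonality, and real landscape fragmentation. Passing the
package's end-to-end tests therefore demonstrates internal consistency of
the method chain under controlled degradation — not the accuracy
achievable on a real satellite archive, which depends on error sources
outside this model.

## Numerical choices and degenerate inputs

* Whittaker systems are solved with sparse Cholesky (banded, ~554 unknowns);
  the smoother is linear, so scaling/offset invariances are exact.
* Zero denominators in index formulas flag the date invalid rather than
  erroring; a season whose EVI2 rise is non-positive cannot be rice; wheat
  windows falling outside the series span make the season unclassifiable
  as wheat, with a logged reason.
* Plateau maxima break ties to the earliest day. Peaks closer than 45 days
  merge (a stressed crop's double peak is one season).
* All-constant EVI2 series yield zero wavelet centres — a valid fallow
  result, not an error.
* Accuracy metrics report NA for classes with empty rows/columns instead
  of propagating NaN; producer's accuracy is diagonal over *row* total and
  user's accuracy diagonal over *column* total, the reading the package's
  benchmark survey table uses (its printed per-class accuracies force it).

## Problem sizes used in the shipped checks

The test-suite and acceptance script run a 50×50-pixel scene cycling
through all eleven pattern codes — once clean (no noise, no gaps, pure
pixels; recovery must be exact) and once degraded (noise_sd 0.02,
gap_rate 0.2, cropland fraction uniform on [0.5, 1]); 200 single pixels
for the intensity/peak-counting equivalence; 100 random confusion
matrices against a brute-force metric oracle; and a 10,000-point random
metric grid for rule monotonicity and stratum nesting. These sizes give
stable statistics while keeping a full run in the minutes range on one
CPU.

## Known limitations

* The intensity constants are calibrated surrogates for an algorithm whose
  authoritative constants are unpublished; on real data they would need
  re-calibration against ground truth.
* The wheat rule depends on a calendar surface; where the supplied
  coefficients are wrong by more than the ±30 d gate, wheat is
  unrecoverable by construction.
* RCPN remains the most noise-sensitive metric even after heavy smoothing;
  under band noise well beyond ~0.02, maize commission errors rise first.
* Suitability masks are inputs; the package does not derive them from
  climate or topography.
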