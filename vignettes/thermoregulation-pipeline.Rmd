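---
title: "Leaf thermoregulation metrics: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Leaf thermoregulation metrics: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of its science: the quantities it
computes, the assumptions behind them, the synthetic experiment it uses to
test itself, and the numerical choices made where the design was genuinely
open.

## The measurement model

The raw observable is a pair of type-T thermocouple channels per plant — one
pressed to the underside of a leaf, one shielded in the canopy air beside it —
logged at 1-minute intervals over an afternoon session (12:00–15:00) in a
thermostated glasshouse room, once under a benign treatment (25 °C setpoint,
canopy air averaging ≈23.2 °C) and once under a high-temperature treatment
(38 °C setpoint, ≈35.7 °C at canopy).

Two stages of filtering precede any statistic:

* **Equilibration window.** Only minutes between 12:30 and 15:00 (both ends
  inclusive) enter the analysis; the first half hour of a session is
  equilibration time.
* **Cooler trimming.** Evaporative coolers cycle on and off in a glasshouse;
  while active they drive sharp air-temperature dips with chaotic circulation
  that carries no signal about the plant. Minute-pairs with T_air at or below
  16 °C (benign) or 31 °C (high) are removed — strictly-greater-than
  retention, both channels together so the series stays paired. Under the
  default generator this removes roughly a tenth of the minutes. The
  threshold is applied to the *air* channel: the artifact being excised is an
  air-side disturbance, and trimming on the leaf channel would selectively
  remove exactly the leaf behaviour under study. Both filters are plain row
  filters, so they commute and are idempotent (property-tested).

From the retained minutes:

* **Thermal offset** ΔT = T_leaf − T_air per minute, summarised per plant by
  its mean.
* **Coupling strength** β. The series is partitioned into non-overlapping
  30-minute windows left-anchored at 12:30 ("at 30-minute intervals" read as
  a partition, not a rolling window; a trailing partial window is kept if it
  meets the minimum point count). Within each window the OLS slope of T_leaf
  on T_air is fitted; β is the unweighted mean of the retained window
  slopes. Windows with fewer than `min_points = 10` minutes or an air range
  under `min_air_range = 0.2` °C are skipped and reported — a thermostated
  room can hold air nearly constant for half an hour, and a slope against a
  constant regressor is noise.

  Whether a per-plant β should be the mean of window slopes or one
  regression over all windows is an open reading; the window-mean is the
  default and an n-weighted mean is exposed as `beta_from_slopes(method =
  "n_weighted")` (the two coincide for equal window sizes, which the default
  design produces up to trimming).
* **Classification.** |β − 1| ≤ ε → poikilotherm; β < 1 − ε → limited
  homeotherm; β > 1 + ε → megatherm. The default ε = 0.1 sits well inside
  the plausible β range (≈0.7–1.3) while absorbing estimation noise; a slack
  of 1e−12 keeps representable band edges such as β = 1.1 inclusive under
  floating point.

## Leaf traits and the thermal time constant

From wet mass, dry mass, area, thickness and width of the single measured
leaf per plant: LWC = (wet − dry)/wet, LDMC = dry/wet (complements summing
to 1, asserted to 1e−12), LMA = dry/area in kg m⁻², LD = dry/(area ×
thickness) in g cm⁻³.

The **thermal time constant** is the leaf's areal heat capacity over its
sensible heat conductance,

$$\tau = \varphi \, \mathrm{LMA} \left( \frac{c_{p,w}}{\mathrm{LDMC}\cdot h}
  + \frac{c_{p,d} - c_{p,w}}{h} \right) \quad [\mathrm{s}],$$

with φ = 0.5 (projected-to-total area), c_p,w = 4181 and c_p,d = 2814
J kg⁻¹ K⁻¹. The typeset source equation is ambiguous about its fraction
structure; the reading implemented here is the unique one that is
dimensionally a heat capacity per area over a heat transfer coefficient
(kg m⁻² · J kg⁻¹ K⁻¹ / W m⁻² K⁻¹ = s) and whose bracket,
c_p,w/LDMC + c_p,d − c_p,w, is exactly the specific heat of wet tissue per
kilogram of dry matter: a leaf at dry-matter content LDMC carries
(1/LDMC − 1) kg water per kg dry matter, so its mixed specific heat is
(1/LDMC − 1)·c_p,w + c_p,d. At LDMC = 1 the water terms cancel to
φ·LMA·c_p,d/h, the dry-leaf closed form the tests pin at 1e−9.

The heat transfer coefficient uses the laminar forced-convection flat-plate
correlation collapsed to one coefficient, h = a_h·√(u/w) with defaults
a_h = 3.87 W m⁻² K⁻¹ (m s)^½ (0.664·k_air·Pr^⅓/ν^½ at ≈25 °C) and
u = 1 m s⁻¹, both configurable via `tau_params()`. The exact h(width)
formula and wind speed used in the original facility are not published, so
absolute τ values here are comparable in rank but not in scale; the
monotonicities that carry the interpretation — τ falls with LDMC (wetter
leaves respond more slowly), rises with LMA and with width — are asserted as
tests.

`vpd()` (Tetens saturation vapour pressure) exists to report simulated
glasshouse conditions. Note one flagged inconsistency in the reference
conditions: a reported high-treatment VPD of 6.3 kPa at 38.5 °C and 23.8 %
RH is not reproducible by Tetens (≈5.2 kPa); the benign conditions
(26.3 °C, 30.5 % → ≈2.38 kPa) reproduce fine. The package reports what the
formula gives and does not "correct" either number.

## The six-trait PCA

Area, width, thickness, LWC, LD and g_sw mix cm², mm, fractions and
mol m⁻² s⁻¹, so traits are z-score standardized by default and the
decomposition is of the correlation matrix (an `scale = FALSE` switch
exists). Plants missing g_sw are excluded first, with a message. Components
are ordered by variance; each loading vector is oriented so its
largest-magnitude element is positive (a deterministic sign convention —
eigenvectors are sign-free). Contributions are squared loadings scaled to
100 % per component. The implementation is `stats::prcomp`; the test oracle
is an independent `eigen(cor(X))`, with reconstruction of the standardized
matrix checked at 1e−8.

## Statistics

* **Type III treatment×biome ANOVA**, fixed effects only, via sum-to-zero
  contrasts and full-vs-reduced QR fits per term. The original analysis
  fitted mixed models with random intercepts for growth form, species within
  family and plant identity; that variance decomposition is deliberately out
  of scope here, and the fixed-effects analogue answers the same marginal
  questions on the synthetic design (where no species-level variance is
  generated — see below). `car::Anova` serves as the independent test oracle
  at 1e−6.
* **Tukey–Kramer contrasts** over all biome×treatment cell pairs, p-values
  from the studentized range with the pooled one-way residual df (no
  Kenward–Roger small-sample correction); Holm is available. Singleton
  groups are excluded with a warning. Oracle: `stats::TukeyHSD`.
* **Bootstrap CIs**: percentile method, 1000 resamples by default, seeded.
  Percentile intervals on n = 25–30 Normal samples cover slightly under
  nominal (the acceptance suite measures ≈93–95 % at the 95 % level over
  2000 simulations), which is the known small-sample behaviour of the
  method, not a defect.

## The synthetic experiment

The generator (`synthetic_config()`, `generate_experiment()`) emulates the
study design: 3 biomes × 5 species × 5 replicate plants (75 plants), each
logged 12:00–15:00 under both treatments (150 series).

* **Air profiles**: stationary AR(1) fluctuation (coefficient 0.9,
  innovation sd 0.3 °C — chosen to resemble smooth logged glasshouse
  profiles) around canopy means of 23.2/35.7 °C, plus cooler dips with
  per-minute onset probability 0.02, 5-minute duration and ≈9 °C (benign) or
  ≈6 °C (high) depth. The dip parameterization is calibrated so that ≈10 %
  of minutes fall below the treatment's trim threshold, matching the
  fraction the preprocessing stage is expected to discard.
* **Coupling**: per plant×treatment, t_leaf = anchor + δ + β_g·(t_air −
  anchor) + N(0, 0.3²) per minute. Offsets δ are drawn per plant from the
  biome×treatment presets (temperate 1.99 sd 1.30 benign, 0.60 sd 0.91
  high; alpine 0.63 sd 1.01 and −1.25 sd 0.77; desert 0.50 sd 1.05 and
  −1.66 sd 0.92 °C). The printed ± spreads are treated as between-plant
  standard deviations; only cell means are asserted downstream, so the
  recovery targets are insensitive to whether they were really sd, se or CI
  half-widths — that choice only sets the Monte-Carlo error of a 25-plant
  grand mean (≈0.15–0.26 °C). Slopes are drawn with sd 0.05 around
  qualitative presets (0.85 everywhere benign; 1.1 temperate / 1.0
  alpine and desert under heat). Inside `generate_experiment()` the anchor
  is the treatment's canopy mean rather than each series' own sample mean:
  the generating offset is then defined at operating temperature and is not
  biased by cooler-dip minutes that preprocessing later removes (with a
  sample-mean anchor, trimming shifts the retained air mean up by ≈0.9 °C
  and couples a (β_g − 1)-sized bias of order 0.1 °C into ΔT).
* **Traits**: log-normal within-biome clusters (alpine thick/water-rich/
  high-g_sw; temperate thin/dense with a wide leaf-area range; desert
  small/narrow), with wet and dry mass back-computed from LD, area,
  thickness and LWC so every raw table satisfies its own invariants.
  Numeric cluster parameters are invented defaults — the per-species trait
  table they stand in for is not published at desk scale — and are labelled
  as such here. 18 of 75 plants get a missing g_sw, drawn at random.
* **Species labels** are round-robin bookkeeping only: no species- or
  family-level variance component is generated. This is the main feature of
  real data the generator does *not* emulate (with radiation load and
  stomatal dynamics), and it is why passing recovery tests show the
  estimator chain is correct, not that field data would behave this simply.

Everything is a pure function of (config, seed): the determinism tests
require byte-identical written CSVs and metric tables across reruns.

## Problem sizes

The default test and acceptance runs use the full 75-plant design (150
series × 181 minutes, ≈3 s for a complete pipeline run), 200-seed
Monte-Carlo calibrations for the trim fraction and β recovery, and 2000
simulated datasets for bootstrap coverage; the whole suite runs in under a
minute on one core.

## Known limitations

* Fixed-effects ANOVA only; no REML variance components, no Satterthwaite or
  Kenward–Roger df.
* τ absolute scale depends on an unpublished h(width) correlation; treat τ
  comparatively.
* The generator's linear coupling is the estimator's own model; it validates
  the pipeline, it cannot validate the biology.
* No energy-budget prediction of T_leaf (radiation, emissivity, latent
  heat) — the pipeline measures coupling, it does not model it.
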