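---
title: "Estimating fractional gluconeogenesis from heavy-water labeling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating fractional gluconeogenesis from heavy-water labeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fgng)
library(dplyr)
```

## The measurement

When an animal drinks water containing deuterium oxide (D₂O), its body
water equilibrates quickly to a stable deuterium fraction. Glucose made de
novo by gluconeogenesis (GNG) picks up deuterium from body water at the
carbon-bound hydrogen positions added during synthesis, while glucose
released from pre-existing (pre-label) glycogen does not. The fraction of
circulating glucose that is newly made — *fractional gluconeogenesis*,
fGNG — can therefore be read off a mass spectrum.

The readout is the glucose penta-acetate derivative's m/z 169 fragment,
monitored by GC-MS in selected-ion-monitoring mode at m/z 169 (M, the
unlabeled ion) and m/z 170 (M+1, one extra mass unit). This fragment
carries six exchangeable hydrogens (carbons 1, 3, 4, 5 and 6) and —
crucially — excludes the carbon-2 hydrogen, which exchanges during the
glucose-6-phosphate/fructose-6-phosphate isomerization and so reflects
total glucose turnover rather than GNG specifically.

Two ratios define the estimator:

1. **Fragment enrichment** — the per-site deuterium enrichment of the
   fragment:
   $$E_{169} = \frac{(M{+}1)_{m/z\,170} / M_{m/z\,169}}{6}.$$
2. **Fractional gluconeogenesis** — fragment enrichment relative to the
   precursor (body water) enrichment $p_w$:
   $$\mathrm{fGNG} = E_{169} / p_w.$$

Body-water enrichment is measured separately: plasma is distilled
overnight, diluted 1:300, read on a liquid water isotope analyzer, and
converted to a D₂O fraction through an ordinary least-squares standard
curve of known-percentage D₂O standards (`fit_standard_curve()`,
`enrichment_from_reading()`). Because standards and samples pass through
the same dilution in the reference workflow, the fitted curve is already
dilution-aware; `curve_includes_dilution = FALSE` covers laboratories that
calibrate on undiluted standards, in which case the inverted value is
multiplied by the dilution factor. Back-calculated enrichments in
$(-10^{-4}, 0)$ are treated as analyzer noise around a blank and clamped to
0 with a QC flag; anything more negative aborts, because it signals a unit
or curve error rather than noise.

## The forward model and the estimator's bias

`label_distribution()` models circulating glucose as a two-component
mixture: a fraction $f$ (true fGNG) whose six monitored sites are each
independently deuterated with probability $p_w$, and a fraction $1-f$
unlabeled at those sites. In **binomial** mode the isotopologue
distribution is $f\,\mathrm{Bin}(6, p_w) + (1-f)\,\delta_0$ — the exact
consequence of independent site labeling. In **linear** mode the model is
truncated to first order: the M+1/M ratio is exactly $6 f p_w$, which is
the assumption under which dividing the ratio by 6 and by $p_w$ returns
$f$ identically.

The two modes let the package characterize the estimator honestly. Under
binomial labeling at $p_w = 0.06$ the product $6 p_w = 0.36$ is not small:
the M+1 mass is depleted by $(1-p_w)^5$ (label spills into M+2 and higher)
while the M ion is depleted by $(1-p_w)^6$, and the net bias of the linear
estimator is

$$\hat f - f = f\left[\frac{(1-p_w)^{5}}{1 - f\,(1-(1-p_w)^6)} - 1\right],$$

which reaches about $-6.6$ percentage points near $f = 0.5$, crosses zero
near $f \approx 0.86$, and is $+6.4$ points at $f = 1$ (where the hard
superunity guard in `compute_fgng()` triggers, by design). The test suite
pins this bias against an independent $2^6$ site-enumeration oracle. On the
fragment-enrichment scale the same error is under 0.4 percentage points;
users comparing cohorts measured at the same $p_w$ are largely unaffected
because the bias is smooth and shared, but absolute fGNG values carry it.
Related consequences the tests document: the binomial M+1/M ratio
increases with $p_w$ only below the single-label turnover $p_w = 1/6$, and
the linear/binomial gap is first order in $6 p_w$ (about 4% relative at
$p_w = 0.01$ for low $f$, shrinking proportionally with $p_w$).

Natural-abundance background (chiefly ¹³C) is available but off by
default. The elemental composition of the m/z 169 ion is not something the
package will assert — it depends on derivative chemistry and fragmentation
— so `fragment_model()` ships with an empty composition, the raw-ratio
convention, and `natural_abundance_m1()` / `convolve_background()` become
active only when a user supplies a composition. The isotope table is a
pinned package data file, not a network lookup.

## Classification bands

`classify_feeding_state()` bands fGNG into the dietary-adequacy states
used at the bedside: **fed** $[0, 0.15]$, **unfed** $(0.40, 1]$, and
**indeterminate** $(0.15, 0.40]$ for the unnamed middle ground, so the
three bands partition $[0, 1]$. An **overfed** warning flag accompanies
values in $[0, 0.10]$. Boundaries are inclusive on the fed side — a
measurement of exactly 15% reads as fed.

## Group statistics

The cohort design is a 2×2 factorial — feeding (ad libitum AL vs 50%
caloric restriction CR) by injury (sham Con vs closed-head TBI) — with
unbalanced cells (3/6/6/5). `two_way_anova()` fits
`fgng ~ feeding * injury` with sum-to-zero contrasts and reports Type III
sums of squares, the SPSS GLM default that studies of this kind report;
with these cell counts Type I and Type III genuinely differ, so the choice
is visible. `independent_t_test()` is the pooled-variance Student test
(Welch behind a flag), and `tukey_hsd()` runs Tukey–Kramer
studentized-range comparisons across the four cells with the pooled
within-cell error term. The significance threshold convention is
$p \le 0.05$, with no correction beyond Tukey.

`anova_from_summary()` rebuilds the same Type III table from per-cell
means, SDs and counts alone: within-cell SS as $\sum (n_i - 1) s_i^2$ and
each 1-df effect as the $\pm 1$ contrast sum of squares
$L^2 / \sum (1/n_i)$ on the cell means. It is an independent derivation —
not a wrapper — so it doubles as an oracle for `two_way_anova()` and lets
published summary tables be checked without raw data. When a degenerate
design has zero residual variance (constructed test cases), the boundary
convention is $F = \infty$, $p = 0$ for a nonzero effect.

Pre-vs-post comparisons are reported unpaired. The underlying samples are
paired (same animals bled twice), so the unpaired report is conservative;
a paired procedure is out of scope and the caveat is deliberate.

## What the synthetic cohort emulates

`simulate_cohort()` generates the complete raw-input bundle — design
table, standard curve, body-water readings, per-injection SIM intensity
pairs, and a truth table — so every pipeline stage is testable without
laboratory data. Its defaults are the study conditions:

* **Cells** 3/6/6/5 animals (AL-Con / AL+TBI / CR-Con / CR+TBI), two
  timepoints per animal.
* **True fGNG** drawn per animal from truncated normals on $[0,1]$.
  Post-intervention cells use the published cell means and SDs directly
  (62.64/59.85/79.83/79.10 ± 6.33/5.01/4.43/4.52 %). Pre-intervention
  values are published for pooled feeding groups as 35.40 ± 1.10 (AL,
  n = 9) and 36.62 ± 1.71 (CR, n = 11); those dispersions are standard
  errors, not SDs — read as SDs they imply $p \approx 0.08$ for the AL-CR
  comparison, while the study reports $p \ge 0.55$, which matches the SEM
  reading exactly ($\mathrm{SD} = \mathrm{SE}\sqrt{n}$: 3.30 and 5.67
  points). The post-intervention printed comparisons conversely verify the
  SD reading (e.g. CR-Con vs CR+TBI gives $p = 0.79$ against the printed
  $p \ge 0.78$). The generator therefore uses SE$\sqrt{n}$ pre and the
  printed SDs post.
* **Body water** 5.5% ± 0.3% between animals — a little under the 6%
  drinking water because food and metabolic water are unlabeled. The exact
  level is irrelevant to round-trip correctness (it cancels in the
  estimator); it sets scale only.
* **Measurement noise** multiplicative lognormal with CV 2% applied
  independently per SIM channel per injection, 3 injections per sample,
  ratioed per injection then averaged — a routine GC-MS repeatability
  level. Body-water readings pass through the simulated curve noiselessly:
  analyzer repeatability is far below the biological spread being modeled,
  and keeping the denominator exact makes the noise-free round trip a
  machine-precision identity test.
* **Determinism**: Mersenne-Twister with inversion normals, seeded
  mandatorily; truncated-normal draws use inverse-CDF sampling so no
  rejection loop perturbs the stream.

What it does **not** emulate: D₂O equilibration kinetics (plateau
enrichment is assumed from day 1 of labeling), deuterium recycling through
TCA/pentose pathways, positional exchange differences among the six sites,
drift or saturation in the mass spectrometer, and any biology linking an
animal's pre and post values (timepoints are drawn independently).
Passing recovery tests therefore demonstrates that the *estimator and
statistics* behave correctly under the study's statistical structure — not
that the labeling chemistry is beyond doubt in real plasma.

`simulate_trajectories()` adds the optional body-weight and food-intake
columns: the deterministic skeleton is the published per-cell means at the
three reported timepoints, with per-cell Gaussian noise scaled by
`trajectory_noise`, and the caloric-restriction ration rule applied
literally (each animal's pre-intervention intake rounded up to the nearest
half gram, then halved).

## Numerical and design choices

* All enrichments are fractions internally; percent appears only in
  reports and plots.
* Superunity tolerance: estimated fGNG in $(1, 1.05]$ is clamped to 1 and
  flagged (noise can push a ratio slightly past the physical bound);
  beyond 1.05 the pipeline aborts rather than report an impossible value.
* `run_pipeline()` output is timestamp-free, so identical inputs give
  byte-identical files; the JSON manifest carries an option hash that
  changes exactly when a semantically meaningful option changes.
* Validation (`validate_inputs()`) collects all schema, join, duplicate
  and range problems before the pipeline refuses to run, naming rows and
  identifiers.

## Problem sizes used in the checks

The packaged checks run 200 replicate cohorts for the parameter-recovery
and inference-pattern properties (about 17 animals × 2 timepoints × 3
injections each), 500 replicates in the reproduction script (with 100
ANOVA replicates for the feeding-effect bound), a 2,000-animal single
cohort for the large-sample bias property, and dense grids for the exact
round-trip identities. These sizes put Monte-Carlo standard errors of
group means near 0.1 percentage points, an order of magnitude below the
effects being recovered.

## Known limitations

* The linear estimator's binomial-labeling bias (±6.6 points of fGNG at
  6% body water) is characterized, not corrected; a bias-corrected
  inversion of the binomial model would be a natural extension.
* Pre/post pairing is ignored in the statistics, as published.
* The natural-abundance path is only as good as the user-supplied
  elemental composition; no default composition is asserted.
* Group sizes of 3–6 animals leave the factorial tests with 16 residual
  degrees of freedom; effects near the significance boundary (the small
  injury contrast especially) will land on either side from cohort to
  cohort, and the package reports that instability rather than smoothing
  it.
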