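---
title: "Profiling bile acids and lysophospholipids from AIF runs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling bile acids and lysophospholipids from AIF runs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aifquant)
```

## The measurement problem

All-ion fragmentation (AIF) acquires one full-scan (MS1) and one
fragment-level spectrum per duty cycle, fragmenting *everything* in the
mass window rather than an isolated precursor. The gain is untargeted
coverage; the cost is that fragment spectra are chimeric, so
precursor–fragment relationships have to be reconstructed from
chromatography: a diagnostic fragment is attributed to a precursor only
when their extracted-ion chromatograms (XICs) peak at the same retention
time. For bile acids the conjugate group fragments are characteristic —
glycine conjugates give the deprotonated glycine anion C2H4NO2⁻ at m/z
74.0248, taurine conjugates a triplet at 79.9574 / 106.9808 / 124.0074,
sulfates the HSO4⁻ anion at 96.9601 and a neutral SO3 loss, glucuronides
C6H9O7⁻ at 193.0354. Lysophospholipids (LPL) give their fatty-acyl
carboxylate and a head-group fragment; choline lipids ionize in negative
mode as acetate adducts, the other classes as [M−H]⁻.

All ion masses in the package are *electron-inclusive*: the printed
reference fragment masses are reproduced at four decimals only when the
electron mass (0.000549 Da) is added to the anion's atomic sum. One
reference inconsistency is worth noting: a circulated value of 79.9597
for the neutral SO3 loss disagrees with the elemental computation
(79.9568); the registry stores the computed value and keeps the other as
a comment in the TSV resource rather than silently choosing.

## Identification model

An analyte is **confirmed** when three criteria hold
(`confirm_identity()`):

1. an MS1 XIC at the adduct m/z (± 5 ppm) contains a detected peak;
2. at least one class-diagnostic fragment XIC (± 5 ppm, AIF level) has a
   peak co-eluting with it (apex distance ≤ 0.1 min and overlapping
   bounds);
3. the apex matches the reference standard's retention time within
   0.1 min.

Criterion 3 is waived when no standard exists (`rt_source =
"predicted"`). Unconjugated bile acids have no diagnostic conjugate
fragment; because they fragment weakly, the deprotonated molecule itself
survives into the AIF scan, and the package uses that surviving-precursor
channel as the fragment-level evidence for those classes. This is a
deliberate design choice: it keeps criterion 2 meaningful for the whole
panel while remaining exactly the co-elution test used everywhere else.

Untargeted screening crosses candidate masses with the co-elution test.
The bile-acid space is built from C24 cholanoic cores with 1–3 hydroxyls
and conjugations (glycine, taurine, sulfate, glucuronide) capped at two
groups, never combining the two amidations; the LPL space spans classes
LPC/O-LPC (acetate) and LPE/LPI/LPS/LPG ([M−H]⁻) with acyl chains C12–C22
and 0–6 double bonds, so a head-group assignment can never conflict with
the adduct rule. Hits without any co-eluting fragment are reported as
`mass_only`, mirroring how low-abundance species behave in practice.

### sn-positional isomers

LPL elute as two positional isomers. The package expects the 2-acyl
isomer *earlier* by roughly 0.3 min at roughly a 1:10 area ratio, and
labels a two-peak pattern as a pair only when the offset lies in
0.15–0.5 min and the minor/major ratio is at most 0.35. Reference
material on the elution order is contradictory (text and figure
annotations disagree); rather than resolving this silently, the expected
order is a configuration flag (`sn2_first = TRUE` by default) and every
labelling carries a `consistent` attribute recording whether the minor
peak actually eluted first. Polyunsaturated species can show additional
isomer peaks; anything that is not a clean pair gets only a dominant
`sn1` label.

### Retention-time prediction

For tentatively identified LPL without standards the package fits, per
class, the plane `rt = a + b·carbons + c·double_bonds` by least squares
over anchor compounds (an equivalent-carbon-number model) and states a
±0.3 min tolerance. The underlying prediction procedure in the reference
workflow is unspecified; the linear model is this package's own declared
substitute and is validated only on synthetic linear data.

## Peak model and numerical choices

XICs sum centroid intensities inside the ppm window per scan, with
explicit zeros when nothing falls inside (this matters for the noise
estimate). Detection runs on a 5-point moving mean; candidate apices are
strict local maxima, bounds extend to flanking valleys or baseline
return, overlapping peaks split at the shared valley. Height and area
subtract the baseline level (median of out-of-peak raw intensities);
area is the trapezoid of the raw trace; noise is `1.4826 × MAD` of the
out-of-peak raw trace, and SNR thresholds (default 3, matching the
LOD rule) are applied to the *smoothed* apex height so single-scan noise
spikes cannot register as peaks. A noiseless trace yields an infinite
SNR, flagged by a zero noise attribute rather than an error. `min_points
= 5` scans per peak at the default 0.5 s per-level sampling gives ≥ 4
points across a σ = 0.04 min peak's FWHM.

## Quantification and validation calculus

Calibration fits area ratio (analyte/IS) against nominal concentration
by weighted least squares with weights 1/x on per-level mean ratios;
replicate handling (fit on means, deviations per replicate) is a
documented choice where the convention is unstated. R² is computed with
the same weights (`1 − SSEw/SSTw`); whether a weighted or unweighted R²
is conventional is genuinely ambiguous, and the weighted one is used so
the acceptance rule and the fit see the same geometry. Back-calculated
deviations gate the curve: every level within ±15 %, ±20 % at the lowest
level (the LLOQ); a failing lowest level is dropped and the curve refit
while at least six levels remain — standard bioanalytical practice, and
the reason the curve object carries `n_points_used`. LOD is the lowest
level at S/N ≥ 3; LOQ the lowest with replicate CV ≤ 20 %; recovery is
`100 × pre/mean(post)` spike areas; matrix effect is
`100 × slope_matrix/slope_solvent`. Trueness and precision follow the
triplicate × three-level × six-day design: repeatability is the pooled
within-day RSD, intermediate precision adds the between-day variance
component from the one-way (by-day) ANOVA decomposition
(`(MSB − MSW)/n0`, floored at zero) — the estimator is named but not
specified in the reference workflow, so the classical decomposition is
used. QC spike levels default to 0.02 / 0.20 / 2.00 µM (two conflicting
printed triples exist; the package defaults to this one and accepts any).

Species without calibration standards get single-point estimates
`area/IS_area × IS_conc`, explicitly documented as estimates under a
response factor of 1 relative to a class-matched IS, not validated
quantification.

## Cohort QC and baseline statistics

Features with more than 10 % missing values or more than 10 % outliers
are discarded. The outlier rule is Tukey fences with the deliberately
wide multiplier `k = 4` (the reference text's "alpha = 4 × inter-quantile
range" is read as the fence multiplier; `k` is configurable). Quartiles
use linear interpolation (type 7) — the estimator is unstated upstream —
and constant features flag nothing by the strict-inequality fence.
Baseline group comparisons from summary data use Welch's t by default
(Satterthwaite df) with pooled Student's t available: both reproduce the
reference table's p values within rounding, and Welch is the safer
unstated default. Gender uses the exact two-sided Fisher test (sum of
hypergeometric probabilities ≤ the observed table's). Downstream
multivariate modelling (multiple imputation, sPLS-DA, mixed models) is
intentionally out of scope; `export_analysis_matrices()` emits exactly
the inputs such tools consume (baseline matrix, log2 fold changes over
the intervention, covariates, and a seeded 75/25 split stratified by
group).

## What the simulator emulates — and what it does not

`simulate_run()` builds the acquisition the pipeline targets: alternating
MS1/AIF scans at 0.5 s per level over a 19-min run (shorter in tests),
MS1 m/z 370–700, Gaussian elution profiles (σ = 0.04 min) at the adduct
m/z with ±2 ppm uniform jitter, M+1 satellites at 1.07 % per carbon,
fragment channels sharing the precursor profile scaled by a yield
(default 0.3, precursor survival 0.2), sn-isomer pairs
(fraction 0.09, offset 0.3 min), and a noise model of an additive
baseline floor (sd 6000 counts on a response of 10⁶ area units/µM,
placing S/N ≈ 5 at 0.003 µM, just above the detection rule) plus a 2 %
proportional term. The constant absolute floor is what produces the
characteristic inverse relation between concentration and replicate CV.
Calibration series default to 8 levels spanning 0.003–5 µM in
triplicate, with a configurable suppression factor on analyte (not IS)
response to emulate matrix ionization suppression. The cohort generator
draws log-normal lipid levels for 2 × 50 subjects × 3 visits with
multiplicative responder effects attenuating over follow-up, plants 7
excess-missingness and 5 gross-outlier features among 116, and is fully
seeded.

The simulator does **not** model peak tailing/fronting, retention drift,
chimeric-fragment interference between co-eluting species at the same
fragment mass, ion suppression that varies over the gradient, or
detector saturation. Passing tests therefore demonstrate that the
algorithms are correct under the stated model — Gaussian peaks, known
noise, exact masses with bounded jitter — not that the method's
real-plasma performance figures transfer. Quantities that depend on real
biological samples (cohort concentration tables, plasma recoveries,
ROC-based prediction results) are out of scope by design.

## Problem sizes and determinism

The test suite and the acceptance script run simulations at reduced but
faithful scale — 7–14 min gradients, 2–26 analytes per run, triplicate
8-level calibration series, five QC seeds, six replicates per point of
the CV–concentration sweep — chosen as the smallest designs that still
exercise every rule (valley splitting, LLOQ refitting, blank
false-positive control). All randomness flows through explicit integer
seeds; the same seed reproduces a bit-identical run, and the CLI prints
the seed it used.

## Known limitations

* Peak bounds are scan-quantized; areas of peaks narrower than ~5 scans
  are biased low, and the integration of heavily overlapping peaks
  (< 3σ apart) splits at the valley rather than deconvolving.
* The untargeted bile-acid space stops at two conjugation groups and
  C24 cores; unusual cores (C27, oxo-, dehydro-) are not enumerated.
* `estimate_conc_by_is()` assumes unit response relative to the matched
  IS; class-level response differences propagate directly into the
  estimate.
* The RT-prediction plane is linear in carbons and double bonds within a
  class; strong nonlinearity at chain extremes is not captured.
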