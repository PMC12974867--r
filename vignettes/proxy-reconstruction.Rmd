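---
title: "Building rainfall proxy records from radiocarbon-dated tree-ring carbon isotopes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building rainfall proxy records from radiocarbon-dated tree-ring carbon isotopes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In semi-arid subtropical woodlands, water stress is the dominant control on
stomatal conductance, so the carbon isotope ratio (delta 13C) laid down in a
tree's growth increments tracks effective rainfall: drier years give less
negative values. Long-lived trees such as baobabs therefore hold centuries of
rainfall information — but they lack countable annual rings, so every step
that dendrochronologists usually get for free has to be rebuilt:

1. **Chronology.** Sparse AMS radiocarbon dates along the core are calibrated
   to calendar-year probability distributions; a piecewise-linear age model,
   anchored on expert-chosen tie points and constrained to pass through the
   1-sigma calibration ranges, assigns a year to every isotope sample.
2. **Correction.** The measured series is contaminated by the atmospheric
   Suess effect (fossil-fuel CO2 lowering atmospheric delta 13C after ~1850)
   and by the plant's physiological response to rising CO2 concentration;
   both are removed relative to a pre-industrial reference year.
3. **Compositing.** Each tree's corrected series is smoothed with a robust
   21-year biweight mean and multiple trees are averaged on an annual grid
   with standard errors.
4. **Statistics.** Monotone trend (Mann-Kendall and least squares),
   mean-shift changepoints (PELT / binary segmentation), and windowed Pearson
   correlations against climate forcing indices.

`dendroiso` implements this pipeline as testable, composable functions, plus
a synthetic-data generator with known ground truth so that every stage — and
the end-to-end reconstruction — is verified by parameter recovery rather
than by eyeball.

## Radiocarbon calibration

A measurement `y ± sigma_lab` (conventional 14C age BP, or F14C for post-1950
samples) is converted to a probability mass over an annual calendar grid by
the standard Gaussian likelihood

> w(theta) ∝ N(y; mu(theta), sigma_lab^2 + sigma_curve(theta)^2),

with `mu` and `sigma_curve` linearly interpolated between the knots of an
IntCal-style curve and the weights normalized to sum to one. Design choices:

- **Grid step 1 year**, matching the annual resolution of the rest of the
  pipeline; all user-facing years are CE, with cal BP = 1950 − CE applied in
  exactly one pair of helpers (`ce_to_bp()`, `bp_to_ce()`).
- **HPD rather than central intervals** (default coverage 0.683, the
  "1-sigma" convention): grid years are accumulated by descending
  probability, ties broken toward earlier years so results are deterministic,
  and contiguous runs merged. On the non-monotone bomb curve this naturally
  yields multiple disjoint intervals.
- Queries outside the curve support are errors, not extrapolations; a
  measurement with essentially zero likelihood everywhere on the grid is
  reported as such instead of returning a spurious uniform density.

No Bayesian sequence calibration is attempted: the age model deliberately
keeps tie points as *inputs* (see below).

## Age models

Tie points — (sample number, calendar year) anchors shared across trees
through wiggle-matched isotope features — are supplied by the analyst, not
estimated. Cross-tree reconciliation of common climate excursions is an
expert-in-the-loop judgement with no objective function; what the package
automates is everything around that judgement: linear interpolation between
tie points, validation of the resulting model against the calibrated 1-sigma
ranges (`validate_model()`), and screening for stratigraphic age inversions
(`detect_inversions()`) that indicate mislabeled samples.

A growth hiatus is declared by listing two years at one sample number (the
younger first). The model then jumps discontinuously at that ring: growth
stopped at the older year and resumed at the younger one, and no sample is
ever assigned a year inside the gap. Queries at exactly the hiatus ring
return the older (stop-side) year — a convention, documented rather than
fundamental, since the ring itself is the boundary. Extrapolation beyond the
terminal tie points is disabled by default (an error) and available as an
explicit clamp, because silent extrapolation of growth rates is the classic
way to wreck a chronology's ends.

The package does not propagate dating error through the age model; the
biweight smoothing window (below) is the mechanism that absorbs age-model
error of a few decades.

## Isotope corrections

Both corrections are anchored at a pre-industrial reference year, default
1748, the inflection between pre- and post-industrial atmospheric change in
the standard atmospheric delta 13C compilations.

**Suess correction** subtracts the atmospheric anomaly:
`delta_corr(t) = delta(t) − (delta_atm(t) − delta_atm(1748))`. Years at or
before the reference are untouched, bit for bit.

**Pre-industrial (pin) correction** addresses the plant's response to rising
CO2 concentration. The observed discrimination
`Delta = (delta_atm(ref) − delta) / (1 + delta/1000)` is converted to a
leaf-internal CO2 concentration through the linear discrimination model
`Delta = a + (b − a) ci/ca` with diffusion and carboxylation endpoints
`a = 4.4` and `b = 27.0` per mille (standard C3 values; configurable, since
different labs use slightly different endpoints). Two response modes bracket
plant behaviour:

- `constant_ci_ca`: the plant keeps ci/ca fixed as ca rises; discrimination
  is unchanged, so the correction is exactly zero. This is one end of the
  bracket by construction.
- `constant_ci_offset` (default): the plant keeps the drawdown `ca − ci`
  fixed, with the result floored at the constant-ci/ca projection. A short
  algebra exercise shows the floor binds whenever `ca(t) > ca(ref)` (because
  `ci < ca`), so under rising CO2 the default mode coincides with the
  conservative zero-correction end of the bracket; the offset branch becomes
  active when `ca(t) < ca(ref)`. Exposing both modes makes the bracket's
  width — the physiological uncertainty itself — reportable instead of
  hidden.

Corrections are applied per tree, before compositing, and fractional sample
years interpolate the annual atmospheric records linearly.

## Smoothing, compositing, statistics

The **21-year Tukey biweight mean** (tuning constant c = 9, MAD scaled by
1/0.6745, at most 10 reweighting iterations from a median start, zero-MAD
windows returning the median) is computed in every annual window
[Y − 10, Y + 10]; truncated windows at the record ends use what is there, and
empty windows drop the year. The window does double duty: it emphasizes the
decadal-and-slower component that is interpretable given radiocarbon dating
error, and its bounded influence function absorbs rogue measurements —
a 10 per-mille outlier moves a 21-sample window value by less than 0.05 per
mille, which is below analytical replication error.

The **composite** is the per-year arithmetic mean across trees with standard
error s/sqrt(k); SE is only reported where k ≥ 2 trees contribute.

**Mann-Kendall** uses the exact S statistic, the tie-corrected variance and
the ±1 continuity correction with a normal two-sided p. S is an integer and
is reported as such, together with Z and p, and never rescaled.

**Changepoints** minimize total within-segment SSE plus a per-changepoint
penalty; PELT solves this exactly with pruning (binary segmentation is kept
as the classical greedy alternative and as an independent cross-check). The
named penalties scale a variance estimate from first differences
(`mean(diff(x)^2)/2`, robust to a small number of genuine shifts) by
2 log n (BIC) or 3 log n (MBIC, the stricter default). On heavily smoothed
series the first-difference variance is small and the default penalty is
correspondingly permissive; when the scientific question is "a handful of
major regime shifts", passing a manual penalty on the scale of the composite's
variance is the intended use. Minimum segment length defaults to 2.

**Correlations** with forcing indices align both series on common integer
years, optionally restrict to a sub-period window and smooth both sides
identically (a centered moving average; even widths use the climatological
half-weight end scheme so a linear series passes through unchanged).
p-values are two-sided and deliberately uncorrected for autocorrelation —
matching common practice in proxy-forcing tables — but the lag-1
autocorrelation of both aligned series is always reported, and the test
suite demonstrates by simulation how strongly autocorrelation inflates the
nominal type-I rate, so users can judge effective sample size.

## The synthetic generator

`simulate_world()` emulates the statistical structure the analysis assumes,
with every default chosen once, up front, to mirror a realistic semi-arid
multi-tree study:

- rainfall: mean 450 mm/yr, −15 mm/century drying trend, a 60 mm centennial
  sinusoid (period 200 yr), AR(1) anomalies (phi = 0.6, sd 40 mm), clipped at
  zero;
- proxy law: delta 13C = −25.3 − 0.35 per 100 mm of rainfall anomaly, plus
  0.15 per-mille signal noise — a linear negative response, the simplest form
  consistent with a monotone rainfall control and no established transfer
  function;
- trees: four cores spanning 1300–2015 CE, sampling rates 0.61–0.99
  samples/yr (so ~430–710 samples per core), one tree with a 1500–1700 CE
  hiatus, 0.1 per-mille measurement noise (below the <0.2 per-mille
  replication error of a well-run lab), 12–15 radiocarbon dates per core with
  25 14C-yr lab error;
- a wiggly calibration curve (20 14C-yr amplitude, 150-yr period, 10 14C-yr
  curve error, slope 1) whose 1-sigma calibrated intervals span a few
  decades, plus a rise-and-fall post-1950 F14C bomb segment;
- atmospheric records flat at −6.3 per mille / 280 ppm until 1850, then a
  smooth monotone −2 per-mille decline and rise to 400 ppm by 2015. The
  rings record the plant signal **plus** this atmospheric anomaly, so the
  Suess correction has a real injected effect to remove.

Everything regenerates bit-identically from (seed, configuration), and the
true rainfall, signal and per-sample ages are returned alongside the
observables so recovery can be asserted, not assumed.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: juvenile effects and ring-width trends, growth-rate
variation between tie points, spatially heterogeneous rainfall across trees,
non-linear or threshold proxy responses, laboratory drift, and reservoir or
species effects on radiocarbon. The generator validates the machinery, not
the botany.

## Numerical choices and degenerate inputs

- Calibration densities are normalized sums on the annual grid; the
  unit-mass invariant is enforced to 1e-9.
- HPD ties are broken toward earlier years (deterministic output).
- Zero-MAD biweight windows return the median; empty windows drop the year.
- The changepoint cost uses cumulative sums (O(1) per segment); PELT pruning
  keeps not-yet-eligible candidates so short minimum segment lengths are
  handled correctly.
- Constant series: Mann-Kendall returns S = 0, p = 1; OLS on a constant year
  vector is an error; a perfect linear fit reports R² = 1 with infinite F.
- Readers reject duplicate sample numbers, non-numeric cells, non-monotone
  axes and implausible delta 13C (outside −40..0 per mille by default) with
  diagnostics naming the offending row.

## Problem sizes used by the test suite

The suite exercises the pipeline at the scale of a real four-tree study
(~1900 isotope samples, 52 dates, 716-year span): 20 calibration-oracle
dates, 500 coverage simulations, 100 biweight oracle windows, exhaustive
8-element permutation enumeration for Mann-Kendall, an exhaustive dynamic
program at n = 60 for PELT, 100 step-recovery composites, and 50 full
end-to-end replicates for signal recovery. These sizes keep each acceptance
property sharp (binomial bands of a few percent) while the whole suite runs
in a couple of minutes.

## Known limitations

- No posterior uncertainty on ages: the age model is deliberately
  deterministic given tie points, and no error is propagated into the
  composite beyond the inter-tree standard error.
- Correlation p-values ignore autocorrelation (reported, not corrected).
- The pin correction's floored default coincides with the zero-correction
  (constant ci/ca) end of the physiological bracket whenever CO2 is above
  its reference value; users whose science depends on the opposite
  (drawdown-preserving) end of the bracket will find the active offset
  branch exercised only where CO2 falls below the reference.
- The composite is an unweighted mean across trees; no attempt is made to
  weight by within-tree replication or growth rate.
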