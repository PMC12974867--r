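# dendroiso

Rainfall proxy records from stable carbon isotopes in radiocarbon-dated tree
cores.

In water-limited subtropical woodlands, stomatal regulation ties the carbon
isotope ratio of wood (δ¹³C, ‰ VPDB) to effective rainfall: dry years leave
less negative values. Long-lived trees without countable annual rings —
baobabs are the canonical case — can therefore yield centuries of rainfall
information, but only after a chain of inference that this package
implements end to end:

- **Radiocarbon calibration** of conventional ¹⁴C ages and post-bomb F14C
  measurements to calendar-year densities, with highest-posterior-density
  (HPD) intervals. The likelihood at calendar year θ is Gaussian with
  variance σ²\_lab + σ²\_curve(θ) around the interpolated curve mean.
- **Tie-point age models**: piecewise-linear sample-number → calendar-year
  maps through analyst-supplied tie points, with growth-hiatus support
  (two years at one ring), validation against the 1σ calibration ranges and
  detection of stratigraphic age inversions.
- **Isotope corrections**: the atmospheric Suess effect is removed by
  normalisation to a pre-industrial reference year (default 1748),
  δ\_corr(t) = δ(t) − (δ¹³C\_atm(t) − δ¹³C\_atm(1748)); the plant response to
  rising CO₂ is handled by a ci/ca-based "pin" (pre-industrial)
  correction with two response modes bracketing plant behaviour.
- **Robust compositing**: a 21-year Tukey biweight mean per tree (tuning
  c = 9), then a multi-tree annual composite with standard errors s/√k.
- **Statistics**: Mann-Kendall trend (exact S, tie-corrected variance,
  continuity-corrected Z), least-squares trend with F = (n−2)R²/(1−R²),
  mean-shift changepoint detection (exact PELT and binary segmentation over
  a penalised-SSE objective), centered moving averages, and windowed Pearson
  correlations against forcing indices with lag-1 autocorrelations reported.
- **A synthetic-data generator** (`simulate_world()`) that produces a
  ground-truth-known four-tree study — drying AR(1) rainfall, a negative
  linear rainfall→δ¹³C law, a growth hiatus, a wiggly calibration curve with
  a bomb segment, and post-1850 atmospheric records — so every stage is
  tested by parameter recovery.

## Worked example

```r
library(dendroiso)

w   <- simulate_world(seed = 42)                # synthetic 4-tree study, 1300-2015 CE
res <- reconstruct(w$trees, w$atm, w$co2)       # date, correct, smooth, composite
comp <- res$composite

head(as.data.frame(comp), 3)
#>   year     value         se n_trees
#> 1 1301 -25.62098 0.01870806       4
#> 2 1302 -25.63981 0.01627659       4
#> 3 1303 -25.63979 0.01629692       4

correlate_with_forcing(comp, w$rainfall)
#> <correlation_result> 1301..2015 CE, n = 715: r = -0.797, p = 4.27e-158 (lag-1 acf 1.00 / 0.84)

mk <- mann_kendall(comp$value)
cat(sprintf("MK: S = %d, Z = %.2f, p = %.3g\n", mk$S, mk$Z, mk$p))
#> MK: S = 100630, Z = 15.77, p = 4.73e-56
```

The composite tracks the injected rainfall with the expected negative sign
(r = −0.80; wetter = more negative δ¹³C), and the injected −15 mm/century
drying trend surfaces as a significant positive Mann-Kendall trend in the
isotope composite. The per-year `se` is the inter-tree standard error; the
lag-1 autocorrelations printed with every correlation warn that the nominal
p-value overstates significance on smoothed series.

Individual stages are just as accessible:

```r
cal <- calibrate_dates(w$trees$T1$dates, w$curves$prebomb, w$curves$postbomb)
cal[[5]]
#> <calibrated_date> T1 sample 160, 68.3% HPD:
#>   1675..1743 CE (68.5%)

fit_age_model(w$trees$T3$tie_points)
#> <age_model> T3: samples 1..330, years 1300.94..2015 CE, hiatus at sample 203 (1499.38-1699.38 CE)
```

A thin command-line layer chains the same stages over CSV files
(`simulate`, `calibrate`, `agemodel`, `correct`, `composite`, `stats`):

```sh
Rscript inst/cli/dendroiso.R simulate --seed 7 --out study/
Rscript inst/cli/dendroiso.R calibrate --dates study/dates.csv \
    --curve study/curve_prebomb.14c --postbomb-curve study/curve_postbomb.14c \
    --out-intervals study/intervals.csv
```

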