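# aerodyn

Seasonal dynamics of airborne bacterial abundance from local generation
and regional dispersal.

Airborne bacteria at a monitoring site come from two places: **local
generation** (LG) — aerosolization from nearby soils, water and
vegetation, governed by humidity, pressure and cloud cover — and
**regional dispersal** (RD) — dust-borne cells transported thousands of
kilometres from arid source regions. Multi-year monitoring campaigns
quantify this with qPCR totals of the 16S rRNA gene (copies·m⁻³),
amplicon read compositions, local PM10 and meteorology, desert-station
air-quality indices, and back-trajectory air-mass pathway labels.
`aerodyn` is for the scientists running such campaigns: it implements
the whole analysis chain as tested, composable R functions, plus a
seeded synthetic-world generator with known ground truth so every
estimator can be validated by recovery experiments.

What the package computes:

* **Absolute abundance** — bacterial read fraction (excluding
  chloroplast/mitochondrial amplicons, which surge in spring) scaled by
  qPCR totals: `log10(total_copies × fraction)`; seasonal-average and
  linear-interpolation gap filling with per-point provenance; ISO-week
  aggregation.
* **Time series** — weighted-moving-average imputation
  `x_t = (1/6)x_{t−3} + (1/3)x_{t−2} + (1/2)x_{t−1}`, WMA-based outlier
  correction, the annual harmonic `Y = c + a·sin(2πt) + b·cos(2πt)`
  with amplitude `√(a²+b²)` and peak-timing phase, phase lags in weeks
  between fitted cycles, a Parseval-exact periodogram, classical
  decomposition and monthly climatologies.
* **Correlation network** — pairwise-complete Spearman matrix with
  t-approximation p-values, collinearity pruning at |ρ| > 0.8,
  significance-filtered edges (p < 0.05), greedy-modularity modules,
  focal subnetwork extraction, SIF/GraphML/CSV export.
* **Dust events** — official events (hourly PM10 > 150 µg·m⁻³ for more
  than two consecutive hours) and desert-pathway PM10 spikes
  (> 45.0 µg·m⁻³); before/during/after effect ratios on linear
  abundance with paired tests on the log scale.
* **Dust immigration** — AQI→PM10 breakpoint inversion (editable YAML
  table), daily pathway frequencies, and the smoothed
  desert-PM10 × pathway-frequency immigration index.
* **Structural equation model** — a from-scratch maximum-likelihood
  engine (RAM formulation, `Σ(θ) = F(I−A)⁻¹S(I−A)⁻ᵀFᵀ`, L-BFGS-B with
  multi-start) for the latent model `LA = LG + RD`, with standardized
  solutions and TLI / RMSEA / SRMR fit indices.
* **Pipeline** — `run_full_analysis()` composes all stages
  deterministically from a config and a seed, and writes a validated
  JSON report plus CSV and Cytoscape-ready network exports.

## A worked example

```r
library(aerodyn)
report <- run_full_analysis(seed = 1)
report
```

```
Airborne-bacteria analysis report
  abundance: 4.32 +/- 0.55 log10 copies/m3 (n = 314)
  harmonic R2: abundance 0.73, local PM10 0.80, desert PM10 0.77
  abundance lags desert PM10 by 4.6 weeks
  events: 11 official, 103 spikes
SEM fit: chi2(17) = 25.50 (n = 213), F_ML = 0.1203
  TLI = 0.991, RMSEA = 0.049, SRMR = 0.034
  standardized paths:
    LA ~ LG = 0.509
    LA ~ RD = 0.269
```

Reading the numbers: the synthetic campaign produced 314 samples whose
adjusted bacterial abundance averages 4.32 ± 0.55 log10 copies·m⁻³; the
annual harmonic carries most of each weekly series' variance; the
bacterial cycle peaks 4.6 weeks after the desert dust cycle (the
generator's configured truth is 4 weeks); eleven official dust events
were detected in the hourly PM10 stream; and the structural model
attributes more of the day-to-day aerosol variation to local generation
(standardized path 0.51) than to regional dispersal (0.27), both
positive, with good fit. `tidy(report$sem)` and `glance(report$sem)`
give the estimates as tibbles; `autoplot(report$harmonics$abundance)`
draws the fitted annual cycle; `write_report(report, "out/")` writes
the JSON report, CSV series and GraphML/SIF networks.

The same functions run on real campaign tables: anything with the
documented columns (`date`, `total_copies`, `reads_*`; daily PM10 and
meteorology; hourly PM10; trajectory labels) drops straight into the
individual stage functions or into `run_full_analysis(world = ...)`.

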