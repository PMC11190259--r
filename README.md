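# sstshift

Attribution of coastal species persistence and local extirpation to
components of sea-surface-temperature (SST) change between two survey
periods.

Populations at a species' warm range edge disappear for reasons that the
warming trend alone rarely explains. `sstshift` decomposes a gridded daily
SST record into the candidate drivers — gradual warming (annual and seasonal
means), discrete extreme events (marine heatwaves and cold spells detected
against a fixed-baseline day-of-year percentile climatology), and temporal
variability (unbounded seasonality a/b, spectral colour of noise β,
coefficient of variation, consecutive disparity index D, skewness, and
species-specific thermal-threshold exceedance) — contrasts each statistic
between a baseline (1982–1990) and a resurvey (1991–2015) period as
anomalies, and asks which anomalies discriminate sites where a species
persisted (1) from sites where it was extirpated (0).

The attribution core is a **hierarchical partitioning of binomial
goodness-of-fit**: for K ≤ 12 candidate anomalies the deviance explained by
every subset is computed and each variable's independent contribution is its
Shapley value,

    I_k = Σ_{S ⊆ X∖{k}}  s!(K−1−s)!/K! · [gof(S ∪ {k}) − gof(S)],

with J_k = gof({k}) − I_k the joint part and Σ I_k equal to the full-model
fit. Significance comes from a 100-repetition randomization test (upper 0.95
confidence limit); large variable sets are handled by the iterative
protocol (per-event-kind pre-selection at the 0.75 I-quantile, final run of
at most 12 variables, "relevant" = I above the final-run median). Variable
redundancy is screened beforehand (Pearson r ≥ 0.70 at p < 0.001, then
VIF- and AIC-guided exclusion among event variables), and the selected
variables are ordinated by two-dimensional NMDS (Euclidean distances, 100
random starts) with permutation-tested environmental vectors.

A fully synthetic data generator (gradient grid, seasonal cycle with
period-varying amplitude, AR(1) or 1/f^β noise, injectable warm/cold events,
logistic species outcomes) makes every stage testable offline.

## Worked example

```r
library(sstshift)

cfg  <- simulationConfig(nSites = 1L, seed = 42)   # 34-yr daily series
s    <- simulateSeries(cfg, 1)
clim <- buildClimatology(s)                        # 11-day window, 31-day smooth
ev   <- detectEvents(s, clim, "MHW")

nrow(ev)                                           # 78 heatwaves in 34 years
head(ev[, c("start", "duration", "intensity_max", "category")], 1)
#>        start duration intensity_max category
#> 1 1983-10-15        5      1.757253        1

base <- slicePeriod(s, baselinePeriod())
res  <- slicePeriod(s, resurveyPeriod())
meanSST(res) - meanSST(base)                       # 0.34 degC warming
seasonalityRatio(base); seasonalityRatio(res)      # 5.19 -> 5.80
noiseColour(s)$beta                                # 1.47, "red" noise
summarizeEvents(ev, baselinePeriod(), "annual")$frequency   # 1.44 events/yr
summarizeEvents(ev, resurveyPeriod(), "annual")$frequency   # 2.60 events/yr
```

The series warms by 0.34 °C between periods, heatwave frequency nearly
doubles (1.44 → 2.60 events/yr against the fixed 1982–2015 climatology), the
seasonal signal-to-noise ratio a/b rises from 5.19 to 5.80, and the daily
noise is strongly reddened (β = 1.47) — exactly the kind of multi-component
change the attribution stage disentangles.

The full chain — anomaly table, screening, hierarchical partitioning, NMDS —
runs from one call:

```r
res <- runPipeline(defaultConfig(), outDir = "run1", seed = 1)
res$manifest$relevant        # per-species variables above the final-run median
res$manifest$axis1_effect    # NMDS axis-1 rank-biserial separation
```

which writes `variable_table.tsv`, per-species `hp_*.tsv`, `nmds_scores.tsv`,
`nmds_vectors.tsv` and a `manifest.json` (seeds, config hash) to `run1/`.
`inst/scripts/sstshift.R` wraps the same calls for shell use.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

re-runs the end-to-end pipeline on the bundled synthetic configuration (12
sites, two synthetic species, 1982–2015) from the installed package and
writes the acceptance JSON to `--out`; progress and the per-species relevant
variables are logged to stderr.

## Layout

- `R/` — data model (`DailySeries`, `SSTGrid`, `Climatology`), simulator,
  event detection, variability statistics, anomaly table, screening,
  hierarchical partitioning (`HPResult`), ordination, pipeline.
- `src/` — compiled 2^K-subset logistic sweep (RcppArmadillo).
- `tests/testthat/` — unit, property and acceptance suites with independent
  brute-force oracles (naive event detector, all-orderings Shapley,
  O(n³) agglomeration, pooled-percentile climatology).
- `vignettes/sst-decomposition.Rmd` — model, assumptions, tunables, and the
  design decisions behind every ambiguous convention.
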