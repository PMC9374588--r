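# beemon

Biodiversity dynamics for season-long wild bee monitoring.

`beemon` is an R package for analysing multi-year, continuously sampled
(weekly trap) monitoring of wild bee communities — the kind of design where
passive traps at a handful of sites are emptied every week from April to
October for several years, every specimen is identified to species, and the
question is how the community changes *within* years (phenology) and
*across* years (population trends). It is aimed at community ecologists and
pollinator-monitoring programs that want a tested, reproducible pipeline
rather than a folder of one-off scripts.

## What it computes

For a specimen-level table (one row per captured individual: species, site,
trap, date) the pipeline builds community matrices under two aggregation
schemes — per month (metrics averaged across years, then across nearby
sites, giving 4 replicates per month) and per year (counts summed across
months) — and derives:

* **Diversity**: abundance, richness *S*, inverse Simpson's
  *D* = 1/Σpᵢ², Simpson evenness *D*/*S* (Pielou's *J* optional),
  individual-based rarefaction E[Sₙ] = Σᵢ[1 − C(N−nᵢ, n)/C(N, n)], and
  species accumulation over individuals.
* **Phylogenetic structure**: a genus-level tree is forced ultrametric,
  species are grafted as random bifurcating subtrees along the genus
  terminal edges, and each community is scored by SES-MPD =
  (MPD_obs − mean MPD_null)/sd MPD_null against richness-matched random
  draws from the species pool (negative = clustered, positive = even).
* **Composition**: Bray–Curtis dissimilarities Σ|xᵢ−yᵢ|/Σ(xᵢ+yᵢ), NMDS
  ordination (Kruskal stress-1, multi-start), and one-factor perMANOVA
  with permutation p-values.
* **Trends**: 5-knot regression-spline fits of each metric against month
  and year (adjusted R², overall F); per-species standardized abundance
  slopes — yearly totals scaled to mean 0 / sd 1, OLS on year, slope × 5 =
  predicted change over the study in SD units — with significance classes
  (stable p > .1, weak .05 < p ≤ .1, decline/increase p ≤ .05, strong
  p ≤ .01) and power diagnostics (abundance–change and CV–change
  correlations).
* **Phenology**: per species, seasonality (median day of year of capture)
  and breadth (10th–90th percentile span), computed on 500 random draws of
  30 individuals and averaged, so unequal sample sizes do not distort the
  comparison.
* **Trait models**: OLS and Brownian-motion PGLS
  (β̂ = (XᵀC⁻¹X)⁻¹XᵀC⁻¹y, C = shared branch length) of the 5-year change
  on each natural-history trait.

A synthetic-data module (`sim_config()`, `simulate_dataset()`) generates
specimen tables with the statistical structure the analysis assumes —
steep lognormal rank abundance, species-specific Gaussian activity windows,
8 sites × 2 traps, weekly collections, per-species year trends, a pure-birth
genus tree — together with the ground truth, so every estimator in the
pipeline is covered by parameter-recovery tests.

## Worked example

```r
library(beemon)

# a full simulated monitoring campaign: 144 species, 6 years, 8 sites
bundle <- run_all(run_config(simulate = TRUE, seed = 1))

ms <- bundle$tables$metrics$month_summary
aggregate(abundance ~ month, ms, mean)
#   month abundance
#       4       6.6
#       5      30.6
#       6      50.8
#       7     102.1
#       8     154.2
#       9     100.3
#      10      28.7

percent_change(m_low = 6.6, m_high = 154.2, m_overall = 67.6)
# [1] 218  -> seasonal peak is +218% of the overall monthly mean
```

The simulated season peaks in late summer at 154 bees per site against an
overall monthly mean of 68 — a percent-change effect size of +218%. On the
published per-site means of the motivating study (April 21, July 168,
overall 76) the same statistic is

```r
round(percent_change(21, 168, 76))
# [1] 193
```

Rarefaction shows why spring matters despite low catches: standardized to
400 individuals, April/May communities hold the most species even though
their raw abundance is lowest:

```r
month_rarefaction(bundle$tables$specimens, n = 400)
#  month individuals richness rarefied_richness
#      4         317       32                NA   (fewer than 400 caught)
#      5        1470       51              34.1
#      7        4903       49              22.2
#      8        7400       51              20.1
```

Per-species trends on this null-trend simulation classify 84.8% of the 33
focal species (≥ 30 individuals) as stable, with 6.1% showing decline
evidence and 9.1% increase evidence — the false-positive rate expected of
the p ≤ .1 thresholds — and a perfectly linear series returns the
closed-form change of `5/sd(2014:2019)` = 2.6726 SD:

```r
species_trend(c(10, 20, 30, 40, 50, 60), 2014:2019)$change_5yr
# [1] 2.672612
```

## Command line

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "beemon.R", package = "beemon"))') \
    run --simulate --seed 7 --out run7/
```

Subcommands: `simulate`, `run`, `summarize`, `phylo`, `compose`, `trends`,
`phenology`, `traits`. Configuration is JSON (`--config`), mirroring
`run_config()`; outputs are tidy CSVs plus a `manifest.json` that records
the master seed and its per-stage substreams, so any table can be
regenerated bit-identically.

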