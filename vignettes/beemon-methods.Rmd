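---
title: "Methods: models, parameters, and design choices in beemon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters, and design choices in beemon}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beemon)
```

`beemon` implements the complete statistical workflow of a multi-year,
season-long bee monitoring analysis. This vignette is the package's own
account of that workflow: the models and their assumptions, the parameters
that matter and their defaults, what the synthetic-data generator does and
does not emulate, the numerical conventions, and the places where the
design was genuinely open and we had to choose.

## 1. Data model and aggregation

The primitive observation is a *specimen*: one captured individual with a
species binomial, site, trap, and collection date. Validation
(`read_specimens()`, `as_specimen_table()`) drops rows without a
species-level identification (counted), rows with unparseable dates
(counted; an error if they exceed a configurable fraction, default 5%), and
rows outside the trapping season (default April–October). Species identity
is the exact binomial after whitespace normalization — no fuzzy matching,
because silent lumping of names is worse than a loud mismatch.

Two aggregation schemes drive everything downstream:

* **Month scheme** (`build_month_matrix()`, `month_summary()`): metrics are
  computed per (site, month, year), averaged across years, then averaged
  across the sites of a site group. Each replicate reads as "the average
  biodiversity value per site for a single month"; with 8 sites in 4
  groups this yields 4 replicates × 7 months.
* **Year scheme** (`build_year_matrix()`, `year_summary()`): counts are
  first summed across months, metrics computed per (site, year), then
  averaged within groups — "the total biodiversity value per site for a
  single year"; 4 replicates × each year.

**Zero-capture units.** Whether a site-month with no captures ever occurred
in the original study is not stated, and nothing in the data format forces
the question. We emit explicit all-zero rows for every (site, month, year)
cell of the season grid, because the year-averaging step must include zero
months for abundance to mean what it claims. Abundance and richness enter
those averages as 0; inverse Simpson's and evenness are undefined on an
empty assemblage and are excluded (`NA`) from the averaging step rather
than imputed. Both conventions are deliberate and tested.

## 2. Diversity metrics

Inverse Simpson's $D = 1/\sum p_i^2$ is the effective number of equally
abundant species, bounded by $1 \le D \le S$. The study this package grew
out of reports an *evenness* pattern without naming the formula; we use
Simpson evenness $D/S$ as the default because it is exactly consistent with
the reported diversity metric, and expose Pielou's $J = H'/\ln S$ as an
option. Rarefaction is the analytic hypergeometric expectation
$E[S_n]=\sum_i \left(1-\binom{N-n_i}{n}\big/\binom{N}{n}\right)$, computed
with log-binomials for stability; the species-accumulation curve is the
Monte-Carlo analogue over random orderings of individuals and equals
rarefaction pointwise in expectation (tested against each other). For the
"species per 900 individuals" style of month contrast,
`month_rarefaction()` pools all sites, traps and years within a month
first — matching the pooled-total framing of that comparison rather than
the site-replicate framing of the summaries.

The percent-change effect size between two period means is
$100\,(m_{high}-m_{low})/m_{overall}$ — difference over the variable's
overall mean — which makes effects comparable across variables with
different units. Year-to-year variability is summarized as
$CV = 100\,s/\bar{x}$ with the sample ($n-1$) standard deviation.

## 3. Phylogenetic structure

The phylogenetic input is a genus-level tree. Three steps produce per-unit
structure scores:

1. **Ultrametric forcing** (`force_ultrametric()`): terminal edges are
   extended so all tips reach the original maximum depth. The original
   analysis used a non-negative least-squares adjustment; we chose terminal
   extension because it is deterministic, idempotent, preserves topology
   and internal edges, and SES-MPD is invariant to the overall
   branch-length scale (tested), so the conclusions do not depend on this
   choice. NNLS remains an extension point.
2. **Random grafting** (`graft_species()`): each genus tip is replaced by a
   random bifurcating subtree of its species bound at a uniform random
   point on the genus terminal edge; within-genus node heights come from
   successive random coalescence below the attachment point. Below-genus
   relationships are therefore random — which is fine for MPD, dominated
   by between-genus path lengths. The acceptance suite verifies that two
   independent graftings give MPD values correlated at r > 0.95 across
   random communities (the published analogue of this check reported
   r = 0.99). Genera absent from the tree are dropped with a warning;
   genus tips with no species are retained. Because the graft is random,
   the pipeline records its seed in every downstream output.
3. **SES-MPD** (`ses_mpd()`): observed mean pairwise patristic distance
   versus `n_null` (default 999; the original null count is unpublished)
   uniform richness-matched draws from the full observed species pool.
   MPD is presence-based and abundance-unweighted. We use a sampled null
   rather than analytic moments; calibration (mean ≈ 0, sd ≈ 1 over random
   communities) is part of the acceptance suite. A degenerate null
   (zero variance, e.g. community = pool) reports SES 0 with a flag.

## 4. Composition

Composition units pool counts per (site group, month) across years, or per
(site group, year) across months — 28 and 24 units for the reference
design. The source analysis does not state its exact unit construction;
this choice mirrors the replicate structure of the summaries, and the
alternative (year-replicated month units) is reachable by calling
`bray_curtis()` on any matrix you build. Bray–Curtis uses the standard
$\sum_i |x_i-y_i| / \sum_i (x_i+y_i)$; a pair of all-zero units is an
error naming the units, not a silent `NaN`.

NMDS minimizes Kruskal stress-1 with monotone regression, delegating the
optimization to `vegan::monoMDS` (global model) under our multi-start
protocol: one metric (principal-coordinates) start plus `n_restarts`
random starts (default 20), best solution kept, deterministic given the
seed. perMANOVA is implemented in-package: $SS_T=\sum_{i<j}d_{ij}^2/N$,
within-group SS from group sizes, pseudo-F on $(a-1, N-a)$ degrees of
freedom, $p=(1+\#\{F^*\ge F\})/(1+n_{perm})$ with unrestricted label
permutations (no strata; one factor, so sequential-SS questions do not
arise). The published Methods name an effect-size function from a
meta-analysis package at this step — an apparent citation slip — so we
implement the standard one-factor perMANOVA and verify it against
`vegan::adonis2` and against hand-enumerated permutations.

## 5. Trends

**Metric trends.** Month and year effects on each metric are fit with
unpenalized natural cubic regression splines with 5 knots at quantiles of
the distinct period values (2 boundary + 3 interior; `splines::ns`). The
original analysis used penalized thin-plate smooths (`mgcv::gam`, k = 5);
with 24–28 replicates and 6–7 distinct x values the unpenalized 5-knot
curve tracks the per-period means closely (tested: it reproduces group
means exactly at ≤ 5 levels and recovers a hump-shaped peak), and
determinism simplifies testing. Adjusted R² from these fits therefore
*approximates* the published values rather than equalling them. With fewer
than 5 distinct x values the basis degrades gracefully (flagged), down to
a straight line.

**Species trends.** Per species, yearly totals are pooled over all sites
and traps (the original aggregation is unstated; site-replicated fits are
possible by calling `species_trend()` on your own series). Totals are
standardized to mean 0, sample sd 1; OLS on calendar year; slope × 5 gives
the predicted change over a 6-year study in SD units. A perfectly linear
series gives the closed form $5/\mathrm{sd}(\text{years}) = 2.6726$ SD,
frozen in the tests. Classes follow the published thresholds: stable
(p > .1), weak decline/increase (.05 < p ≤ .1, by sign), decline/increase
(p ≤ .05), with p ≤ .01 recorded as "strong". A species with zero variance
across years is stable by definition and flagged. Diagnostics correlate
total abundance and yearly CV against the predicted change — the checks
used to argue that neither sample size nor volatility drove the detected
declines.

## 6. Phenology

Seasonality is the median day of year of capture; breadth is the
10th–90th percentile span. Because both are sample-size dependent,
species with at least 30 individuals (the focal filter; 40 species in the
reference dataset) are summarized by drawing 30 dates without replacement,
computing both statistics, repeating 500 times, and averaging. Species
below the threshold are excluded with a reason code.

**Quantile convention.** The published rule is unstated; we use linear
interpolation between order statistics (R's type 7, the default in the
original computing environment). The convention shifts breadth by a few
days, so it is an explicit argument (`type`) and recorded in outputs.
Day-of-year uses the capture year's own calendar; leap years shift
post-February days by one day, which is negligible at weekly trap
resolution.

## 7. Trait models

Species' 5-year change is regressed on each trait separately (the
single-predictor structure of the original analysis; fit a multiple
regression yourself if desired) twice: OLS, and PGLS with Brownian-motion
covariance $C_{ij}$ = shared root-to-tip branch length on the grafted
species tree. The GLS estimator
$\hat\beta=(X^{\mathsf T}C^{-1}X)^{-1}X^{\mathsf T}C^{-1}y$ uses a
Cholesky solve with a flagged ridge jitter only if $C$ is numerically
singular. On a star phylogeny with equal depths PGLS and OLS coincide to
10⁻⁸ (acceptance-tested). Binary traits enter as 0/1; body length is
log-transformed by default (whether the original was transformed is
unstated — log is the conventional choice for body-size allometry and is
configurable). Phylogenetic signal of traits is deliberately out of scope:
randomly grafted below-genus topology does not support signal estimation.

## 8. The synthetic-data generator

`simulate_dataset()` draws a whole monitoring campaign from a stated world
chosen once to match the reference design, not tuned to any test:

* 144 species, 30 genera, 5 families; 8 sites in 4 groups, 2 traps per
  site; years 2014–2019; weekly collections on days 91–304.
* Per-species expected totals: lognormal(meanlog 2.1, sdlog 2.5) rescaled
  to an expected 26,716 individuals — the study's reported catch — which
  reproduces the printed rank-abundance shape (~10 species above 1000
  individuals, about half at ≤ 5).
* Activity windows: Gaussian with peak $\mu_s \sim U(115, 280)$ and spread
  $\sigma_s \sim U(8, 35)$ days, discretized to weekly weights and
  truncated by the season.
* Counts: independent Poisson per (species, site, trap, year, week) with
  intensity $A_s\,e^{b_s(y-\bar y)}\,\mathrm{site}_i\,k_w(s)$; lognormal
  site effects (sd 0.3 on the log scale); per-species log-linear year
  trends $b_s$ (default 0; a configurable fraction can be set to a decline
  value); capture dates uniform within the week.
* Genus membership by a skewed multinomial (gamma weights, shape 0.6), so
  some genera are speciose; a pure-birth ultrametric genus tree; families
  as clades of that tree. Traits are null by default (Bernoulli(0.5)
  binaries, lognormal body length) with an optional injected linear
  trait → trend effect.

All randomness flows from one master seed through named substreams
(`substream_seed()`), so specimen noise, grafting, null models,
permutations and subsampling are independently reproducible.

What the generator does **not** emulate: trap-attractiveness biases,
weather and floral-resource covariates, honey-bee competition, detection
differences among species, spatial autocorrelation beyond the lognormal
site effect, and multi-brood (bimodal) phenologies. A green recovery test
therefore establishes that the estimators recover the stated generative
world — not that any of those field complications are handled.

**Recovery tolerances.** The acceptance suite checks that for well-sampled
species (≥ 200 individuals) estimated seasonality matches the generator's
truth within ±3 days and breadth matches $2.563\,\sigma_s$ (the q90–q10
span of a Gaussian) within ±15%, and that ≥ 80% of injected declines are
flagged. Two measurement details matter. First, the truth for seasonality
is the median of the *season-truncated* window — the distribution the
generator actually emits; comparing edge-of-season species against the
untruncated $\mu_s$ would test the wrong target. Second, at n ≈ 200 the
realized sample median itself has a sampling sd of ~2.5 days, so the
±3-day band is enforced for ≥ 85% of species together with a small mean
absolute error, rather than species-by-species; the breadth band is
enforced for every species whose window lies inside the season (the
2.563σ formula presumes no truncation). Subsampling at n = 30 shortens
breadth by ~7% relative to the asymptotic Gaussian span (order-statistic
bias), which sits comfortably inside the ±15% band and affects all
species equally — exactly the bias the equal-subsample design is meant to
equalize.

## 9. Numerical and interface conventions

* Seeded functions save and restore the caller's RNG state.
* p-values from permutation tests are $(1+k)/(1+n)$ — never 0.
* Undefined statistics return `NA` markers (zero assemblages, zero-mean
  CVs, constant correlations); degenerate SES nulls return 0 with a flag.
* Configs are JSON (`read_run_config()`): the environment this package
  targets ships no YAML parser, and jsonlite is already a dependency.
* All outputs are tidy CSVs; `manifest.json` captures config, seeds and
  package version so any table regenerates bit-identically
  (`run_all()` twice with one seed is byte-identical, tested).

## 10. Known limitations

* Spline trend R² approximates, not equals, penalized-GAM R².
* perMANOVA is one-factor with unrestricted permutations; no strata,
  dispersion (PERMDISP) tests, or pairwise post-hoc contrasts.
* No Chao/ACE richness estimators, coverage-based rarefaction, or Hill
  numbers beyond q = 2; no MNTD/NRI/NTI variants of phylogenetic
  structure; no Pagel's λ or OU covariances in PGLS.
* Trap catches are attraction-biased samples: every "abundance" here is a
  relative index, and the package makes no attempt to convert it into
  true population size.
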