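---
title: "Core and conditionally rare taxa: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Core and conditionally rare taxa: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crtcore)
```

## The problem

Freshwater bacterial communities sampled repeatedly over a season are
dominated, numerically, by a huge tail of taxa seen once or twice at trace
abundance. Two much smaller subcommunities carry most of the interpretable
temporal signal: a **core** of taxa that are consistently present and
abundant, and **conditionally rare taxa (CRT)** that sit at or below the
detection limit most of the time but surge episodically when conditions
change (storm flow, nutrient pulses, drought concentration). `crtcore`
implements the selection of both subcommunities from a rarefied ASV count
table, quantifies how much of the community's compositional heterogeneity
each explains through time, and summarises temporal constancy and
environmental drivers.

## Models and procedures

### Rarefaction

Counts are subsampled without replacement (multivariate hypergeometric) to a
common depth per sample; samples below the target depth are dropped rather
than kept at native depth, so every retained column sums exactly to the
depth. The draw is delegated to `vegan::rrarefy()` under a mandatory seed:
rarefaction is a random operation and unseeded results are unreproducible.
Whether to average several rarefaction draws is left to the caller (run
`rarefy()` with several seeds); the pipeline itself uses a single seeded
draw.

### Abundance–occupancy ranking and core selection

Each ASV in the analysis group receives two criterion ranks: occupancy
(fraction of samples with a nonzero count) and mean per-sample relative
abundance, both ranked "higher is better" with average ranks on ties. The
composite score is the *mean of the two criterion ranks* — a symmetric
weighting, configurable through `occupancy_weight` for variants that
privilege occupancy. Exact composite ties are broken by higher mean
abundance, then lexicographic ASV id, so the ranking is a deterministic
permutation.

Bray–Curtis dissimilarity between two count vectors,
$BC(x, y) = \sum_i |x_i - y_i| / \sum_i (x_i + y_i)$,
has a numerator that is additive over taxa. Pooling numerators over all
unordered sample pairs in the group gives each taxon an exact share of the
whole-community heterogeneity, and the cumulative share of the top-$k$
ranked taxa defines the explained curve

$$\mathrm{explained}(k) =
  \frac{\sum_{\text{pairs}} \sum_{i \le k} |x_i - y_i|}
       {\sum_{\text{pairs}} \sum_{i} |x_i - y_i|}.$$

This pooled (sum-over-pairs) decomposition is chosen deliberately over a
mean-of-ratios: it is the only aggregation under which the curve is
guaranteed non-decreasing with $\mathrm{explained}(n) = 1$, which in turn is
what makes a *stepwise marginal gain* well defined. The core is the top
$k_\mathrm{sel}$ taxa where $k_\mathrm{sel}$ is the largest $k$ whose
marginal gain exceeds the threshold (default 0.005): selection ends when the
last included ASV explains an additional 0.5% or less of community
beta-diversity. All samples of the analysis group enter one pairwise pool
(no temporal blocking), matching multi-year pooling of the group. A useful
identity for large tables: the pooled per-taxon numerator equals
$\sum_k (2k - n - 1)\, v_{(k)}$ over the taxon's sorted sample values, which
avoids enumerating the $\binom{n}{2}$ pairs.

The related literature alternates between phrasing this ratio with
"similarity" and "dissimilarity"; the two are complementary, and only the
dissimilarity share yields a coherent stepwise-gain rule, so that is what is
implemented.

### CRT detection

For every non-core ASV, the per-sample relative-abundance series within the
group is screened in two steps:

1. **Abundance screen.** The ASV must reach at least `abundance_threshold`
   (default 0.001, i.e. 0.1%) in *some* sample. The maximum is the right
   statistic for sporadically abundant taxa — a mean would discard exactly
   the taxa of interest.
2. **Bimodality.** The coefficient of bimodality
   $b = (g_1^2 + 1) \big/ \left(g_2 + \frac{3(n-1)^2}{(n-2)(n-3)}\right)$
   with $g_1$ the sample skewness and $g_2$ the sample excess kurtosis,
   both with small-sample (SAS-convention) corrections, must reach
   `b_threshold` (default 0.90, applied as $\ge$). A two-state series —
   rare baseline, occasional surges — has population $b = 1$ regardless of
   the fraction of surging samples; within-state spread lowers it.

Core and CRT are mutually exclusive: the core set is removed before
screening, so a partition of analyzed taxa into core / CRT / other is exact.
Observations are individual samples (site × date) within the group.
Degenerate series (short, constant, screened out) are reason-coded with
`is_crt = FALSE`, never errors, since they are expected in bulk on real
tables. An optional `min_rare_fraction` switch additionally requires the
taxon to be *rare* (below the abundance threshold) in a minimum fraction of
samples; it is off by default because the bimodality requirement already
enforces a dominant rare state in practice, but it is exposed for strict
conditional-rarity definitions.

A consequence of the small-sample correction worth knowing: with $n = 20$
observations even a perfectly clean two-state series cannot exceed
$b \approx 0.87$, because the correction term in the denominator exceeds 3.
From roughly $n \ge 30$ the threshold 0.90 behaves as intended. Detection on
short series is therefore conservative by construction.

### Contribution series

At each sampling date the unordered pairs of sites observed that date are
pooled: the subcommunity's contribution is 100 × (sum of its partial
Bray–Curtis numerators over pairs) / (sum of full numerators). Sum/sum
pooling again preserves additivity — disjoint subcommunities' percentages
sum to the percentage of their union — and avoids instability when a single
pair's dissimilarity is near zero. Dates with fewer than two samples are
skipped with a reason (a single site cannot yield a cross-site
dissimilarity; this mirrors excluding solitary reference sites from
contribution analyses). An optional block map averages paired sites'
count vectors before pairing, for designs where two nearby stations on one
watershed act as one unit.

### Stability and drivers

Community stability (constancy) of a subcommunity is the temporal mean of
its summed abundance divided by the sample (n−1) standard deviation over the
within-year series of sampling dates — the reciprocal of the coefficient of
variation, computed per site (or block) per year with at least three dates
and no gap interpolation (drought-shortened seasons simply shorten the
series). Cross-class comparison of stabilities (mixed models and post-hoc
tests) is standard-package territory and out of scope here; the table of
per-unit-year values is the hand-off point.

Driver screening is Spearman's rank correlation of a matched per-(site,
date) series against each covariate, with two-sided p-values and
Benjamini–Hochberg adjustment across the covariate family (the adjustment
choice is configurable territory; BH is the default because covariate
families of 15–30 weather/hydrology/chemistry variables are typical and a
family-wise bound would be needlessly conservative). Stars mark adjusted
q at 0.05/0.01/0.001/0.0001.

## The synthetic community

`simulate_community()` exists so every stage is testable end-to-end with
known ground truth, without any sequencing download. Defaults emulate the
motivating study design: 8 sites (half agricultural-ditch, the rest mixed
plus one forest reference), 14 bi-weekly dates from mid-April × 2 years,
13,430 reads per sample drawn multinomially (tables are born rarefied; a
`variable_depth` mode produces uneven totals to exercise `rarefy()`).

Latent per-sample weights before renormalisation:

* **Core** (50 taxa): i.i.d. lognormal, `meanlog = log(0.01)`,
  `sdlog = 0.6`, at every sample — occupancy ≈ 1 and high mean abundance,
  with enough temporal scatter that each core taxon carries a nontrivial
  share of pairwise dissimilarity.
* **CRT** (100 taxa): a rare baseline of 1e-4, except on shared **event
  dates** drawn per date with probability 0.12 (roughly 3 events per
  simulation), when each (site, taxon) joins the surge with probability 0.7
  at a lognormal magnitude around 5e-3 (50× the baseline) with tight
  scatter (`sdlog = 0.15`). Three deliberate choices here:
  events are *shared across taxa and sites* because per-taxon independent
  spike dates would give every date the same expected number of surging
  taxa and hence no date-level contrast to detect (episodic, community-wide
  surges are the phenomenon of interest); partial participation makes
  sites differ on event dates, so events register in cross-site
  dissimilarity; and the tight magnitude scatter keeps the planted series
  genuinely two-state — a wide scatter smears the upper mode, inflates
  kurtosis, and the planted class would no longer be bimodal by its own
  construction.
* **Background** (2,000 taxa): per-taxon occupancy uniform on [0.01, 0.3]
  and lognormal weights (`meanlog = log(3e-6)`, `sdlog = 1.2`) when
  present, calibrated so the large majority of background taxa total fewer
  than 10 reads across the whole table, as in real ASV tables where most
  of the richness is singleton-scale.
* **Site-specific core** (`n_core_site`, default 0): optionally, taxa
  abundant and persistent only at one land-use class — used to demonstrate
  that group-restricted core selection differs from cross-site selection.

Covariates are smooth seasonal curves (discharge high in spring/fall,
temperature peaking mid-summer, nutrient and turbidity analogues) plus site
offsets and noise, named after typical hydrology/water-chemistry variables.
`covariate_coupling` ties event dates to high-discharge dates: at 0 events
are independent, at 1 they are confined to the top decile of site-mean
discharge. The default is 0 (neutral); the worked analysis scripts couple at
0.6 to emulate hydrologically driven surges.

What the generator does **not** emulate: taxonomic/phylogenetic structure,
compositional correlation between taxa beyond the shared renormalisation,
overdispersion beyond multinomial sampling, spatial autocorrelation between
sites, or drift in the core across years. Passing recovery tests on this
generator therefore demonstrate the pipeline's statistical machinery under
its stated model — not performance on real sequencing data, where
between-taxon dependence and overdispersion will loosen all margins.

A compositional caveat discovered during design and worth stating: at fixed
depth, the core's *absolute* counts necessarily dip on CRT event dates
(reads are a zero-sum budget), so the combined core+CRT total — equal to
depth minus the small background total — is *more* constant than the core
alone. The intuitive "adding volatile CRT makes the aggregate less stable"
holds for the CRT aggregate itself (orders of magnitude less stable than
the core) but not for the combined total. Stability comparisons on rarefied
tables should be read with this coupling in mind.

## Numerical choices and degenerate inputs

* Explained curves are validated non-decreasing to 1e-9; the final value
  equals 1 within 1e-9 by construction.
* An all-identical group (zero total dissimilarity) is an error for core
  selection; a zero-dissimilarity *date* in a contribution series is
  skipped with a reason.
* All-zero samples are flagged and left unnormalised by
  `relative_abundance()`, never divided.
* Zero-variance series: error for the scalar `bimodality_coefficient()`
  (the statistic is undefined), reason-coded non-CRT inside `detect_crt()`.
* Constant totals give `stability = NA` with a `degenerate` flag rather
  than `Inf`.
* Ranking ties: average criterion ranks, then abundance, then lexicographic
  id — fully deterministic.
* Seeds: every random operation (simulation, rarefaction) takes an explicit
  seed and restores the caller's RNG state (`withr::with_seed`), so a
  pipeline run is a pure function of (inputs, config, seeds) and reruns are
  byte-identical.

## Problem sizes used in validation

The shipped tests and the acceptance script run the generator at its default
design (2,150 taxa × 224 samples) for ten seeds, which completes in well
under a minute per stage; oracle-equivalence checks use 100 random small
instances (≤ 30 observations or ≤ 8 × 5 tables) against brute-force
reimplementations at 1e-12 tolerance. Unit tests use scaled-down designs
(3–4 sites, 5–8 dates, depths of 1,500–3,000) chosen to exercise the same
code paths at interactive speed.

## Known limitations

* The composite rank's symmetric weighting of occupancy and abundance is a
  convention; published variants weight occupancy first. The weight is a
  parameter, but the default is the symmetric mean.
* The marginal-gain rule reads the curve in ranked order; it does not
  re-rank after exclusions, and a taxon far down the ranking with a large
  individual share extends the core to its position.
* Contribution percentages compare *across sites at a date*; the
  complementary per-site-across-dates reading is not implemented.
* `detect_crt()` on groups with fewer than ~30 samples is conservative (see
  the small-sample bound on b above).
* No phylogenetic or taxonomic aggregation is provided beyond an optional
  genus-style grouping of driver series inputs done by the caller before
  `spearman_drivers()`.
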