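# crtcore

Core microbiome and conditionally rare taxa (CRT) analysis for temporal 16S
rRNA ASV count tables.

Repeatedly sampled freshwater communities (streams, agricultural drainage
ditches) carry most of their interpretable temporal signal in two small
subcommunities: a persistent, abundant **core**, and **conditionally rare
taxa** that stay near the detection limit but surge episodically with
environmental events. `crtcore` selects both from a rarefied ASV table,
quantifies their share of community heterogeneity through time, and
summarises temporal stability and environmental drivers. It is aimed at
microbial ecologists with a denoised count table and per-sample metadata in
hand (read processing, taxonomy, and mixed-model inference are upstream and
downstream of this package).

## Methods at a glance

* **Rarefaction** — without-replacement subsampling to a fixed depth, seeded
  and reproducible; under-depth samples are dropped (`rarefy()`).
* **Core selection** — ASVs ranked by the mean of their occupancy rank and
  mean relative-abundance rank; Bray-Curtis dissimilarity
  `BC(x,y) = Σ|xᵢ−yᵢ| / Σ(xᵢ+yᵢ)` decomposes additively over taxa, so the
  top-k ranked taxa have an exact explained share of the pooled
  whole-community dissimilarity; selection stops when the last included ASV
  adds ≤ 0.5% (`core_microbiome()`, `select_core()`).
* **CRT detection** — per-ASV relative-abundance series screened at max
  abundance ≥ 0.1%, then flagged when the coefficient of bimodality
  `b = (g₁² + 1) / (g₂ + 3(n−1)²/((n−2)(n−3)))` ≥ 0.90, with
  sample-corrected skewness g₁ and excess kurtosis g₂ (`detect_crt()`).
* **Contribution series** — per sampling date, the percentage of pooled
  cross-site Bray-Curtis dissimilarity attributable to a subcommunity
  (`contribution_series()`).
* **Stability** — temporal mean over sample SD of a subcommunity's summed
  abundance, per site and year (= 1/CV; `community_stability()`).
* **Drivers** — tie-corrected Spearman correlations against environmental
  covariates with Benjamini-Hochberg adjustment (`spearman_drivers()`).
* **Synthetic truth** — `simulate_community()` generates multi-site,
  multi-year tables with planted core / CRT / background taxa and coupled
  covariates, so the whole pipeline is testable against known ground truth.

## Worked example

The `analysis/` scripts run the full workflow on a simulated study (8 sites,
bi-weekly sampling over 2 seasons, 13,430 reads/sample; 50 planted core, 100
planted CRT, 2,000 background taxa):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_core_selection.R
Rscript analysis/03_crt_detection.R
Rscript analysis/04_contribution.R
Rscript analysis/05_stability_drivers.R
```

Output (abridged) from a run:

```
Core selection: 50 of 1940 ranked ASVs (marginal threshold 0.005)
core recovery: recall 1.000, precision 1.000 (k = 50)
core explains 87.5% of pooled Bray-Curtis dissimilarity

CRT detection: 99 flagged; recall 0.980, background FPR 0.0005

core           mean contribution 93.0% (range 57.4-97.4%)
crt            mean contribution 5.9% (range 1.6-41.0%)
CRT contribution on spike dates: mean 40.2% vs 1.8% off-event

median stability by subcommunity:
         core core_plus_crt           crt
         8.38        426.31          0.48
```

Read: the marginal-gain rule recovers exactly the 50 planted core taxa,
which carry 87.5% of the community's pooled heterogeneity; 98 of 100
planted CRT are flagged at b ≥ 0.90 with a 0.05% false-positive rate on
background taxa; the CRT share of cross-site dissimilarity jumps from ~2%
to ~40% on planted event dates; and the CRT aggregate is an order of
magnitude less constant over time than the core. Stage tables land in
`results/`.

On real data, replace the simulation with your own inputs:

```r
library(crtcore)
counts <- read_count_table("asv_counts.tsv")     # or format = "biom"
meta   <- read_sample_metadata("metadata.tsv")
counts <- rarefy(counts, depth = 13430, seed = 1)
core   <- core_microbiome(counts, threshold = 0.005)
crt    <- detect_crt(counts, core_set = core$core_set)
```

or drive everything from one configuration with `run_pipeline()`.

## Layout

* `R/` — package functions (all computation lives here)
* `analysis/` — numbered narrative drivers for the worked example
* `scripts/acceptance.R` — headline-quantity reproduction
* `tests/testthat/` — unit, property, and end-to-end tests with brute-force
  oracles
* `vignettes/core-crt-methods.Rmd` — models, parameter choices, generator
  design, and limitations
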