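# microcore

Community-ecology analysis of OTU-level amplicon surveys, built for the
question agricultural soil studies keep asking: which parts of a soil
bacterial community are shaped deterministically by the environment (soil
texture, chemistry, organic amendments such as farmyard manure, digestate
or slurry), which parts drift neutrally, and which taxa form a core
microbiome that persists across farms and treatments?

`microcore` takes a filtered OTU count table, sample metadata, and a rooted
phylogeny, and provides every stage of that analysis as plain R functions
returning classed objects with `print`/`summary`/`coef`/`predict`/`plot`
methods:

* **Preprocessing** — library-size filtering (strictly > 5,000 reads by
  default), contaminant-lineage removal (mitochondria, chloroplasts),
  total-sum scaling and the centred log-ratio transform.
* **Diversity and ordination** — rarefied Shannon and bias-corrected Chao1;
  Bray–Curtis and unweighted UniFrac distances; principal coordinate
  analysis; sequential PERMANOVA with permutation p-values; stepwise
  distance-based RDA variable selection; a distance-to-distance regression
  whose slope serves as a stability/resilience proxy.
* **Assembly null models** — abundance-weighted or unweighted βMNTD and the
  β nearest taxon index (βNTI) against a tip-shuffle null (z-score
  convention: βNTI < −2 indicates phylogenetic clustering / homogeneous
  selection, βNTI > +2 overdispersion), with the inner loop in C++.
* **Sloan neutral community model** — one-parameter (migration rate `m`)
  fit of the abundance–occupancy relationship with a 95% prediction band;
  taxa partitioned into *above* (environmentally selected), *neutral*, and
  *below* (dispersal limited).
* **Core microbiome** — abundance–occupancy ranking
  `Index = (site-specific occupancy + replication consistency) / 2`, the
  cumulative Bray–Curtis explanatory curve `E(k) = BC_core(k) / BC_all`
  (reported alongside its complement `C = 1 − BC_core/BC_all`), the 2%
  stopping rule, per-amendment occupancy models, Venn overlaps of fully
  prevalent cores, and an overlay of neutral-model partitions on the core.
* **Taxon–covariate models** — a generalised linear latent variable model
  (GLLVM), `g(μ_ij) = η_ij = β0_j + x_i'β_j + u_i'θ_j`, with negative
  binomial or Poisson counts, latent scores treated as standard-normal
  effects, and 95% CIs that propagate latent uncertainty; associations are
  labelled positive/negative when the CI excludes zero. And CODA-LASSO:
  sparse log-contrast regression with the compositional zero-sum
  constraint `Σβ = 0`, an elastic-net penalty, cross-validated penalty
  choice, and scale-invariant predictions.
* **Synthetic data** — a generator that emulates the target survey design
  (116 samples, 14 farms, four amendment groups with realistic imbalance,
  four textures, library sizes 5,079–41,827, lognormal metacommunity,
  Sloan-type neutral sampling, clade-confined environmental filtering)
  with full ground truth for calibration and recovery testing.
* **Pipeline** — `run_pipeline()` chains all stages under a single global
  seed with deterministic per-stage seed fan-out; reruns are byte-identical.

## Worked example

Simulate a survey with known ground truth and run the main analyses:

```r
library(microcore)

ds     <- simulate_dataset(sim_config(seed = 42))
counts <- filter_dataset(ds$counts, ds$taxonomy, min_reads = 5000)

fit <- fit_sloan_neutral(counts)
fit
#> Sloan neutral community model: m = 0.0701, R^2 = 0.952
#>   N = 23062 reads, detection limit 4.34e-05, 300 OTUs, 116 samples
#>   partition at 95% CI: 14 above / 230 neutral / 56 below
```

The fitted migration parameter `m = 0.07` says local communities are
fairly strongly dispersal-coupled to the regional pool; the high `R²`
means occupancy is mostly predictable from abundance alone, and the 14
taxa sitting **above** the 95% band are candidates for environmental
selection (the generator planted 30 filtered taxa; the strongly filtered
ones surface here).

```r
pm <- permanova(bray_curtis(counts), ds$metadata,
                c("amendment", "texture", "Ca", "LOI"),
                n_perm = 999, seed = 1)
pm
#> PERMANOVA (sequential SS, 999 permutations, n = 116)
#>                   df     sum_sq  r_squared pseudo_F p_value
#> amendment 3.0000e+00 5.5097e-01 6.1777e-02   2.4553   0.030 *
#> texture   3.0000e+00 1.8709e-01 2.0978e-02   0.8338   0.539
#> Ca        1.0000e+00 1.0881e-01 1.2200e-02   1.4547   0.193
#> LOI       1.0000e+00 6.8272e-02 7.6551e-03   0.9127   0.388
#> Residual  1.0700e+02 8.0035e+00 8.9739e-01
```

Amendment explains ~6% of compositional variance (p = 0.03) — the same
order of magnitude such covariates explain in real soil surveys, where
most variation is residual.

```r
cores <- occupancy_models(counts, ds$metadata,
                          model_var = "amendment", site_var = "farm_id")
cores[["all"]]
#> Core microbiome ('all' occupancy model): 9 of 300 taxa, E(k) = 0.272 (delta = 0.02)

neutral_overlay(cores[["all"]], fit)$counts
#>   above neutral   below
#>       0       9       0
```

Nine top-ranked taxa are retained before the next taxon adds less than 2%
explanatory value; on this draw all nine are consistent with neutral
assembly — matching the common finding that the most prevalent taxa are
abundant enough to be everywhere regardless of selection.

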