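---
title: "Methods and design notes for microcore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for microcore}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`microcore` analyses OTU-level amplicon surveys of soil (and similar
environmental) microbiomes: which community members are selected by the
environment, which drift neutrally, which form a persistent core, and how
individual taxa respond to measured covariates. This vignette documents the
models, the defaults and why they were chosen, the numerical decisions, and
what the synthetic-data generator does and does not emulate.

## Data model and preprocessing

The universal input is an integer count matrix with OTUs as rows and
samples as columns, a metadata table keyed by sample id, and a rooted
phylogeny with branch lengths covering the OTUs used in phylogenetic
metrics. `filter_dataset()` removes contaminant lineages (case-insensitive
substring match over the concatenated lineage; defaults `mitochondria`,
`chloroplast`), optionally OTUs unassigned at every rank, and then drops
samples whose library size is not strictly greater than `min_reads`
(default 5,000 reads). Contaminants are removed *before* the library-size
threshold so that filtering is idempotent and every retained sample's
cleaned library size clears the threshold. "Unassigned" defaults to
*unassigned at all ranks*; a single missing rank is common in reference
taxonomies and is not treated as evidence of artefact.

`tss_clr()` shifts counts by a pseudocount (default 0.5, the half-count
convention; the data give no basis for a different zero model), scales each
sample to proportions, and returns log-proportions centred per sample, so
each sample's transformed values sum to zero.

## Diversity, distances, ordination

Alpha diversity (Shannon entropy in nats; bias-corrected Chao1,
`S_obs + F1(F1−1)/(2(F2+1))`) is computed on counts rarefied without
replacement to the minimum library size, because richness estimators are
depth-sensitive. Beta diversity is computed on unrarefied counts:
Bray–Curtis is ratio-based and unweighted UniFrac presence-based, so
rarefaction mainly adds noise there; both choices are switchable because
practice differs between studies.

`pcoa()` performs classical metric scaling (double-centred −D²/2,
eigendecomposition). Negative eigenvalues — expected for non-Euclidean
dissimilarities like Bray–Curtis — are reported but excluded from the
variance-explained denominator, and no Cailliez/Lingoes correction is
applied by default: the corrections change axis scaling without changing
the picture, and reporting the convention used is the more transparent
choice. The degenerate all-zero distance matrix yields a single null axis.

### PERMANOVA and stepwise db-RDA

`permanova()` implements the Gower-centred partitioning of squared
distances with sequential (type-I) sums of squares, pseudo-F per term, and
free permutation of sample labels; p = (1 + #{F* ≥ F}) / (1 + n_perm), so
p can never be zero and respects the 1/(n_perm+1) lower bound. Sequential
partitioning matches the forward-selection workflow the package supports;
for n ≤ 8 an exhaustive mode enumerates all n! permutations and returns
the exact p. The implementation is cross-checked in the test suite against
`vegan::adonis2` (sums of squares and pseudo-F agree to 1e-10) and against
a brute-force enumeration oracle.

`stepwise_dbrda()` runs forward selection on conditional (added-last)
permutation tests: at each step the candidate with the smallest p enters if
p ≤ `alpha_enter` (0.05), then a backward pass drops any term whose
conditional p exceeds `alpha_drop` (0.10). The conditional tests reuse the
same distance partitioning directly rather than regressing on retained
principal-coordinate axes; on the positive-inertia part of the distance
matrix the two formulations coincide, and the direct form avoids an
arbitrary axis-retention cutoff. Permutation seeds are derived per
step-and-candidate from the caller's seed, so the trace is reproducible.

`distance_regression()` regresses a second distance matrix (for example, a
functional dissimilarity) on the taxonomic one over unique sample pairs;
the slope is a resilience proxy (a flat slope means the secondary distance
does not respond to taxonomic turnover). Pairs are not independent, so the
standard errors are descriptive only, and the tests treat them that way.

## Phylogenetic null models

`beta_mntd()` computes the between-sample mean nearest taxon distance:
for each taxon in one sample, the patristic distance to the nearest taxon
present in the other, averaged with relative-abundance weights (the
Stegen-style convention; an unweighted switch divides by richness instead).
A taxon present in both samples contributes zero. `beta_nti()` z-scores the
observed βMNTD against `n_null` (default 999) tip-label shuffles of the
patristic distance matrix; richness and abundances are preserved exactly,
only phylogenetic positions are randomised. The sign convention is the
standard z-score: βNTI < 0 means communities are phylogenetically *more*
similar than chance (clustering; below −2, homogeneous selection), βNTI > 0
overdispersion. Narrative descriptions that call co-occurrence of close
relatives "positive βNTI" map onto this convention with the sign flipped;
the package keeps the standard convention and documents the mapping rather
than silently flipping signs. Pairs whose null distribution has zero
standard deviation (e.g. all taxa shared) are set to NaN with a warning.
The nearest-taxon kernel is in C++; 999 nulls at 500 taxa × 30 samples run
in seconds.

## The Sloan neutral model

With community size N (the mean library size) and migration parameter m,
the local relative abundance of a taxon with metacommunity relative
abundance p is Beta(Nmp, Nm(1−p)). Predicted occupancy follows from a
detection model, and here the package makes a deliberate choice between
two conventions:

* `occupancy_model = "threshold"` — the classic form: the probability the
  latent relative abundance exceeds the detection limit 1/N,
  `1 − BetaCDF(1/N; Nmp, Nm(1−p))`.
* `occupancy_model = "sampling"` (default) — the probability at least one
  of N multinomially sampled reads hits the taxon,
  `1 − E[(1−q)^N] = 1 − B(a, b+N)/B(a, b)` with a = Nmp, b = Nm(1−p).

When counts really are reads drawn at finite depth — which is both how
sequencing works and how the package's generator samples — detection is a
smooth function of abundance, not a hard threshold, and the sampling form
recovers the generating migration parameter without the upward bias the
threshold form incurs for rare taxa. The threshold form is retained for
comparability with the widespread implementation of this fit.

m̂ minimises the occupancy SSE by bounded one-dimensional optimisation on
(10⁻⁶, 1); an estimate at either bound triggers a warning. The partition
band around predicted occupancy is, by default, the exact binomial
prediction interval (quantiles of Binomial(n_samples, predicted)); the
Wilson score interval is available for comparability. The exact band
respects the discreteness of occupancy: a taxon observed in every sample is
*not* flagged "above" when the model itself makes full occupancy likely —
a failure mode of the Wilson form, which treats the predicted proportion as
if it were an observed one and has upper bound < 1 whenever the prediction
is below 1. On neutrally simulated data the default combination labels
roughly 95% of taxa neutral at the 95% level and recovers m within a few
percent; the acceptance suite recomputes both properties.

## Core microbiome

`occupancy_index()` ranks taxa by
`Index = (mean group occupancy + mean all-replicate presence) / 2`, where
groups ("sites") are typically farms or amendment levels. Both terms lie in
[0, 1], so the index does too; ties break by total abundance, then OTU id.
Detection is count > 0 (no minimum-count threshold; configurable upstream
by zeroing low counts).

`bc_contribution_curve()` decomposes mean pairwise Bray–Curtis: per pair,
the numerator restricted to the top-k ranked taxa over the *full-table*
denominator, so the explanatory value `E(k) = BC_core(k)/BC_all` grows
monotonically from 0 to 1 as taxa are added. The complementary printed
form `C = 1 − BC_core/BC_all` is reported alongside; note that C
*decreases* as taxa are added, so the "explanatory value increases by less
than 2%" stopping rule is applied to E — the quantity that actually
increases — with "2%" read as an absolute increment of 0.02 on the [0, 1]
scale. `select_core()` stops at the smallest k whose next increment falls
below `delta`; at least one taxon is always selected. On a table where a
known subset carries essentially all between-sample variation, the rule
recovers exactly that subset (an acceptance check).

`occupancy_models()` repeats ranking, curve, and selection within each
level of a grouping variable (default `amendment`) and on all samples
pooled, reporting each core's minimum within-level occupancy;
`core_overlap()` restricts cores to fully prevalent members (occupancy ≥ 1
by default) and emits Venn counts plus Jaccard sharing percentages;
`neutral_overlay()` attaches the Sloan partition labels to the core.

## GLLVM

The association model is a per-taxon log-linear count regression with
shared latent factors: `η_ij = β0_j + x_i'β_j + u_i'θ_j`, family negative
binomial (default; amplicon counts are overdispersed) or Poisson, d = 2
latent variables by default (enough to absorb the dominant unmeasured
covariation without starving the fixed effects; configurable). Optional
per-sample intercepts are off by default. Estimation maximises the
penalised joint log-likelihood `Σ log f(y_ij; η_ij) − ½Σ‖u_i‖²` by
alternating Fisher scoring over per-taxon parameters, profile updates of
the NB size parameter, and penalised Newton steps for the scores.

Three algorithmic details matter and were each adopted after observing the
failure mode they prevent:

1. **Design orthogonalisation.** Each iteration the scores are
   orthogonalised against [1, X] with an exact compensation added to
   (β0, β). The likelihood is invariant to this shift and the penalty can
   only decrease, so it is a strict improvement — and it removes the ridge
   along which latent factors absorb covariate effects, which otherwise
   corrupts coefficients under alternating updates.
2. **Scale normalisation.** The likelihood depends on the scores and
   loadings only through their product, and the penalty acts on the scores
   alone, so the unconstrained optimum drifts toward zero scores and
   unbounded loadings. Each latent dimension's scores are normalised to
   unit variance (the standard-normal score convention), pinning the
   scale split.
3. **Latent-aware standard errors.** Conditioning on the estimated scores
   as if they were observed covariates underestimates coefficient
   variance when the latent terms carry real variation: the true scores'
   random alignment with the design is projected out during estimation
   and its effect lands in the coefficients. The default standard errors
   add the analytic term `‖θ_j‖² diag((W'W)⁻¹)` for that contribution.
   With this correction, null-taxon z-scores are approximately standard
   normal in simulation, and the false-exclusion rate of the 95% CIs sits
   near nominal (the acceptance suite checks ≤ 10%).

Identifiability of the latent rotation is fixed post hoc by an orthogonal
rotation making the leading d × d loading block lower triangular with a
positive diagonal. With d = 0 the model collapses exactly to independent
per-taxon GLMs, which provides the oracle check against `glm()` /
`MASS::glm.nb`. Taxa with more than 95% zeros are excluded with a warning
— their coefficients are not estimable at reasonable precision.
Directionality labels (`positive` / `negative` / `none`) come from 95%
Wald intervals not crossing zero.

## CODA-LASSO

`fit_coda_lasso()` regresses a continuous response (squared error) or a
binary group (logistic deviance) on Z = log(TSS proportions + pseudocount
equivalent), under the compositional zero-sum constraint Σβ = 0 with an
elastic-net penalty. The count-scale pseudocount (module default 0.5) is
converted to the proportion scale by dividing by the mean training library
size and is stored in the fit, so predictions are exactly invariant to
per-sample rescaling of new counts.

The solver is pairwise coordinate descent: every update moves a pair
(β_j + δ, β_k − δ), preserving the constraint identically at every step
while keeping lasso zeros exact; the one-dimensional subproblem is
piecewise quadratic with kinks at −β_j and β_k and is solved in closed
form. (A projection of the full coefficient vector onto the zero-sum
hyperplane after soft-thresholding — the obvious alternative — moves every
zero off zero and does not converge to the constrained optimum.) Solutions
satisfy the constrained elastic-net KKT conditions to ~1e-8, which the
test suite verifies directly. The penalty is chosen at the minimum mean
k-fold cross-validation error over a geometric grid (50 values, floor
`lambda_min_ratio` of the data-driven maximum); fold assignment is seeded.

A scope note on the recovery test: minimum-CV lasso is prediction-optimal,
not selection-consistent — at moderate noise it reliably *contains* the
planted signature but includes additional small coefficients, and in purely
compositional designs the closure correlations can remove the exact-support
window from the entire path. The recovery study therefore runs in a
high signal-to-noise regime (independent per-taxon lognormal variation,
noise two orders of magnitude below the signal, grid floor 10⁻²), where
exact support recovery at the CV optimum is information-theoretically
clean. Passing it certifies the solver, path, and CV machinery — not that
CV-min lasso performs exact selection on noisy field data, which no lasso
variant does.

## The synthetic-data generator

`simulate_dataset()` composes: a pure-birth (Yule) topology with
independent exponential branch lengths; lognormal metacommunity relative
abundances (log-sd 1.5, a typical amplicon rank-abundance slope); a survey
design of 116 samples across 14 farms, amendment frequencies
None 0.55 / FYM 0.38 / Digestate 0.035 / Slurry 0.035 (the rare groups
land near n = 4, reproducing the power caveats such imbalance causes),
four soil textures, and library sizes uniform on [5079, 41827] reads;
deterministic environmental filtering in which a phylogenetically compact
clade of taxa (chosen as the clade with the smallest mean within-clade
patristic distance near the requested size) responds multiplicatively to
standardized Ca and LOI; and Sloan-type neutral sampling — per sample,
local proportions drawn Dirichlet(N·m·p), so each taxon's marginal is the
Sloan Beta(Nmp, Nm(1−p)), then counts multinomial at depth N. Soil
chemistry is drawn normal with group-specific means (higher Ca in silty
clay loam, higher LOI under digestate and slurry) to mirror the
qualitative field patterns; the magnitudes are generator conventions, not
measured values. Everything is reproducible from (config, seed), with
per-stage seeds fanned out deterministically so one stage's draws cannot
silently shift another's.

What the generator does **not** emulate: sequencing-read error and
chimeras, spatial autocorrelation within fields, taxon–taxon interactions,
and real taxonomies (lineages are synthetic labels). Tests passing on this
generator therefore certify the estimators under their stated assumptions
— not performance under artefacts the generator omits.

## Problem sizes and runtime conventions

The packaged studies use deliberately moderate sizes chosen so the whole
suite re-runs comfortably on a laptop core: 300 taxa × 116 samples for the
default survey; 500 taxa × 50 samples at depth 10,000 for Sloan recovery;
30 samples × 200 taxa × 199 permutations × 200 replicates for PERMANOVA
size calibration; 999 nulls for βNTI; 30 taxa × 100 samples for GLLVM and
CODA-LASSO recovery. The statistical conclusions these support scale with
the usual √n caveats, and the acceptance script recomputes all of them
from scratch at run time.

## Known limitations

* The GLLVM uses a penalised-joint (Laplace-type) objective, not the full
  marginal likelihood; dispersion and loadings for very sparse taxa are
  rough, which is why >95%-zero taxa are excluded.
* PERMANOVA uses free permutation; restricted permutation schemes for
  nested designs (samples within farms) are not implemented — farm can be
  included as a term instead.
* βNTI supports only the tip-shuffle (taxa-label) null; full ecological
  process partitioning (e.g. Raup–Crick on Bray–Curtis) is out of scope.
* The stepwise db-RDA p-values are conditional permutation tests computed
  greedily; as with all stepwise selection, they are not simultaneous
  inference.
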