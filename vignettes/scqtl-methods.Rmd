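---
title: "Statistical methods behind scqtl"
author: "scqtl maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods behind scqtl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`scqtl` implements the statistical chain of a cell-type-resolved single-cell
eQTL study: per-cell-type pseudo-bulk aggregation, cis-eQTL mapping with
permutation-based eGene calling, empirical-Bayes harmonization of allelic
effects across cell types, functional annotation of eQTL SNPs,
cell-state-interacting (dynamic) eQTL modelling along a pseudotime
trajectory, and GWAS integration by colocalization and TWAS. A synthetic
cohort generator with ground-truth effect records drives calibration and
parameter-recovery testing.

This vignette explains the models, the tunable parameters, the numerical
choices, and what the synthetic data do — and do not — establish about real
data. Nothing here states an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

# The synthetic cohort generator

`sim_config()` / `simulate_cohort()` emulate a cohort of roughly 129 donors
(a typical single-tissue single-cell eQTL study size) with a configurable
number of cell types, each donor contributing a negative-binomially
distributed number of cells per cell type.

**Genotypes.** Per-variant minor allele frequencies are drawn uniformly from
`maf_range` (default 0.05–0.5). Two haplotypes per donor are drawn from a
latent Gaussian with compound-symmetric correlation `ld_rho` within LD
blocks of `ld_block_size` variants and thresholded at the allele frequency.
This gives exact Hardy–Weinberg genotype frequencies per variant (the two
haplotypes are independent) with tunable within-block dosage r² — a simple
block-LD model chosen because the exact LD structure is not critical to any
downstream operation, only its presence.

**Counts.** For gene $g$, cell $c$ of donor $d$ in cell type $k$:

$$y_{gc} \sim \mathrm{NB}\!\left(\mu_{gc},\ \theta = 1/\phi\right), \qquad
\log \mu_{gc} = \log s_c + b_g + \beta_{gk} x_{dg}
  + \gamma_g \tilde q_c x_{dg} + u_{gd}$$

with $s_c$ a log-normal cell size factor, $b_g$ a log-uniform baseline
expression rate, $x_{dg}$ the dosage of the gene's causal variant (the
variant nearest its TSS), $\tilde q_c$ the centered pseudotime quantile bin
of the cell, $u_{gd} \sim N(0, \texttt{donor\_sd}^2)$ a per-gene donor
random intercept, and $\phi$ = `nb_dispersion` (variance
$\mu + \phi\mu^2$). Recorded `n_umi` is the realized column sum, so library
size behaves like real data (it includes the gene's own counts).

**Effects.** The `effect_grid` assigns each gene one sharing pattern:
`null`, `global` (all cell types), `category` (all cell types of one of the
four lung cell categories), `specific` (one cell type), or `dynamic`
(global effect whose magnitude drifts by `slope` per pseudotime quantile).
Published single-cell eQTL effect-size distributions are not well
characterized, so the default sizes (0.5 on the log scale for cis effects,
0.25 + 0.15 per quantile for dynamic ones) are chosen for test power, not
realism — they
make a 120-donor cohort well-powered so that recovery failures indicate
implementation defects rather than sampling noise.

**Pseudotime** is uniform on [0, 30] by default (matching the scale of an
alveolar AT2 → transitional → AT1 trajectory), with a `bimodal` option for
cells piling up at trajectory termini, and a small configurable fraction of
cells assigned infinite pseudotime to exercise the removal rule.

What the generator does **not** emulate: ambient RNA, doublets, read-level
noise, imputation error beyond fractional dosages, cell-type
misclassification, and latent batch structure. Passing tests therefore show
that the estimators are correct and calibrated under their assumed models,
not that those models capture every artefact of real tissue data.

# Pseudo-bulk construction

Cell types qualify when ≥ 40 donors contribute ≥ 5 cells each; genes are
kept when expressed in ≥ 10% of all cells (both thresholds inclusive and
configurable). Counts are summed per (cell type, donor) and normalized in
two steps: per-donor library scaling (counts / total × 10⁴, `log1p`), then
a per-gene rank-based inverse-normal transform across donors with offset
$(r - 0.5)/n$ and average ranks for ties. The inverse-normal choice (over
across-sample distribution matching, the other reading of "quantile
normalization") makes the linear model's null exact and is the standard
phenotype transform in eQTL practice.

Covariates are donor age, genotype PCs computed on LD-pruned standardized
dosages (default 3), and expression factors — the top PCs of the normalized
pseudo-bulk matrix, the accepted stand-in for latent-factor methods such as
PEER. `optimize_factor_count()` picks, per cell type, the smallest factor
count whose eGene discovery is within 2% of the grid maximum.

# cis-eQTL mapping

`map_nominal()` regresses the transformed phenotype on alternative-allele
dosage with covariates for every variant within ±1 Mb of the TSS (boundary
inclusive; TSS is the strand-aware single-position anchor). Phenotype and
dosages are residualized against the covariates once, after which
per-variant OLS is exact (Frisch–Waugh); two-sided p-values use
$df = n - (\text{covariates} + 2)$. Variants need in-sample MAF > 0.05 and
imputation R² > 0.3; monomorphic variants are skipped.

`map_permutation()` permutes the covariate-residualized phenotype (default
1,000 times), records the minimum cis p-value per permutation, fits a
Beta(α, β) distribution to the minima by maximum likelihood
(method-of-moments start, box-constrained quasi-Newton), and reports
`p_beta_adjusted` = CDF of the top nominal p. One numerical point deserves
emphasis: after permuting the residual vector entrywise, the permuted
vector is **re-projected onto the covariate-orthogonal subspace**. Without
this step permuted correlations are deflated by roughly $(n-k-1)/n$
relative to the observed statistic, which inflates the far tail of the
adjusted p — enough to produce spurious eGenes on a fully null cohort. The
alternative `permute = "phenotype"` mode permutes raw phenotypes and
re-residualizes each round. The degrees-of-freedom recalibration some
mappers apply to the nominal p ("effective df") is deliberately not
implemented; the re-projection above addresses the same failure mode within
the residual-permutation scheme.

eGenes are called with Storey q-values on the adjusted p-values, with
$\hat\pi_0 = \min\!\big(1, \overline{\{p > 0.5\}}/0.5\big)$ — a single-λ
estimator that is robust at the few-hundred-to-few-thousand-gene scale of
the fixtures; below 20 genes it falls back to $\pi_0 = 1$
(Benjamini–Hochberg-equivalent). Top-variant ties break by lowest p, then
largest |t|, then lexicographic variant id.

`map_nb()` is the count-based alternative mapper: per (gene, variant) a
negative-binomial GLM with log link on raw pseudo-bulk counts, log library
size offset, ML dispersion, and a Wald test on dosage; non-converging fits
fall back to Poisson and are flagged.

# Cross-cell-type effect sharing

`fit_eb_model()` is a self-contained empirical-Bayes multi-condition
shrinkage model in the spirit of multivariate adaptive shrinkage. It is
parameterized on z-scores (the "EZ" convention): $\hat z_r \sim
N(z_r, V)$ with a common residual correlation $V$ across rows, and a prior
on true z-effects that is a mixture of zero-mean multivariate normals. The
components are canonical patterns — exact null, identity, per-cell-type
singletons, rank-1 equal effects — plus data-driven patterns (top principal
components of the strong-set z-scores and their rank-limited
reconstruction, eigenvalue-clipped to PSD), each expanded over a geometric
scale grid of length 20 spanning 0.1 to twice the largest observed |z|.
Working in z units makes the per-component likelihood identical across rows
(one Cholesky per component per missingness pattern), which is what makes
the EM affordable in pure R; posterior means and SDs are mapped back to the
effect-size scale through the standard errors. No
extreme-deconvolution refinement of the data-driven matrices is applied:
the mixture over scaled patterns gives the same posterior machinery at
bounded complexity.

$V$ is the correlation of z-scores over near-null random rows (all |z| <
2), shrunk 5% toward the identity and eigenvalue-floored. Mixture weights
are fitted by EM on the random subset; because component likelihoods are
fixed, each iteration is a closed-form weight update and the marginal
log-likelihood is non-decreasing by construction (asserted at run time).

The local false sign rate for entry $(r, k)$ is
$\min\{P(\beta \le 0 \mid \text{data}), P(\beta \ge 0 \mid \text{data})\}$,
with posterior mass on exactly-zero components counting toward both signs.
Untested entries are handled by conditioning the posterior on the observed
coordinates only.

Sharing classification (lfsr < 0.05): significant in one cell type →
cell-type-specific; in ≥ 2 cell types of one category → category-shared;
spanning ≥ 2 categories → cross-category-shared. Pairwise sharing between
cell types A and B is the fraction of jointly significant rows with equal
sign and B/A fold change in [0.5, 2] (boundaries inclusive; a zero
posterior mean fails the rule; no jointly significant rows yields NA).

# Functional annotation

`ld_prune()` follows the plink `--indep-pairwise 250 50 0.9` scheme: a
250-variant window stepping by 50; within a window, while any retained pair
exceeds r² = 0.9, the lower-MAF member is removed (ties: later position).
The exact member-selection rule of plink is not public; the lower-MAF rule
is a documented choice that affects set membership, not the downstream
statistics materially.

Enrichment of (pruned) eQTL SNPs against annotation labels uses two-sided
Fisher exact tests per label with BH FDR across labels, with pruned
non-eQTL SNPs as background. Zero cells report the unconditional odds ratio
(0 or ∞) rather than a Haldane correction — the exact p-value is unaffected
and the direction label stays interpretable. Interval queries are 0-based
half-open (a 1-based SNP position $p$ is inside $[s, e)$ iff
$s \le p-1 < e$), implemented on GenomicRanges.

TSS-distance comparisons between shared and cell-type-specific eQTL SNPs
use a one-sided Mann–Whitney U test on |distance| (shared closer); no
single test is canonical for this density comparison in the field, so the
test choice is a design decision of this package. ATAC-peak overlap assigns each SNP
to at most one peak group with precedence cell-type-specific >
multi-category > other and tests the class × group table with Pearson's
chi-square (no continuity correction), warning when an expected count
drops below 1.

# Dynamic (cell-state-interacting) eQTLs

Cells on the trajectory are ranked by pseudotime and split into Q = 6
equal-count bins (±1; ties broken by stable cell order; infinite
pseudotime excluded), making the assignment invariant to monotone
transformations of pseudotime. The ordinal bin index, centered, enters the
model as a continuous covariate; centering decorrelates the main and
interaction terms without changing the interaction estimate.

`fit_interaction()` models per-cell UMI counts as

$$y_{c} \sim \mathrm{NB}(\mu_c, \theta), \qquad
\log \mu_c = \beta_0 + \beta_g x + \beta_t \tilde q_c
 + \beta_{int}\, x \tilde q_c + \text{covariates} + \log(\mathrm{nUMI}_c)
 + u_{d(c)}$$

with a Gaussian donor random intercept, and Wald-tests $\beta_{int}$. The
marginal likelihood integrates the one-dimensional random effect per donor:
the per-donor modes come from a concave Newton iteration vectorized across
donors, and the default integration is a Laplace approximation whose
gradient is computed analytically (envelope identity at the mode plus the
total derivative of the log-curvature term). Adaptive Gauss–Hermite
quadrature with 9 nodes (`re_mode = "aghq"`) is available as a refinement,
and a donor-fixed-effects NB GLM (`re_mode = "fixed"`) is retained as a
slow reference oracle. The fit is authored in-package rather than delegated
to a general mixed-model engine because per-fit overhead dominates at the
scale of hundreds of genes; unit tests verify estimates, standard errors,
variance components and log-likelihoods against glmmTMB to three-plus
decimals. Wald SEs are observed-information (curvature); when the donor
variance collapses (σ < 0.01) the near-flat log-σ direction is dropped from
the curvature so the fit degenerates cleanly to the fixed-effect GLM.

Per-quantile allelic effects refit the model (no interaction term) within
each quantile's cells — retaining the donor random effect, which is our
resolution of the ambiguity in "adjusting for the same covariates" —
requiring ≥ 50 cells and dosage variation per quantile. Trend
classification runs weighted least squares (weights 1/se²) of the
per-quantile effects on the quantile index: `linear` if only the slope is
significant at 0.05, `quadratic` if only the curvature, `both`, or `none`.
Interaction p-values are BH-corrected. Regulon-activity trends use the
same linear/quadratic machinery on per-cell activity scores. Global
expression PCs (not per-quantile) enter as covariates when supplied.

# GWAS integration

**Colocalization.** Loci are the variants within ±100 kb (inclusive) of
each GWAS lead SNP that appear in both the GWAS and eQTL statistics; loci
with no shared variant are dropped. Per variant and trait the Wakefield log
approximate Bayes factor is
$\tfrac12\log\frac{V}{V+W} + \tfrac{z^2}{2}\frac{W}{V+W}$ with $V = se^2$;
the prior effect variance is $W = (0.15\,\mathrm{sd}_Y)^2$ for quantitative
traits — with $\mathrm{sd}_Y$ estimated from the regression identity
$\mathrm{var}(\hat\beta_j) \approx \mathrm{sd}_Y^2 / (2 n\, f_j(1-f_j))$
when not supplied — and $W = 0.2^2$ on the log-odds scale for case-control
traits, matching the conventional defaults. Hypothesis sums are in log
space (log-sum-exp; the two-distinct-variants sum uses the complement
identity), with priors p1 = p2 = 10⁻⁴, p12 = 10⁻⁵; the five posterior
probabilities sum to 1 and PP.H4 is invariant to trait order. Multi-causal
fine-mapping is out of scope.

**TWAS.** `train_weights()` fits four weight models on standardized cis
dosages against the covariate-residualized phenotype: top SNP, ridge (a
BLUP surrogate; exact REML-BLUP equivalence is not claimed), lasso, and
elastic-net (α = 0.5). Each penalized model's λ is tuned once on the full
data and held fixed across cross-validation folds and permutations — the
fixed-λ scheme keeps the per-gene cost linear and is the standard
compromise in weight-training pipelines. The best model by k-fold
cross-validated R² is selected; the gene is retained when a permutation
test of that R² (refitting on permuted phenotypes; default 30 permutations)
gives p < 0.05 — our stand-in for a REML cis-heritability filter, which is
unstable at ~129 donors — and the correlation test of out-of-fold
predictions is also significant. Association uses
$z_{\mathrm{TWAS}} = w^\top z / \sqrt{w^\top R w}$ with the in-sample LD
correlation matrix regularized as $(1-\epsilon)R + \epsilon I$,
$\epsilon = 0.01$, and BH FDR across genes within cell type.

# Numerical choices and degenerate inputs

* Beta-distribution fits clip permutation minima to [10⁻¹², 1−10⁻¹²];
  fewer than 100 permutations are refused as unstable.
* EM stops on relative log-likelihood change < 10⁻⁸ or 500 iterations; a
  likelihood decrease beyond tolerance raises an error rather than
  continuing silently.
* Non-PSD covariance patterns are eigenvalue-clipped; Cholesky failures
  retry on the clipped matrix.
* Donors with zero pseudo-bulk totals, all-zero genes, monomorphic
  variants, quantiles without alternative-allele carriers, and loci without
  finite statistics are each dropped with an explicit message, never
  silently.
* All simulation stages derive child seeds deterministically from a single
  top-level seed, so every cohort is bit-reproducible.

# Problem sizes used in validation

The shipped validation suite runs on cohorts of 80–120 donors, 100–500
genes, 1–3 cell types and a few hundred variants, with 300–10,000
permutations depending on what the check needs; the dynamic-eQTL
calibration uses 20 replicates of 400 null genes plus 200 power replicates,
and TWAS calibration uses 500 trained genes. These sizes make every
distributional claim in the tests a property of hundreds-to-thousands of
draws rather than anecdote, while keeping the whole suite runnable on a
single CPU in well under half an hour.

# Known limitations

* The pseudo-bulk mapper assumes donors are pre-matched between genotype
  and expression data; no sample-swap detection is performed.
* The EB sharing model fixes data-driven covariances at their PCA
  estimates rather than refining them by extreme deconvolution; with very
  few strong rows the data-driven patterns can be noisy (the canonical
  patterns then dominate).
* The Laplace approximation can misestimate variance components for genes
  with very few cells per donor; `re_mode = "aghq"` is the accurate
  fallback.
* Trans-eQTLs, conditional/independent cis signals, multi-causal
  colocalization and pseudotime inference itself are out of scope.
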