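---
title: "Sparse tensor components and trans-eQTL mapping: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse tensor components and trans-eQTL mapping: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(factorqtl)
```

## The problem

Trans-acting genetic effects on gene expression are individually tiny and
scattered across thousands of genes, so SNP-by-gene trans-eQTL scans pay an
enormous multiple-testing price. `factorqtl` takes the component-based
route: multi-condition expression data are decomposed into latent components
— gene networks with per-individual magnitudes — and the *individual scores*
of each component become the phenotype for a genome-wide association scan.
A single association test per component replaces thousands of per-gene
tests, and the component's gene loadings name the trans-regulated network.

## The decomposition model

The data form a three-way array `Y[n, l, t]` over individuals, genes and
conditions (stimulation states, cell types or tissues), with

$$ Y_{nlt} = \sum_{c=1}^{C} A_{nc}\, B_{tc}\, X_{cl} + \varepsilon_{nlt},
\qquad \varepsilon_{nlt} \sim \mathcal N(0,\ \lambda_{lt}^{-1}), $$

where `A` (N x C) holds individual scores, `B` (T x C) condition activity
scores, and `X` (C x L) gene loadings. Precisions are per gene and
condition. An indicator `I[n, t]` marks whether individual `n` was measured
in condition `t`; unobserved slices contribute to nothing (the likelihood is
raised to the power `I[n, t]`).

Gene loadings carry a spike-and-slab prior: `X[c, l] = s[c, l] w[c, l]`
with `s ~ Bernoulli(pi_c)`, `w ~ N(0, 1/beta_c)`, `pi_c ~ Beta(1, 1)`, and
`beta_c ~ Gamma(1e-3, 1e-3)`. The posterior probability of `s[c, l] = 1` is
the gene's **posterior inclusion probability** (PIP). One inclusion rate and
one slab precision per component is the implemented hierarchy; the
individual and condition scores have fixed-variance Gaussian priors
(`a_prior_scale`, `b_prior_scale`, both 1 by default) and the noise
precisions a vague Gamma prior.

### Inference

Fitting is mean-field variational Bayes with coordinate ascent
(`fit_sda()`). The factorization is
`q(A) q(B) q(s, w) q(lambda) q(pi) q(beta)`, with `q(w | s = 0)` tied to the
prior at the current `E[beta]` so spike terms cancel in the evidence lower
bound (ELBO). One sweep updates, in fixed order: `lambda`, the spike/slab of
`X` component-by-component, `A`, `B`, then the inclusion rates and slab
precisions. Every update is an exact coordinate maximizer, so the ELBO is
non-decreasing across sweeps (asserted to within `1e-8 * |ELBO|`, and
checked on every fit via the `monotone` flag); fitting stops when the
relative ELBO change falls below `tol` (default `1e-6`) or at `max_iter`.

### Initialization and warm-up — why they matter

Coordinate ascent in this model has an absorbing all-zero fixed point: once
a component's scores decay toward zero, its posterior variances revert to
the prior, inflate every ridge denominator it appears in, and the component
can never regrow. Two measures keep real components alive, and both were
adopted after observing the failure, not hypothetically:

* **Data-scaled initialization.** The default `init = "svd"` seeds the
  individual scores and slab means from a truncated SVD of the
  condition-averaged matrix. With a random cold start
  (`init = "random"`), components active in a single condition are
  frequently lost — on the standard benchmark the mean matched loading
  correlation drops from 0.999 to roughly 0.7.
* **Spike warm-up.** For the first `warmup` sweeps (default 10) the
  inclusion probabilities stay frozen near 1 and the inclusion rates at
  their prior, so the model behaves as a dense Bayesian tensor
  factorization while components align with signal; activating the spike
  from a cold start extinguishes everything. Skipping a coordinate update
  never decreases the ELBO, so monotonicity is preserved, and convergence
  is not declared before the spike phase has run.

Numerical floors: precisions are clipped to `[1e-8, 1e8]` and Bernoulli
posteriors to `[1e-10, 1 - 1e-10]`. A component whose loadings collapse
entirely into the spike is flagged `pruned`; its inclusion indicators no
longer touch the likelihood (their variational posterior freezes at an
arbitrary value), so the PIPs of an identically zero loading row are
reported at the numerical floor. This is a reporting convention for a
posterior that is genuinely degenerate, and it is what makes surplus
components (when `C` exceeds the true rank) show near-zero PIP.

Scale and sign of each component are not identified; `orient_and_scale()`
normalizes loading rows to unit L2 norm (absorbing the scale into `A`) and
makes the largest loading positive, without changing the reconstruction.
Downstream association tests are invariant to this choice, but fitted
`beta` values for component scores are interpretable only up to it.

## Calling sparse components

Confounders (batch, technical artifacts) appear as components with many
small loadings; real regulatory networks concentrate weight on few genes.
Genes are assigned to a component when **both** `PIP > pip_threshold`
(default 0.5) **and** the loading lies beyond the component's two-sided
empirical tail quantiles (`tail_fraction = 0.025`, i.e. the 2.5% / 97.5%
cut). Intersection was chosen over union because either rule alone admits
bulk genes: the PIP rule keeps dense-component genes whose inclusion is
certain but weight is trivial, and the quantile rule always passes 5% of
genes by construction. Loosening either rule (lower PIP threshold, wider
tail fraction) can only add genes.

Each component `i` is then scored by the sparsity ranking statistic

$$ R_i = \mathbf 1\{\text{min\_genes} \le N_i \le T_{\max}\} \cdot
   \frac{f(w_i)}{g(N_i)}, $$

with `N_i` the selected-gene count, `w_i` the mean absolute loading of the
selected genes, and defaults `f(w) = w`, `g(N) = N` (both injectable).
`T_max` defaults to 5% of the gene count — sparse networks of interest hold
tens of genes out of thousands — and `min_genes` to 5. The sparse/dense
cutoff is a limiting-case lower bound rather than a distributional
assumption: the `R` of a hypothetical component holding `min_genes` genes
exactly at the component's own tail-quantile magnitude (the selection
threshold itself), the smallest configuration that could still qualify. A
genuinely sparse component concentrates weight far beyond its bulk
threshold and clears this bound by orders of magnitude; a dense component's
selected genes sit *at* the threshold, so its statistic falls below the
bound by roughly `min_genes / N_i`. On the standard benchmark (4 sparse + 2
dense planted components) this classifies all components correctly across
20 seeds.

Before association testing, components correlated with known covariates are
discarded (`screen_covariates()`): OLS slope t-tests for continuous
covariates, one-way ANOVA F-tests for categorical ones, Bonferroni-corrected
across components x covariates. Components replicated across datasets can
be identified by two-way reverse correlation of absolute loadings on shared
genes (`match_components()`), reporting reciprocal best hits.

## Trans-eQTL mapping

`map_component_trans_eqtl()` regresses each component's individual scores
on each SNP's allele dosage (additive coding, intercept included) and
applies Benjamini-Hochberg correction **jointly across all SNP x component
tests** — a genome-wide correction, deliberately stricter than correcting
within components. Significance is reported at FDR 0.05, with a more
liberal 0.15 reserved for overlap with trait-associated loci
(`overlap_gwas()`, catalog pre-filtered to p < 5e-8 and LD-pruned).

SNPs enter the scan after QC (`filter_snps()`): MAF > 0.05 and
Hardy-Weinberg chi-square p > 0.001 at the association stage; the
imputation-stage filter (MAF >= 0.01, INFO >= 0.3, HWE p > 1e-6) is the
same function under a different parameterization. The HWE test is the
1-df goodness-of-fit chi-square on hard-called genotype counts;
monomorphic sites return p = 1 by convention.

The permutation null (`permutation_pvalues()`) permutes individuals' score
rows against the genotypes and recomputes all association p-values each
round. Null p-values are pooled per component across SNPs — the pragmatic
reading of comparing nominal p-values against an empirical distribution —
giving `perm_p = (1 + #\{null p <= observed\}) / (1 + pool size)`. With
pooling, the attainable floor is below `1/(n_perm + 1)`; a per-SNP mode
(`pool = "snp"`) is available where the classical floor applies exactly.

Cis mapping (`map_cis_eqtl()`) tests SNPs within 1 Mb either side of a
gene's transcription start or end site, boundaries inclusive on 1-based
coordinates (the VCF convention). Expression is first residualized against
its leading latent factors — a truncated SVD of the gene-centered matrix,
15 factors by default — standing in the role hidden-factor models play in
cohort pipelines. This correction is computed from the expression matrix
itself and can absorb genuine broad signal; for cis effects, which are
local and sparse, the planted-effect tests show the bias is negligible.

## Mendelian-randomization mediation

Does a trans-eSNP act on its network through a nearby cis gene?
`mr_mediation()` implements single-instrument two-stage least squares: the
SNP instruments the cis gene (stage 1), and the outcome — component scores
(`mediate_component()`) or a trans-gene's expression (`mediate_genes()`) —
is regressed on the instrumented cis expression (stage 2). The mediated
effect `beta_M` equals the ratio `cov(outcome, g) / cov(cis, g)`; the
standard error uses the 2SLS residuals (observed cis expression, not fitted
values). First-stage F below 10 flags a weak instrument; flagged results
are reported, never suppressed.

The estimator's assumptions are not hidden: a direct (pleiotropic) SNP
effect `delta` on the outcome shifts `beta_M` by `delta / alpha`, and the
synthetic generator can plant exactly this violation
(`simulate_mediation_triple(..., delta =)`) — the test suite verifies the
bias formula rather than pretending the method is immune. The analytic
2SLS t-test is the implemented significance measure; self-mediation pairs
(trans gene equal to cis gene) are rejected as degenerate.

## The synthetic benchmark

All validation is property-based on generated data, since the cohort data
the method targets are controlled-access. The generator
(`sim_config()` / `simulate_truth()` / `assemble_tensor()`) plants:

* genotypes as Binomial(2, p) dosages, p uniform on (0.1, 0.4) by default;
* 4 sparse components with 20-gene supports, on-support loadings N(0, 1);
* 2 dense confounders loading N(0, 0.1^2) on every gene — weak enough that
  sparsity calling is a real discrimination task, not a triviality;
* condition-activity patterns from a small library (single condition, all
  conditions, contiguous subset), mirroring stimulus-specific versus shared
  programs;
* individual scores N(0, 1), plus `beta * dosage` for genetically driven
  components (`beta = 1.5` at MAF 0.3 in the power benchmark);
* per-(gene, condition) noise precisions, 4 by default (noise sd 0.5);
* optional missingness of whole individual x condition slices, repaired so
  every individual and condition keeps at least one observation.

Default sizes are N = 150, L = 600, T = 3 with C = 8 fitted components —
chosen so a full decomposition takes seconds and the complete pipeline
under a minute, while keeping every statistical regime of interest
(overfitted C, single-condition components, dense confounders) present.
Where the underlying study conditions leave a quantity unstated (the
effect-size distribution of genetically driven components, the dense
confounder scale), the defaults above are this package's declared choices.

What the generator does **not** emulate — and what passing tests therefore
do not establish about real data: linkage disequilibrium beyond duplicated
SNPs (no haplotype structure), population stratification, microarray
probe-level artifacts, non-Gaussian expression noise, and correlated
missingness. Determinism is exact: every operation derives its RNG stream
from an explicit seed, and rerunning a pipeline configuration reproduces
identical per-file checksums.

## The pipeline

`run_pipeline()` chains simulate (or load) → decompose → component calling
→ covariate screen → trans-eQTL → permutation null → GWAS overlap →
mediation, writing each stage's TSV/JSON outputs and a manifest with
per-stage seeds and per-file MD5 checksums. In synthetic mode the mediation
stage runs on planted chain and null triples (the tensor benchmark plants
direct SNP-on-component effects, which are deliberately *not* mediated);
`summarize_run()` reports headline counts plus recovery metrics against the
planted truth. Real mode accepts per-condition expression TSVs, VCF
(DS or GT) or TSV genotypes, a covariate table and a GWAS catalog table.

## Known limitations

* Model selection for `C` is manual; the implementation caps `C` at 500 but
  makes no attempt to choose it.
* The mean-field posterior underestimates uncertainty, as mean-field
  posteriors do; PIPs are used as a ranking/thresholding device, not as
  calibrated probabilities.
* The exact update equations of the original multi-tissue decomposition
  software are not public in the source describing it; this implementation
  commits to the model and prior family stated above, and numerical
  agreement with that software is not claimed.
* Single-instrument MR cannot detect exclusion-restriction violations; the
  pleiotropy bias is documented and quantified instead.
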