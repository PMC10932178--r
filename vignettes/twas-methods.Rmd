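---
title: "Methods: from test-day records to gene-based association in buffalo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from test-day records to gene-based association in buffalo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models behind `bubalusTwas`, the choices made
where conventions were genuinely open, and what the synthetic cohort does
and does not establish about real data.

## The analysis chain

Water buffalo milk traits (daily milk yield, fat and protein percentage)
are recorded repeatedly along the lactation. The package estimates one
breeding value per animal from those records, associates it with
whole-genome SNP dosages, and then asks — via genetically regulated
expression — which genes' *cis*-regulated blood expression carries the
association. The chain is:

1. test-day records → random-regression mixed model → per-animal EBV;
2. genotype QC → kinship + principal components;
3. RNA-seq counts → TPM → expression filter;
4. per-gene *cis*-eQTL weights by Dirichlet process regression (stage I);
5. single-SNP association scan of the EBV (summary statistics);
6. gene-based burden Z statistics in the FUSION and SPrediXcan forms
   against an LD reference (stage II), Bonferroni thresholds, overlap,
   and 25 kb positional annotation.

## Random-regression test-day model

A record at `t` days in milk (DIM) for animal `m` is modelled as

```
y = HTD + YS + MC + sum_n b_n phi_n(w_t) + sum_n a_mn phi_n(w_t)
    + sum_n p_mn phi_n(w_t) + e
```

with fixed herd–test-date (HTD), calving year–season (YS) and month of
calving (MC) classes, fixed Legendre regressions `b`, additive-genetic
coefficients `a_m ~ N(0, A ⊗ K_a)` (A = pedigree numerator relationship
matrix by Henderson's tabular method, with inbreeding), permanent
environment `p_m ~ N(0, I ⊗ K_p)` and i.i.d. residuals. Choices:

* **Basis.** `phi_n(w) = sqrt((2n+1)/2) P_n(w)`, the Kirkpatrick
  normalisation that test-day software uses by default, with
  `w = -1 + 2 (DIM - 5)/295` from the recording window DIM 5–300. Order 3
  (four terms).
* **Identifiability.** The first level of each retained class factor is
  constrained to zero; `phi_0` is constant and acts as the intercept.
* **Factor screening.** Candidate class factors are screened jointly in an
  ordinary linear model; a factor is retained when its partial F-test has
  p < 0.05. Single-level factors are dropped with a warning.
* **Variance components are inputs.** No reference values exist for this
  cohort, so `K_a`, `K_p`, `sigma_e2` are explicit configuration
  (defaults: diagonal matrices on a kg daily-yield scale giving a daily
  heritability near 0.2 at mid-lactation). REML estimation is out of scope.
* **Scalar EBV.** The per-animal summary is the mean daily additive value
  over DIM 5..300, `mean_t phi(w_t)' a_m` — equivalently the 296-day
  additive total divided by 296. Any collapse rule is a convention; this
  one weights the whole lactation evenly and is shift-free in the odd basis
  terms.
* **Solver.** Henderson's mixed-model equations, dense symmetric solve.
  At desk scale (≤ a few hundred animals, ≤ ~10k records) this is exact
  and fast; the unit tests verify equality with a generalised least squares
  oracle built from the full covariance on small instances (tolerance
  1e-8).

## Genotype QC and structure covariates

Filter order: individual call rate > 0.99, SNP call rate > 0.99 (both
strict), minor allele frequency > 0.05, exact Hardy–Weinberg p > 1e-6.
The HWE test is the exact conditional test (two-sided, summing
configurations no more likely than the observed one) rather than the
chi-square approximation — with ~100 animals the exact test is the
defensible choice, and it is validated exhaustively against an enumeration
oracle for totals ≤ 50. Missing dosages surviving QC are mean-imputed per
SNP. Kinship is VanRaden method 1; principal components come from the
column-standardised dosages with a fixed sign convention so runs are
reproducible.

## Expression preparation

TPM is the standard length-normalised formula
`TPM = (c/len) / sum(c/len) * 1e6`; the effective length is the annotated
gene span unless an explicit length column is supplied. The expression
filter keeps a gene reaching TPM ≥ 0.1 in at least `ceil(0.2 n)` samples
(both comparisons inclusive).

## Stage I: Dirichlet process regression

Per gene, with centered expression `E` and centered (not standardised)
*cis* dosages `G` within ±1 Mb of the TSS:

```
E = G w + eps,  w_l ~ N(0, sigma_l^2),  sigma_l^2 ~ H,  H ~ DP(IG(a0, b0), alpha)
```

The DP prior on the effect-size variances lets the architecture interpolate
between sparse and polygenic without choosing in advance. Inference is
truncated stick-breaking mean-field variational Bayes (no Monte Carlo):
conjugate coordinate updates for the effect vector, component assignments,
sticks, component precisions and the residual precision. The ELBO is
computed each sweep and asserted non-decreasing; convergence is a relative
ELBO change below `tol`.

Numerical and design choices:

* Defaults `k_trunc = 4`, `dp_alpha = 1`, `a0 = b0 = 0.1`, `tol = 1e-5`,
  `max_iter = 1000`. Initialisation is deterministic (uniform
  responsibilities; component precisions on a geometric grid around the
  variance-split-evenly-over-SNPs scale), so the fit is reproducible
  bit-for-bit.
* Expression is standardised internally and the weights rescaled back.
  This makes the fit exactly scale-equivariant and places the weakly
  informative inverse-gamma base measure on a unit-variance scale; the
  returned weights are on the per-allele input scale that the SPrediXcan
  statistic's explicit `sigma_l` factor expects.
* With `k_trunc = 1` the model collapses to ridge regression; the tests
  exploit this as an analytic oracle (agreement to 1e-6).
* Cross-validation: 5 folds as contiguous blocks of a permutation seeded
  by `cv_seed` (default 42); CV R² is the squared Pearson correlation of
  pooled out-of-fold predictions with the observed expression. Models are
  retained when CV R² > 0.005 (strict).

## Stage II: summary-statistic burden tests

The single-SNP scan is OLS of the EBV on `[1, PCs, dosage]`; p-values use
the standard normal reference so `z` and `p` round-trip exactly through
the burden statistics (at n = 100 the normal and t references differ
mildly in the far tail; the round-trip property was judged more important
than the small-sample refinement). An optional kinship pre-whitening flag
is available. The iterative multi-locus machinery of published GWAS tools
is intentionally not reproduced: stage II only needs well-calibrated
per-SNP summary statistics.

The burden statistics are

```
Z_FUSION     = sum_l w_l z_l / sqrt(w' Corr(G0) w)
Z_SPrediXcan = sum_l w_l sigma_l z_l / sqrt(w' Cov(G0) w)
```

with the cohort (or any reference panel) supplying `Corr(G0)`, `Cov(G0)`
and `sigma_l^2 = Var(G0_l)`. They coincide when all reference variances
are 1. Degenerate denominators (< 1e-12) yield `NA` and are excluded from
the default effective test count. Non-PSD reference covariances are
repaired by eigenvalue clipping at 1e-8 (recorded per gene). Two-sided
p-values are floored at 1e-300. The per-trait threshold is
`0.05 / N_effective`, where `N_effective` defaults to the genes actually
tested and can be supplied explicitly to reproduce printed thresholds.
The headline correctness property — verified in the acceptance tests — is
that when the GWAS cohort is its own LD reference, `Z_SPrediXcan` agrees
with the t statistic of regressing the phenotype directly on imputed GReX
to within 0.05 per gene on a 500-animal, 50-gene panel with weak per-gene
trait associations (the regime in which the summary-statistic identity
holds; with strong associations the two references differ at order
`R^3 sqrt(n)`).

## The synthetic cohort

The generator mirrors the study design rather than buffalo biology:

* **Pedigree**: founder generation plus equal-sized descendant
  generations, parents always earlier; the default run uses 215 animals of
  which the last 100 are phenotyped and genotyped.
* **Genotypes**: haplotypes from a first-order Markov copying process —
  each allele copies its left neighbour with probability `ld_rho` (default
  0.3), otherwise a fresh Bernoulli draw. This gives tunable
  exponentially-decaying LD without an external reference panel. Dosages
  are sums of two haplotypes; allele frequencies are drawn from
  `maf_range` (default 0.05–0.5).
* **Expression**: `E = base + G w + eps` with the causal fraction
  `p_causal_cis` (default 0.1) of cis SNPs receiving normal effects scaled
  to an exact in-sample `h2_cis` (default 0.1, in line with modest blood
  cis heritability); counts are Poisson draws proportional to
  expression × length × depth, so TPM recovers the profile.
* **Test-day records**: forward simulation of the random-regression model
  above, with staggered calving dates so herd–test-date classes are not
  confounded with DIM.

Deliberately absent: genotype–trait coupling in the default cohort (the
breeding values come from the pedigree, not the SNPs), so the default
end-to-end run is a *null* panel — the correct expectation is zero
significant genes, which is what the pipeline reports. Also absent:
buffalo demography, sequence-level mutation processes, expression batch
structure, and non-Gaussian trait noise. Passing tests therefore establish
algorithmic correctness and calibration, not biological effect recovery on
real data.

## Problem sizes and reproducibility

All simulations are seeded and byte-reproducible; the pipeline manifest
records seeds, per-stage counts and file checksums, and running the same
configuration twice yields identical manifests. The test suite exercises:
oracle equality on small instances (≤ 10 animals for the mixed model,
totals ≤ 50 for HWE); recovery panels at n = 500 (DPR, stage II) and 200
animals × 20 replicates (EBV); null calibration at 2000 SNPs and 500
genes; and the full default pipeline (100 animals, 5000 SNPs, 300 genes)
run twice. These sizes were chosen as the smallest panels at which the
statistical properties under test are stable.

## Known limitations

* Variance components are fixed inputs; misspecification propagates to
  EBV reliability exactly as in routine BLUP evaluation.
* The DPR fit is variational: posterior means are exact only in the ridge
  limit; posterior uncertainty in `w` is not propagated into stage II
  (standard practice for TWAS weights, but worth remembering).
* The normal-reference p-values of the scan are mildly anti-conservative
  at very small n relative to the t reference.
* `N_effective` equal to the number of tested genes ignores inter-gene LD;
  the explicit `n_effective` input exists for externally derived counts.
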