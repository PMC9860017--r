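# finewas

Integrative statistical genetics for dissecting the architecture of a
complex disease from summary statistics: QTL effect-size meta-analysis,
enumeration-based fine-mapping annotations, stratified LD-score regression,
two-stage transcriptome-wide association (TWAS) with gene-level
fine-mapping, and rare-variant genic burden testing. Every stage runs on
synthetic cohorts with recorded simulation truth, so the full pipeline is
testable without access-controlled genotype data. The shipped example
tables are published two-stage ALS TWAS and rare-variant burden summaries,
used in the worked examples below.

The package is aimed at statistical geneticists who want desk-scale,
auditable implementations of these estimators — every core statistic is
cross-checked in the test suite against an independent brute-force
implementation.

## The statistics implemented

**Fixed-effect QTL meta-analysis.** Per-variant effect sizes across studies
combine as z_FE = Σ_j w_j β_j / sqrt(Σ_j w_j) with w_j = 1/se(β_j)²,
equivalent to a weighted average of per-study z-scores
(`fixed_effect_meta`).

**Fine-mapping and MaxCPP annotations.** For a region with marginal
Z-scores z and LD matrix R, causal configurations C (all subsets up to size
K, plus the null configuration) are scored under
z ~ N(0, R + s² R_C R_Cᵀ); the causal posterior probability (CPP) of a SNP
is the posterior mass of configurations containing it, and the 95% credible
set accumulates configurations by descending posterior (`compute_cpp`,
`credible_set`). The MaxCPP annotation of SNP j is max_i α_ji over genes i
whose credible set contains j, optionally restricted to a gene subset
(`max_cpp_annotation`); binding-site annotations flag SNPs within ±100 nt
flanks of RNA-binding-protein intervals (`rbp_annotation`).

**Stratified LD-score regression.** With annotation LD scores
l(j,c) = Σ_k a_c(k) r²_jk (`ld_scores`), per-SNP χ² statistics follow
E[χ²_j] = N Σ_c τ_c l(j,c) + N b + 1; weighted regression estimates the
per-annotation coefficients τ_c and the confounding intercept, with SEs, Z
and one-sided p-values from a delete-one-block jackknife
(`regress_partitioned`, `block_jackknife`). Effect sizes standardize as
τ* = M·sd(a_c)/h² · τ_c (`standardize_tau`); binary annotations also get
enrichment (h² share)/(SNP share) (`enrichment`), and `conditional_model`
refits one focus annotation at a time against a fixed baseline.

**Two-stage TWAS.** Genes passing a Haseman–Elston cis-heritability screen
(`estimate_cis_h2`) get expression weights (`fit_weights`: top-eQTL or
cross-validated ridge); the association statistic is
Z = wᵀz / sqrt(wᵀRw) (`twas_associate`). Stages combine by Stouffer's
method weighted by effective sample size N_eff = 4/(1/N_cases + 1/N_controls)
(`stouffer_meta`), with Bonferroni control at 0.05/(genes × tissues)
(`multiple_testing`). Gene-level posterior inclusion probabilities reuse
the configuration machinery on the predicted-expression correlation matrix
(`gene_pip`).

**Rare-variant burden.** Variants classify into disruptive / damaging
(missense, unanimously deleterious across prediction algorithms) /
missense / other (`classify_variants`); masks pair a MAF threshold (0.01 or
0.005) with a nested class family (`burden_mask`). Per-individual burden
counts qualifying sites (`build_burden`; transcripts need ≥ 5 carriers),
tested by Firth-penalized logistic regression — Newton iteration on the
Jeffreys-prior-penalized likelihood, finite under complete separation, with
profile-penalized-likelihood CIs (`firth_logistic`). Cohorts combine by
inverse-variance weighting (`ivw_meta`).

## Worked example

Partitioned heritability on a synthetic GWAS (4000 individuals, 1000
LD-blocked SNPs, a 30%-membership "binding site" annotation with true
τ = 3e-4 on top of a base annotation with τ = 5e-5):

```r
library(finewas)
panel <- simulate_ld_panel(4000, 1000, block_size = c(1, 25), rho = 0.6, seed = 1)
set.seed(2)
annot <- cbind(base = rep(1, 1000), rbp = as.numeric(runif(1000) < 0.3))
gwas  <- simulate_gwas(panel, annot, tau = c(base = 5e-5, rbp = 3e-4), seed = 3)
fit <- regress_partitioned(gwas$sumstats, ld_scores(panel, annot), n_blocks = 50)
fit$coef[, c("annotation", "tau", "tau_se", "tau_star", "enrichment", "p_one_sided")]
#>   annotation      tau   tau_se tau_star enrichment p_one_sided
#> 1       base 7.04e-05 4.42e-05       NA       1.00    5.57e-02
#> 2        rbp 3.01e-04 7.04e-05    0.847       2.25    9.59e-06
```

The focus annotation's coefficient (3.01e-4) recovers the simulated 3e-4;
its one-sided jackknife p-value 9.6e-6 detects the enrichment (2.25×
heritability concentration on 30% of SNPs).

Combining the shipped published two-stage TWAS table with
effective-sample-size Stouffer weights, and the per-cohort rare-variant
burden estimates by inverse-variance meta-analysis:

```r
ex  <- function(f) system.file("extdata", f, package = "finewas")
zz  <- read.delim(ex("twas_two_stage_z.tsv"))
cnt <- read.delim(ex("twas_stage_counts.tsv"))
row <- zz[zz$gene == "SCFD1", ]
stouffer_meta(c(row$z_discovery, row$z_replication), cnt$n_cases, cnt$n_controls)
#> SCFD1 combined Z = 6.2   p = 5.62e-10

co <- read.delim(ex("nup50_burden_cohorts.tsv"))
le <- logor_from_ci(co$or, co$ci_low, co$ci_high)
ivw_meta(le$beta, le$se)
#> NUP50 burden meta: OR = 3.26 (95% CI 1.43-7.40), p = 0.0048
```

Both reproduce the published combined values (6.20; OR 3.29) from the
rounded per-stage inputs.

## Vignette

`vignettes/finewas-methods.Rmd` describes the models and their
assumptions, the synthetic-data generators and what they do and do not
emulate, the numerical choices (ridge regularization, tie-breaking,
profile-likelihood intervals) and known limitations.
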