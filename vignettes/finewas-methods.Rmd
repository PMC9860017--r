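---
title: "Models, simulation designs and numerical choices in finewas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, simulation designs and numerical choices in finewas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

finewas implements, at desk scale, the summary-statistic machinery used to
triangulate risk genes for a complex disease: molecular-QTL effect-size
meta-analysis, fine-mapping-derived functional annotations, partitioned
SNP-heritability, two-stage TWAS with gene-level fine-mapping, and
rare-variant genic burden testing. This vignette records the models, the
assumptions behind them, the simulation designs used to validate them, and
the numerical decisions a maintainer would want to know about.

## Partitioned heritability

The model is the stratified LD-score regression of GWAS chi-square
statistics on annotation LD scores:

$$E[\chi^2_j] \;=\; N \sum_c \tau_c\, l(j,c) \;+\; Nb \;+\; 1,
\qquad l(j,c) = \sum_k a_c(k)\, r^2_{jk},$$

where $a_c(k)$ is the value of annotation $c$ at SNP $k$ (binary or
continuous in $[0,1]$), $r_{jk}$ the reference-panel correlation, $N$ the
GWAS sample size and $b$ a confounding term. LD scores always use
**squared** correlations: the regression above is only coherent with
$r^2$, since the tagged variance of SNP $k$ by SNP $j$ is $r^2_{jk}
\sigma^2_k$. A `squared = FALSE` mode summing raw correlations exists
purely so unit tests can pin the literal summation; it is not meaningful
for inference. When LD scores are estimated from a genotype panel of $n$
individuals, the standard finite-sample adjustment
$r^2_{\rm adj} = r^2 - (1 - r^2)/(n - 2)$ removes the upward sampling bias
of squared sample correlations.

`regress_partitioned` fits by weighted least squares with a free
intercept. Default weights are the usual heteroskedasticity/overcounting
weights $1/[l_{\rm base}(1 + N \bar h^2 l_{\rm base}/M)^2]$ computed from a
first-pass unweighted fit ($\bar h^2$ clamped to $[10^{-9}, 1]$,
$l_{\rm base}$ floored at 1); `weights_mode = "ols"` exists for the
exactness oracles, for which a noiseless system must be recovered to
machine precision. Inference is a delete-one-block jackknife over
contiguous SNP blocks (200 by default, the field's convention, capped at
half the SNP count), with one-sided upper-tail p-values by default because
the scientific hypotheses are enrichment-directional; a flag gives
two-sided. Effect sizes standardize as
$\tau^* = M \,\mathrm{sd}(a_c)\, \tau_c / h^2$ so they compare across
traits; enrichment, defined only for binary annotations, is the ratio of
heritability share to SNP share and conserves
$\sum_c (M_c/M)\,\mathrm{enr}_c = 1$ over disjoint partitions.
`conditional_model` refits one focus annotation at a time against a fixed
baseline — never all foci jointly — matching how per-annotation scans are
reported.

**Identifiability caveat.** In a region of ~1000 SNPs, $N \cdot
l_{\rm base}$ and the free intercept are strongly correlated, so the base
(all-SNP) coefficient is weakly identified: its point estimate is noisy and
its jackknife intervals undercover mildly (~0.86–0.90 across simulation
seeds instead of 0.95). The focus-annotation coefficient — the quantity the
method is used for — is well identified (coverage 0.92–0.96 in the same
runs). The recovery benchmark therefore asserts accuracy and coverage on
the focus coefficient and only a sanity floor on the base coefficient.
Genome-scale analyses with millions of SNPs do not face this to the same
degree.

## Fine-mapping and annotations

`compute_cpp` enumerates causal configurations $C$ (all subsets of the
region up to size $K$, plus the null configuration) and scores each under

$$z \mid C \;\sim\; N\!\left(0,\; R + s^2 R_C R_C^\top\right),$$

with $R$ the LD matrix, $R_C$ its causal columns and $s$ the
non-centrality scale of a standardized causal effect. Defaults: $s = 5.2$
(a conventional value for this family of models; no principled setting is
implied, and it is exposed in the API), ridge regularization $R +
10^{-4} I$ for invertibility, per-SNP prior $1/m$ per causal slot with the
multi-causal prior the product over slots, and the null configuration
carrying the empty product. Enumeration is capped at $m \le 50$, $K \le 3$;
larger regions must be split. The credible set is built at **configuration**
level: configurations sorted by posterior (ties broken by ascending SNP
index — the sort is stable over the generation order) accumulate until the
target mass, and the set is the union of SNPs in retained configurations.
This honours the guarantee of containing *all* causal variants with the
stated probability, which a marginal-CPP construction does not when
$K > 1$.

MaxCPP assigns SNP $j$ the maximum CPP over genes whose credible set
contains it, zero otherwise. One annotation column is built per QTL
dataset; an across-dataset column is the element-wise `pmax` of the
per-dataset columns. The gene keying is whatever unit the fine-mapping was
run on — genes for eQTLs, introns for splicing QTLs — so both keyed modes
are available by construction, and a gene subset (e.g. constrained genes)
restricts the maximum. Binding-site annotations flag SNPs within merged
intervals extended by a 100-nt flank on both sides; BED input is 0-based
half-open, SNP coordinates 1-based, and all conversions happen in the I/O
layer only.

`gene_pip` reuses the same enumeration at gene level, with the
predicted-expression correlation matrix in place of LD and exhaustive
subset enumeration by default (regions capped at 15 genes). Including the
null configuration means PIPs need not sum to 1; the 90%-credible gene set
accumulates genes by descending PIP normalized over genes.

## Two-stage TWAS

The cis-heritability screen is a Haseman–Elston regression: with
standardized expression $y$ and cis relatedness $A_{ij}$ (inner product of
standardized cis genotypes divided by the SNP count), the slope of
$y_i y_j$ on $A_{ij}$ over unordered pairs estimates $h^2_{\rm cis}$. The
screen p-value is a one-sided label permutation (200 permutations by
default, seeded); the exclusion threshold $p < 0.01$ is configurable since
different pipelines use different screens. Weight fitting offers two
members of the usual predictive-model menu — the top-eQTL indicator and
ridge with 5-fold cross-validated penalty — because these are closed-form
checkable and sufficient to exercise the association statistic, which is
the object of interest:

$$Z_{\rm TWAS} = \frac{w^\top z}{\sqrt{w^\top R\, w}},$$

invariant to rescaling of $w$ and exactly standard normal under the null
$z \sim N(0, R)$.

Stages combine by Stouffer's weighted method,
$Z = \sum_s w_s z_s / \sqrt{\sum_s w_s^2}$, with $w_s$ proportional to the
per-stage effective sample size $N_{\rm eff} = 4/(1/N_{\rm cases} +
1/N_{\rm controls})$. This weight choice reproduces the published combined
Z-scores in the shipped two-stage example table at two decimals
(`stouffer_meta`'s `weight_mode` also offers $\sqrt{N_{\rm eff}}$ and
total-N). Two of the six genes in that table (SCFD1, JAKMIP3) are exactly
reproducible from their printed per-stage Z-scores under this weighting;
the others are not under any simple weighting, presumably because the
original per-gene weights differed, so only the reproducible two serve as
worked examples. Transcriptome-wide significance uses Bonferroni at
$0.05/(\text{genes} \times \text{tissues})$ plus Benjamini–Hochberg FDR.

## Rare-variant burden

Variants classify as *disruptive* (frame-shift, splice-site, exon loss,
stop gained, start loss, transcription ablation), *damaging* (missense and
unanimously deleterious across **all supplied** prediction-algorithm flags
— the algorithm count is a property of the input, not the code),
*missense*, or *other* (unknown terms warn, never drop). Masks pair a MAF
threshold of 0.01 or 0.005 with one of the nested class families. The MAF
used for masking is the external (population-reference) allele frequency
when present, else the cohort frequency. Burden counts **sites** at which
an individual carries at least one alternate allele — homozygotes count
once — because "number of variants per individual" is the common
convention; a dosage mode is available behind a flag. Transcripts with
fewer than five non-zero-burden individuals are excluded.

Firth regression maximizes $\ell(\beta) + \tfrac12 \log \det I(\beta)$ by
Newton iteration with the hat-matrix score correction
$U^*_j = \sum_i (y_i - p_i + h_i(1/2 - p_i)) x_{ij}$ and step-halving on
the penalized likelihood; estimates are finite under complete separation.
Confidence intervals default to the profile penalized likelihood (more
accurate than Wald for sparse tables; Wald and a fast no-CI mode are
flags), searched by bracket expansion up to $32\,\mathrm{SE}$ and
root-finding on the penalized deviance. Both the penalized
likelihood-ratio p-value (the primary `p`) and the Wald p-value are
reported, since either convention appears in practice. Cross-cohort
combination is inverse-variance weighting on the log-OR scale;
`logor_from_ci` recovers $(\beta, \mathrm{SE})$ from results published
only as OR with a 95% CI, with the precision limit that implies.

## What the generators emulate — and what they do not

*Genotypes* follow a latent Gaussian threshold model: two independent
haplotype-level latent draws per individual with block-constant
correlation $\rho$, thresholded at the allele-frequency quantile. This
yields Hardy–Weinberg-consistent dosages and controllable LD, with block
sizes drawn from a range so LD scores vary across the panel as they do in
real genomes. The thresholding *attenuates* correlation (latent
$\rho = 0.9$ realizes genotype $r \approx 0.71$ at MAF 0.4–0.5, less at
lower MAF); the attenuation is measured empirically in the tests, never
assumed. There is no coalescent realism: no allele-frequency spectrum
shaped by drift, no recombination hotspots, no population structure beyond
the explicit confounder, and no imputation-error model.

*GWAS statistics* draw per-SNP causal effects $\beta_j \sim N(0,
\sigma^2_j)$ with $\sigma^2_j = \sum_c a_c(j) \tau_c$ — the
infinitesimal-within-annotation model that the partitioned regression
assumes — so the regression's expectation holds by construction.
Confounding is a shared score proportional to each individual's mean
standardized genotype, scaled so every $\chi^2$ gains the requested amount
in expectation (exact for independent SNPs, approximate under LD). Passing
tests therefore show the estimators are correct *under their own model*;
they do not show robustness to LD-dependent architecture or
annotation-dependent allele frequencies, which real analyses must worry
about.

*Expression panels* partition the panel's SNPs into contiguous cis
windows, one gene each, with the causal genetic score rescaled to exactly
the requested $h^2_{\rm cis}$. *Rare-variant cohorts* draw carrier
genotypes binomially per site, simulate consequence labels and
exchangeable per-algorithm deleteriousness flags, and draw case status
from a logistic liability on the count of **non-synonymous** sites (so a
qualifying-variant mask can match the causal set exactly); a prospective
pool is then sampled down to the requested arm sizes, which leaves the
odds ratio invariant. Deleteriousness flags are exchangeable Bernoulli
draws — there is no correlation structure between algorithms, unlike real
predictors.

## Validation designs and problem sizes

The benchmarks (exported as `benchmark_*`, shared by the test suite and
`scripts/acceptance.R`) use designs sized to finish in seconds-to-a-minute
each on one CPU while leaving Monte-Carlo error well inside the asserted
tolerances:

* τ recovery: one panel of 4000 individuals × 1000 SNPs (blocks 1–25,
  $\rho = 0.6$), base τ $5\times10^{-5}$, 30%-membership focus τ
  $3\times10^{-4}$, 50 GWAS replicates; asserts the focus mean within 10%
  and 95% jackknife coverage ≥ 0.90.
* cis-h²: 100 genes, 20-SNP windows, 1000 individuals, true 0.8; mean
  within ±0.1.
* Firth recovery: 200 cohorts of 300+300 with ~30 carriers per arm and
  OR 5; mean log-OR within ±0.35 of log 5.
* Null calibration: 2000 exact-null TWAS draws, 500 null burden genes
  (rejection at 0.05 within its binomial interval; order-statistic band on
  the p-values), 500 single-causal regions (credible-set coverage ≥ 0.93 —
  configuration-level sets are conservative, and measured coverage is
  essentially 1).

## Known limitations

* Real-data standardized effect sizes depend on genome-scale baseline
  annotation files and reference panels; they are not reproducible at this
  package's scale, and no attempt is made.
* Enumeration fine-mapping is capped (50 SNPs, $K \le 3$; 15 genes); there
  is no stochastic search for large regions.
* Allele harmonization (strand flips, palindromic SNPs) is out of scope:
  matching is exact on the effect/other allele pair, with an optional swap
  that negates Z, and upstream QC is assumed.
* The Firth profile intervals report the bracket edge if the profile is
  flat beyond $32\,\mathrm{SE}$ — pathological but possible in tiny
  tables.
* Chi-square statistics are taken as $z^2$ with no genomic-control
  correction.
* The penalized-LRT burden p-values are mildly anti-conservative at sparse
  carrier counts (pooled empirical type-I ≈ 0.055 across benchmark seeds
  at a nominal 0.05), and gene-level tests within one cohort are
  positively correlated through the shared phenotype and covariates, so
  the null benchmark's rejection rate varies more across cohorts than an
  independent-binomial model implies.
* Scans over many annotations summarize as the plain mean of the per-focus
  conditional τ* values (each focus fitted separately against the same
  baseline); the mean of identical focus columns equals the single-column
  τ* by construction.
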