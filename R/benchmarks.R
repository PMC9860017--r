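# Parameter-recovery and calibration benchmarks: fixed simulation designs
# that exercise the full pipeline against recorded simulation truth. The
# test suite and the reproducibility script both call these, so the study
# conditions are defined once. Problem sizes are chosen so each benchmark
# runs in seconds-to-a-minute on one CPU; the methods vignette discusses
# the designs.

# per-replicate seeds derived reproducibly from one master seed
derive_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Benchmark: partitioned-heritability coefficient recovery
#'
#' One LD-blocked panel (4000 individuals, 1000 SNPs, variable block sizes)
#' with a base annotation plus a 30%-membership focus annotation; GWAS
#' statistics are redrawn per replicate with tau = (5e-5, 3e-4) and the
#' regression re-estimated each time. Reports the mean estimate/truth ratio
#' for the focus coefficient and the empirical coverage of 95% jackknife
#' intervals for both coefficients.
#'
#' @param n_reps replicates (default 50)
#' @param seed master seed
#' @return list with `ratio_focus`, `coverage`, per-replicate estimates and
#'   the true tau
#' @export
benchmark_tau_recovery <- function(n_reps = 50L, seed = 1L) {
  tau <- c(base = 5e-5, focus = 3e-4)
  seeds <- derive_seeds(seed, n_reps + 2L)
  panel <- simulate_ld_panel(4000, 1000, block_size = c(1, 25), rho = 0.6,
                             seed = seeds[n_reps + 1L])
  set.seed(seeds[n_reps + 2L])
  A <- cbind(base = rep(1, 1000), focus = as.numeric(stats::runif(1000) < 0.3))
  ls <- ld_scores(panel, A)
  est <- matrix(NA_real_, n_reps, 2)
  cover <- matrix(NA, n_reps, 2)
  for (r in seq_len(n_reps)) {
    g <- simulate_gwas(panel, A, tau = tau, seed = seeds[r])
    fit <- regress_partitioned(g$sumstats, ls, n_blocks = 50)
    est[r, ] <- fit$coef$tau
    lo <- fit$coef$tau - 1.96 * fit$coef$tau_se
    hi <- fit$coef$tau + 1.96 * fit$coef$tau_se
    cover[r, ] <- tau >= lo & tau <= hi
  }
  list(ratio_focus = mean(est[, 2]) / tau[["focus"]],
       coverage = colMeans(cover), est = est, tau = tau, n = n_reps)
}

#' Benchmark: cis-heritability recovery at cis_h2 = 0.8
#'
#' 100 genes with one causal cis SNP each (windows of 20 SNPs, 1000
#' individuals); Haseman-Elston estimates are averaged over genes.
#'
#' @param n_genes genes (default 100)
#' @param seed master seed
#' @return list with `mean_h2`, per-gene estimates
#' @export
benchmark_cis_h2 <- function(n_genes = 100L, seed = 1L) {
  seeds <- derive_seeds(seed, 2L)
  panel <- simulate_ld_panel(1000, 20L * n_genes, block_size = c(1, 5),
                             rho = 0.4, seed = seeds[1])
  eq <- simulate_eqtl_panel(panel, n_genes = n_genes, causal_per_gene = 1,
                            cis_h2 = 0.8, seed = seeds[2])
  h2 <- vapply(seq_len(n_genes), function(g)
    estimate_cis_h2(eq, g, n_perm = 0)$h2, numeric(1))
  list(mean_h2 = mean(h2), h2 = h2, n = n_genes)
}

#' Benchmark: Firth log-odds-ratio recovery at OR = 5
#'
#' Per replicate: a cohort of 300 cases / 300 controls with one gene of 20
#' rare variants (MAF 1e-3 to 4e-3, about 30 expected carriers per arm),
#' a true per-burden-unit odds ratio of 5 and a sex covariate; the full
#' classify/mask/burden/Firth chain is run and the burden log-OR recorded.
#'
#' @param n_reps replicates (default 200)
#' @param seed master seed
#' @return list with `mean_beta`, `true_beta` (= log 5), per-replicate betas
#' @export
benchmark_firth_recovery <- function(n_reps = 200L, seed = 1L) {
  seeds <- derive_seeds(seed, n_reps)
  mask <- burden_mask(0.01, c("disruptive", "damaging", "missense"))
  covspec <- data.frame(name = "sex", type = "binary", effect = 0.2,
                        stringsAsFactors = FALSE)
  betas <- vapply(seq_len(n_reps), function(r) {
    co <- simulate_rare_cohort(
      300, 300, n_genes = 1, per_gene_or = 5,
      variant_maf_spec = list(n_variants = 20, maf_range = c(1e-3, 4e-3)),
      covariate_spec = covspec, seed = seeds[r])
    bb <- build_burden(co$geno, classify_variants(co$variants), mask)
    firth_logistic(bb$burden[, 1], co$pheno$case,
                   covariates = co$pheno[, "sex", drop = FALSE],
                   ci = "none")$beta
  }, numeric(1))
  list(mean_beta = mean(betas), true_beta = log(5), betas = betas,
       n = n_reps)
}

#' Benchmark: TWAS association null calibration
#'
#' GWAS Z-vectors drawn exactly from N(0, R) for the LD matrix of a small
#' panel, combined with random weight vectors; under the null the TWAS
#' statistic is standard normal, so the empirical |Z| > 1.96 rate should be
#' 0.05.
#'
#' @param n_draws draws (default 2000)
#' @param seed master seed
#' @return list with `rejection_rate`, draws used
#' @export
benchmark_twas_null <- function(n_draws = 2000L, seed = 1L) {
  seeds <- derive_seeds(seed, 2L)
  panel <- simulate_ld_panel(1000, 30, block_size = 6, rho = 0.5,
                             seed = seeds[1])
  R <- panel_ld_matrix(panel)
  ch <- chol(R + diag(1e-8, 30))
  set.seed(seeds[2])
  rej <- vapply(seq_len(n_draws), function(d) {
    z <- drop(crossprod(ch, stats::rnorm(30)))
    w <- stats::rnorm(30)
    gwas <- data.frame(snp = panel$snps$snp, z = z, n = 1e4)
    abs(twas_associate(list(snps = panel$snps$snp, w = w), gwas, R)$z) > 1.96
  }, logical(1))
  list(rejection_rate = mean(rej), n = n_draws)
}

#' Benchmark: type-I error of the burden chain
#'
#' One cohort of 500 cases / 500 controls with 500 null genes (per-gene
#' odds ratio 1, 8 rare variants each) and a sex covariate; the full
#' mask/burden/Firth chain is run per transcript and the rejection rate at
#' alpha = 0.05 reported over included transcripts, together with the
#' p-value vector for Q-Q inspection.
#'
#' @param n_genes null genes (default 500)
#' @param seed master seed
#' @return list with `type1`, `p_values`, `n_included`
#' @export
benchmark_burden_null <- function(n_genes = 500L, seed = 1L) {
  seeds <- derive_seeds(seed, 1L)
  covspec <- data.frame(name = "sex", type = "binary", effect = 0.2,
                        stringsAsFactors = FALSE)
  co <- simulate_rare_cohort(
    500, 500, n_genes = n_genes, per_gene_or = 1,
    variant_maf_spec = list(n_variants = 8, maf_range = c(1e-3, 8e-3)),
    covariate_spec = covspec, seed = seeds[1])
  mask <- burden_mask(0.01, c("disruptive", "damaging", "missense"))
  bb <- build_burden(co$geno, classify_variants(co$variants), mask)
  covs <- co$pheno[, "sex", drop = FALSE]
  keep <- which(bb$included)
  pv <- vapply(keep, function(t)
    firth_logistic(bb$burden[, t], co$pheno$case, covariates = covs,
                   ci = "none")$p, numeric(1))
  list(type1 = mean(pv < 0.05), p_values = pv, n_included = length(keep),
       n = n_genes)
}

#' Benchmark: credible-set coverage over single-causal regions
#'
#' Per region: a fresh 20-SNP LD-blocked panel of 500 individuals, one
#' expression trait with a single causal SNP (cis_h2 = 0.2), marginal eQTL
#' Z-scores, and enumeration fine-mapping at K = 1; coverage is the
#' fraction of regions whose 95% credible set contains the true causal SNP.
#'
#' @param n_regions regions (default 500)
#' @param seed master seed
#' @return list with `coverage`, per-region hit indicator
#' @export
benchmark_credible_coverage <- function(n_regions = 500L, seed = 1L) {
  seeds <- derive_seeds(seed, 2L * n_regions)
  hit <- vapply(seq_len(n_regions), function(r) {
    panel <- simulate_ld_panel(500, 20, block_size = 5, rho = 0.5,
                               seed = seeds[r])
    eq <- simulate_eqtl_panel(panel, n_genes = 1, causal_per_gene = 1,
                              cis_h2 = 0.2, seed = seeds[n_regions + r])
    Xs <- standardize_genotypes(panel$X)
    z <- drop(sqrt(500) * stats::cor(Xs, eq$expr[, 1]))
    fm <- compute_cpp(z, panel_ld_matrix(panel), K = 1)
    fm$in_credible[eq$genes[[1]]$causal] == 1L
  }, logical(1))
  list(coverage = mean(hit), hit = hit, n = n_regions)
}
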