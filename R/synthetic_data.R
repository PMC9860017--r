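# Generators for every input the pipeline consumes: LD-blocked genotype
# panels, annotation-stratified GWAS summary statistics, sparse cis-causal
# expression panels and rare-variant case/control cohorts. Each generator is
# a pure function of its arguments including `seed`, and records the
# simulation truth needed by the parameter-recovery test suites.

#' Simulate an LD-blocked genotype reference panel
#'
#' Genotypes follow a latent Gaussian threshold model: each individual draws
#' two independent haplotype-level latent vectors with block-constant
#' correlation `rho`, and each is thresholded at the per-SNP allele-frequency
#' quantile, so genotypes are Hardy-Weinberg consistent by construction.
#' SNPs in different blocks are independent. The attenuation of the latent
#' correlation into realized genotype correlation is a property of the
#' thresholding and is measured empirically in tests, never assumed.
#'
#' @param n_individuals number of individuals (>= 2)
#' @param n_snps number of SNPs
#' @param block_size SNPs per LD block: a scalar for equal blocks or a
#'   length-2 range from which each block's size is drawn uniformly
#'   (variable block lengths make LD scores vary across the panel, as in
#'   real genomes)
#' @param rho latent within-block correlation, 0 <= rho < 1
#' @param maf_range length-2 vector; MAFs drawn uniformly in this range
#' @param seed integer seed
#' @param chrom chromosome label for the SNP metadata
#' @param spacing base-pair spacing between adjacent SNPs
#' @return an object of class `genotype_panel`: list with `X` (individuals x
#'   SNPs dosage matrix in \{0,1,2\}), `snps` (data.frame snp/chr/bp/a1/a2/maf),
#'   `blocks` (block index per SNP) and the generating parameters.
#' @export
simulate_ld_panel <- function(n_individuals, n_snps, block_size = 10,
                              rho = 0.5, maf_range = c(0.05, 0.5),
                              seed = 1L, chrom = "1", spacing = 1000L) {
  if (n_individuals < 2) fw_stop("argument", "need at least 2 individuals")
  if (rho < 0 || rho >= 1) fw_stop("argument", "rho must be in [0, 1)")
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2])
    fw_stop("argument", "maf_range must satisfy 0 < low <= high <= 0.5")
  set.seed(seed)
  n <- n_individuals; m <- n_snps
  maf <- stats::runif(m, maf_range[1], maf_range[2])
  if (length(block_size) == 1L) {
    blocks <- rep(seq_len(ceiling(m / block_size)),
                  each = block_size)[seq_len(m)]
  } else {
    sizes <- integer(0)
    while (sum(sizes) < m)
      sizes <- c(sizes, sample(block_size[1]:block_size[2], 1L))
    blocks <- rep(seq_along(sizes), times = sizes)[seq_len(m)]
  }
  thr <- stats::qnorm(1 - maf)
  X <- matrix(0L, n, m)
  for (hap in 1:2) {
    latent <- matrix(stats::rnorm(n * m), n, m)
    if (rho > 0) {
      for (b in unique(blocks)) {
        cols <- which(blocks == b)
        shared <- stats::rnorm(n)
        latent[, cols] <- sqrt(rho) * shared +
          sqrt(1 - rho) * latent[, cols]
      }
    }
    X <- X + (latent > rep(thr, each = n))
  }
  snps <- data.frame(
    snp = paste0("rs", seq_len(m)), chr = chrom,
    bp = seq_len(m) * spacing, a1 = "A", a2 = "G",
    maf = maf, stringsAsFactors = FALSE)
  colnames(X) <- snps$snp
  structure(list(X = X, snps = snps, blocks = blocks, rho = rho,
                 seed = seed),
            class = "genotype_panel")
}

# column-standardized dosages; monomorphic columns become all-zero
standardize_genotypes <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[sd == 0] <- Inf
  sweep(sweep(X, 2, mu, "-"), 2, sd, "/")
}

#' Empirical LD correlation matrix of a panel
#'
#' @param panel a `genotype_panel`
#' @return SNP x SNP correlation matrix with SNP dimnames
#' @export
panel_ld_matrix <- function(panel) {
  R <- stats::cor(panel$X)
  R[is.na(R)] <- 0
  diag(R) <- 1
  dimnames(R) <- list(panel$snps$snp, panel$snps$snp)
  R
}

#' Simulate GWAS summary statistics under an additive annotation model
#'
#' Per-SNP causal effects are drawn as beta_j ~ Normal(0, sigma2_j) with
#' sigma2_j = sum_c a_c(j) tau_c (the infinitesimal-within-annotation model
#' that stratified LD-score regression assumes), the phenotype is
#' y = X beta + confounder + noise with the noise scaled so the total
#' variance is 1, and marginal Z-scores are computed on `n_gwas`
#' individuals. Under this construction E[chi2_j] = N sum_c tau_c l(j,c)
#' + intercept_inflation + 1.
#'
#' Confounding is induced by a per-individual shared score proportional to
#' the individual's mean standardized genotype, scaled so each chi2 gains
#' `intercept_inflation` in expectation (exact for independent SNPs,
#' approximate under LD).
#'
#' @param panel a `genotype_panel`
#' @param annotations annotation data.frame (snp/chr/bp + columns) or a
#'   numeric matrix with one row per panel SNP
#' @param tau per-annotation variance coefficients (per-SNP heritability
#'   units), one per annotation column
#' @param intercept_inflation expected chi2 excess from confounding (the
#'   `N b` term); 0 disables the confounder
#' @param n_gwas GWAS sample size (must not exceed the panel size)
#' @param seed integer seed
#' @return list with `sumstats` (LDSC-dialect data.frame as from
#'   [read_sumstats()]) and `truth` (tau, per-SNP sigma2, beta, total h2,
#'   expected intercept)
#' @export
simulate_gwas <- function(panel, annotations, tau, intercept_inflation = 0,
                          n_gwas = nrow(panel$X), seed = 1L) {
  A <- annotation_matrix(annotations, panel$snps$snp)
  if (length(tau) != ncol(A))
    fw_stop("argument", "length(tau) must equal the number of annotations")
  sigma2 <- drop(A %*% tau)
  if (any(sigma2 < 0))
    fw_stop("model", paste0("negative per-SNP variance at SNP ",
                            panel$snps$snp[which(sigma2 < 0)[1]]))
  n <- n_gwas
  if (n > nrow(panel$X))
    fw_stop("argument", "n_gwas exceeds the panel size")
  m <- ncol(panel$X)
  h2 <- sum(sigma2)
  gamma2 <- if (intercept_inflation > 0) intercept_inflation * m / n else 0
  if (h2 + gamma2 >= 1)
    fw_stop("argument", "total genetic + confounder variance must be < 1")
  set.seed(seed)
  Xs <- standardize_genotypes(panel$X[seq_len(n), , drop = FALSE])
  beta <- stats::rnorm(m, 0, sqrt(sigma2))
  y <- drop(Xs %*% beta)
  if (gamma2 > 0)
    y <- y + sqrt(gamma2) * drop(Xs %*% rep(1 / sqrt(m), m))
  y <- y + stats::rnorm(n, 0, sqrt(1 - h2 - gamma2))
  z <- drop(crossprod(Xs, y)) / (sqrt(n) * stats::sd(y))
  ss <- data.frame(snp = panel$snps$snp, chr = panel$snps$chr,
                   bp = panel$snps$bp, a1 = panel$snps$a1,
                   a2 = panel$snps$a2, z = z, n = n,
                   stringsAsFactors = FALSE)
  ss$chi2 <- ss$z^2
  attr(ss, "n_dropped") <- 0L
  list(sumstats = ss,
       truth = list(tau = tau, sigma2 = sigma2, beta = beta, h2 = h2,
                    intercept = 1 + intercept_inflation, n_gwas = n))
}

# coerce an annotation data.frame (snp/chr/bp + value columns) or plain
# matrix to an m x C numeric matrix aligned with `snp_order`
annotation_matrix <- function(annotations, snp_order) {
  if (is.matrix(annotations)) {
    if (nrow(annotations) != length(snp_order))
      fw_stop("integrity", "annotation matrix rows do not match the SNP list")
    A <- annotations
    if (is.null(colnames(A))) colnames(A) <- paste0("annot_", seq_len(ncol(A)))
    return(A)
  }
  idx <- match(snp_order, annotations$snp)
  if (anyNA(idx))
    fw_stop("integrity", paste0("annotation table is missing SNP ",
                                snp_order[which(is.na(idx))[1]]))
  as.matrix(annotations[idx, setdiff(names(annotations),
                                     c("snp", "chr", "bp")), drop = FALSE])
}

#' Simulate a cis-eQTL expression reference panel
#'
#' The panel's SNPs are partitioned into contiguous cis windows, one per
#' gene. Each gene receives `causal_per_gene` causal SNPs drawn uniformly
#' from its window; expression is the causal genetic score rescaled to
#' variance `cis_h2` plus independent Gaussian noise of variance
#' 1 - `cis_h2`.
#'
#' @param panel a `genotype_panel`
#' @param n_genes number of genes (cis windows)
#' @param causal_per_gene causal SNPs per gene
#' @param cis_h2 cis heritability of expression in [0, 1)
#' @param seed integer seed
#' @return object of class `eqtl_panel`: list with `expr` (individuals x
#'   genes), `genes` (list per gene: id, SNP window indices, causal indices,
#'   effect sizes) and `truth` (cis_h2, causal IDs per gene)
#' @export
simulate_eqtl_panel <- function(panel, n_genes, causal_per_gene = 1,
                                cis_h2 = 0.2, seed = 1L) {
  if (cis_h2 < 0 || cis_h2 >= 1) fw_stop("argument", "cis_h2 must be in [0, 1)")
  m <- ncol(panel$X); n <- nrow(panel$X)
  win_size <- floor(m / n_genes)
  if (win_size < max(causal_per_gene, 2))
    fw_stop("argument", "cis windows too small for causal_per_gene")
  set.seed(seed)
  Xs <- standardize_genotypes(panel$X)
  expr <- matrix(0, n, n_genes)
  genes <- vector("list", n_genes)
  for (g in seq_len(n_genes)) {
    window <- ((g - 1) * win_size + 1):(g * win_size)
    causal <- sort(sample(window, causal_per_gene))
    beta <- stats::rnorm(causal_per_gene)
    gs <- drop(Xs[, causal, drop = FALSE] %*% beta)
    if (cis_h2 > 0 && stats::sd(gs) > 0) {
      sc <- sqrt(cis_h2) / stats::sd(gs)
      gs <- gs * sc
      beta <- beta * sc
    } else {
      gs <- rep(0, n); beta <- rep(0, causal_per_gene)
    }
    expr[, g] <- gs + stats::rnorm(n, 0, sqrt(1 - cis_h2))
    genes[[g]] <- list(id = paste0("gene_", g), window = window,
                       causal = causal, beta = beta)
  }
  colnames(expr) <- vapply(genes, `[[`, "", "id")
  structure(list(expr = expr, genes = genes, panel = panel,
                 truth = list(cis_h2 = cis_h2,
                              causal = lapply(genes, `[[`, "causal")),
                 seed = seed),
            class = "eqtl_panel")
}

#' Simulate a rare-variant case/control cohort
#'
#' Individuals receive rare alternate alleles per gene from independent
#' binomial draws at each site; case status follows a logistic model with
#' log(per-gene odds ratio) per qualifying-variant burden unit plus
#' covariate effects. A prospective pool is simulated and then sampled down
#' to the requested arm sizes (the odds ratio is invariant under
#' case/control sampling). Variant records carry simulated consequence
#' labels and exchangeable per-algorithm deleteriousness calls, so the
#' burden stage's classification and masking can run unchanged.
#'
#' @param n_cases,n_controls arm sizes
#' @param n_genes number of genes
#' @param per_gene_or odds ratio per burden unit, recycled over genes
#' @param variant_maf_spec list with `n_variants` (per gene) and `maf_range`
#'   (both bounds < 0.01)
#' @param covariate_spec data.frame with columns `name`, `type`
#'   ("binary"/"normal") and `effect` (log-odds per unit); default is sex
#'   plus 20 principal-component scores
#' @param n_algorithms number of deleteriousness prediction algorithms to
#'   simulate flags for
#' @param baseline_logit intercept of the liability model (controls the pool
#'   case fraction)
#' @param seed integer seed
#' @return object of class `rare_cohort`: `variants` (incl. gene, transcript,
#'   consequence, gnomad_af and algorithm flag columns), `geno`
#'   (individuals x variants dosage), `pheno` (iid, case, covariates) and
#'   `truth` (per-gene odds ratios)
#' @export
simulate_rare_cohort <- function(n_cases, n_controls, n_genes = 1,
                                 per_gene_or = 1,
                                 variant_maf_spec = list(n_variants = 20,
                                                         maf_range = c(5e-4, 5e-3)),
                                 covariate_spec = NULL,
                                 n_algorithms = 7L,
                                 baseline_logit = -0.5,
                                 seed = 1L) {
  if (any(per_gene_or <= 0)) fw_stop("argument", "per_gene_or must be > 0")
  if (variant_maf_spec$maf_range[2] >= 0.01)
    fw_stop("argument", "rare-variant MAFs must be < 0.01")
  or <- rep_len(per_gene_or, n_genes)
  if (is.null(covariate_spec)) {
    covariate_spec <- data.frame(
      name = c("sex", paste0("PC", 1:20)),
      type = c("binary", rep("normal", 20)),
      effect = c(0.2, rep(0, 20)),
      stringsAsFactors = FALSE)
  }
  set.seed(seed)
  nv <- variant_maf_spec$n_variants
  maf <- stats::runif(n_genes * nv, variant_maf_spec$maf_range[1],
                      variant_maf_spec$maf_range[2])
  gene_of <- rep(seq_len(n_genes), each = nv)
  # carrier-count feasibility warning (power, not validity)
  exp_carriers <- min(n_cases, n_controls) *
    (1 - exp(sum(log(1 - 2 * maf[gene_of == 1]))))
  if (exp_carriers < 1)
    warning("expected carrier count < 1 in an arm; burden power will be ~0")

  # consequence labels drawn up front: only functional (non-synonymous)
  # sites are causal in the liability model, mirroring what a qualifying-
  # variant mask will count downstream
  cons_pool <- c("frameshift_variant", "stop_gained", "splice_site_variant",
                 "missense_variant", "missense_variant", "missense_variant",
                 "missense_variant", "synonymous_variant")
  consequence <- sample(cons_pool, length(maf), replace = TRUE)
  causal_site <- consequence != "synonymous_variant"

  n_pool <- ceiling(2.5 * (n_cases + n_controls))
  pool_geno <- NULL; pool_cov <- NULL; pool_case <- NULL
  draw_pool <- function(np) {
    G <- matrix(stats::rbinom(np * length(maf), 2, rep(maf, each = np)),
                np, length(maf))
    covs <- sapply(seq_len(nrow(covariate_spec)), function(k) {
      if (covariate_spec$type[k] == "binary") stats::rbinom(np, 1, 0.5)
      else stats::rnorm(np)
    })
    colnames(covs) <- covariate_spec$name
    burden <- sapply(seq_len(n_genes), function(g)
      rowSums(G[, gene_of == g & causal_site, drop = FALSE] > 0))
    lp <- baseline_logit + drop(burden %*% log(or)) +
      drop(covs %*% covariate_spec$effect)
    case <- stats::rbinom(np, 1, stats::plogis(lp))
    list(G = G, covs = covs, case = case)
  }
  for (attempt in 1:5) {
    p <- draw_pool(n_pool)
    pool_geno <- rbind(pool_geno, p$G)
    pool_cov <- rbind(pool_cov, p$covs)
    pool_case <- c(pool_case, p$case)
    if (sum(pool_case == 1) >= n_cases && sum(pool_case == 0) >= n_controls)
      break
  }
  if (sum(pool_case == 1) < n_cases || sum(pool_case == 0) < n_controls)
    fw_stop("argument", "could not assemble the requested arms; adjust baseline_logit")
  take <- c(which(pool_case == 1)[seq_len(n_cases)],
            which(pool_case == 0)[seq_len(n_controls)])
  geno <- pool_geno[take, , drop = FALSE]
  covs <- pool_cov[take, , drop = FALSE]
  case <- pool_case[take]

  # exchangeable per-algorithm deleteriousness calls (the burden stage
  # consumes flags, never raw scores)
  flags <- matrix(1L, length(maf), n_algorithms)
  mis <- consequence == "missense_variant"
  # ~70% of missense unanimously deleterious, the rest carry >=1 benign call
  unanimous <- mis & stats::runif(length(maf)) < 0.7
  for (i in which(mis & !unanimous))
    flags[i, sample(n_algorithms, sample(1:2, 1))] <- 0L
  colnames(flags) <- paste0("alg", seq_len(n_algorithms))
  variants <- data.frame(
    chr = "22", pos = 45500000L + seq_along(maf) * 50L,
    id = paste0("var_", seq_along(maf)), ref = "C", alt = "T",
    gene = paste0("gene_", gene_of),
    transcript = paste0("ENST_", gene_of),
    maf = maf, gnomad_af = maf, consequence = consequence,
    stringsAsFactors = FALSE)
  variants <- cbind(variants, as.data.frame(flags))
  rownames(geno) <- sprintf("ind_%05d", seq_len(nrow(geno)))
  pheno <- data.frame(iid = rownames(geno), case = case, covs,
                      stringsAsFactors = FALSE)
  structure(list(variants = variants, geno = geno, pheno = pheno,
                 truth = list(per_gene_or = or, gene_of = gene_of,
                              causal_site = causal_site,
                              covariate_spec = covariate_spec),
                 seed = seed),
            class = "rare_cohort")
}
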