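# Transcriptome-wide association: cis-heritability screen, expression-weight
# fitting, summary-based association, two-stage meta-analysis with weighted
# Stouffer combination, multiple-testing control, and gene-level
# fine-mapping posterior inclusion probabilities.

# resolve a gene argument (index or id) against an eqtl_panel
resolve_gene <- function(eqtl, gene) {
  if (is.character(gene)) {
    g <- match(gene, colnames(eqtl$expr))
    if (is.na(g)) fw_stop("argument", paste0("unknown gene: ", gene))
    g
  } else as.integer(gene)
}

#' Cis heritability of an expression trait
#'
#' Haseman-Elston regression of pairwise expression products on the
#' genotype-relatedness entries of the cis window: with standardized
#' expression y and cis relatedness A_ij, the slope of y_i y_j on A_ij over
#' all i < j pairs estimates the cis heritability. The p-value comes from a
#' permutation of expression labels (one-sided: how often a permuted slope
#' reaches the observed one).
#'
#' @param eqtl an `eqtl_panel` from [simulate_eqtl_panel()]
#' @param gene gene index or id
#' @param n_perm permutations for the p-value (default 200)
#' @param seed seed for the permutation draw
#' @return list with `h2`, `p`, `n`, `n_snps`
#' @export
estimate_cis_h2 <- function(eqtl, gene, n_perm = 200L, seed = 1L) {
  g <- resolve_gene(eqtl, gene)
  window <- eqtl$genes[[g]]$window
  n <- nrow(eqtl$expr)
  if (n < 50) fw_stop("argument", "need at least 50 individuals")
  if (length(window) < 2) fw_stop("argument", "need at least 2 cis SNPs")
  y <- eqtl$expr[, g]
  if (stats::sd(y) == 0) fw_stop("numeric", "constant expression")
  y <- drop(scale(y))
  Xs <- standardize_genotypes(eqtl$panel$X[, window, drop = FALSE])
  A <- tcrossprod(Xs) / length(window)
  dA <- diag(A)
  # off-diagonal sums; each unordered pair counted once
  S2 <- (sum(A^2) - sum(dA^2)) / 2
  he_slope <- function(yy) ((drop(crossprod(yy, A %*% yy)) -
                               sum(dA * yy^2)) / 2) / S2
  h2 <- he_slope(y)
  if (n_perm > 0) {
    set.seed(seed)
    hits <- 0L
    for (b in seq_len(n_perm))
      if (he_slope(sample(y)) >= h2) hits <- hits + 1L
    pval <- (hits + 1) / (n_perm + 1)
  } else pval <- NA_real_   # n_perm = 0 skips the screen p-value
  list(h2 = h2, p = pval, n = n, n_snps = length(window))
}

#' Fit cis expression-prediction weights
#'
#' Two desk-scale members of the usual predictive-model menu:
#' `top_eqtl` puts weight 1 on the cis SNP with the largest marginal
#' chi-square and 0 elsewhere; `ridge` solves
#' (X'X + lambda I)^-1 X'y on standardized genotypes with lambda chosen by
#' 5-fold cross-validation over a fixed grid. With fewer than 25 individuals
#' cross-validation is degenerate and the fit falls back to `top_eqtl` with
#' a warning.
#'
#' @param eqtl an `eqtl_panel`
#' @param gene gene index or id
#' @param method "top_eqtl" or "ridge"
#' @param lambda_grid ridge penalty grid for cross-validation
#' @param hsq,hsq_p optional cis-h2 screen results to record
#' @param seed seed for the CV fold assignment
#' @return object of class `weight_set`: gene, tissue, `snps`, `w`, method,
#'   hsq, hsq_p
#' @export
fit_weights <- function(eqtl, gene, method = c("top_eqtl", "ridge"),
                        lambda_grid = c(0.1, 0.3, 1, 3, 10, 30, 100),
                        hsq = NA_real_, hsq_p = NA_real_, seed = 1L) {
  method <- match.arg(method)
  g <- resolve_gene(eqtl, gene)
  window <- eqtl$genes[[g]]$window
  y <- drop(scale(eqtl$expr[, g]))
  Xs <- standardize_genotypes(eqtl$panel$X[, window, drop = FALSE])
  n <- nrow(Xs); p <- ncol(Xs)
  if (method == "ridge" && n < 25) {
    warning("n < 25: cross-validation degenerate, falling back to top_eqtl")
    method <- "top_eqtl"
  }
  if (method == "top_eqtl") {
    chi2 <- drop(crossprod(Xs, y))^2 / n
    w <- numeric(p)
    w[which.max(chi2)] <- 1
  } else {
    set.seed(seed)
    folds <- sample(rep_len(1:5, n))
    cv_err <- vapply(lambda_grid, function(lam) {
      err <- 0
      for (f in 1:5) {
        tr <- folds != f
        XtX <- crossprod(Xs[tr, , drop = FALSE])
        b <- solve(XtX + diag(lam, p),
                   crossprod(Xs[tr, , drop = FALSE], y[tr]))
        err <- err + sum((y[!tr] - Xs[!tr, , drop = FALSE] %*% b)^2)
      }
      err
    }, numeric(1))
    lam <- lambda_grid[which.min(cv_err)]
    w <- drop(solve(crossprod(Xs) + diag(lam, p), crossprod(Xs, y)))
  }
  if (all(w == 0)) fw_stop("numeric", "all-zero weight vector")
  structure(list(gene = colnames(eqtl$expr)[g], tissue = "synthetic",
                 snps = eqtl$panel$snps$snp[window], w = w, method = method,
                 hsq = hsq, hsq_p = hsq_p),
            class = "weight_set")
}

#' Summary-based TWAS association
#'
#' Tests the association between the genetic component of expression and the
#' trait: Z = w'z / sqrt(w' R w), where w are the expression weights, z the
#' GWAS Z-scores at the weight SNPs, and R the LD among them. Invariant to
#' positive rescaling of w.
#'
#' @param weights a `weight_set`
#' @param gwas sumstats data.frame covering the weight SNPs
#' @param R LD matrix with dimnames covering the weight SNPs
#' @return list with `z` and two-sided `p`
#' @export
twas_associate <- function(weights, gwas, R) {
  idx <- match(weights$snps, gwas$snp)
  if (anyNA(idx))
    fw_stop("integrity", paste0("weight SNP missing from GWAS: ",
                                weights$snps[which(is.na(idx))[1]]))
  ridx <- match(weights$snps, colnames(R))
  if (anyNA(ridx))
    fw_stop("integrity", "weight SNP missing from the LD matrix")
  z <- gwas$z[idx]
  Rw <- (R[ridx, ridx, drop = FALSE] + t(R[ridx, ridx, drop = FALSE])) / 2
  denom <- drop(crossprod(weights$w, Rw %*% weights$w))
  if (denom <= 0)
    fw_stop("numeric", "non-positive weighted LD quadratic form")
  zt <- sum(weights$w * z) / sqrt(denom)
  list(z = zt, p = 2 * stats::pnorm(-abs(zt)))
}

#' Effective sample size of a case/control stage
#'
#' N_eff = 4 / (1/N_cases + 1/N_controls).
#'
#' @param n_cases,n_controls arm sizes
#' @export
effective_n <- function(n_cases, n_controls) {
  4 / (1 / n_cases + 1 / n_controls)
}

#' Weighted Stouffer meta-analysis of stage Z-scores
#'
#' Combines per-stage TWAS Z-scores with weights proportional to the
#' per-stage effective sample size N_eff = 4/(1/N_cases + 1/N_controls)
#' (default), its square root, or the total sample size:
#' Z = sum_s w_s z_s / sqrt(sum_s w_s^2), with a two-sided normal p.
#' With equal weights this reduces to the unweighted Stouffer formula.
#'
#' @param z per-stage Z-scores (length >= 2)
#' @param n_cases,n_controls per-stage case/control counts
#' @param weight_mode "neff" (default), "sqrt_neff" or "total_n"
#' @return list with `z_combined`, `p_combined`, `weights`
#' @export
stouffer_meta <- function(z, n_cases, n_controls,
                          weight_mode = c("neff", "sqrt_neff", "total_n")) {
  weight_mode <- match.arg(weight_mode)
  if (length(z) < 2) fw_stop("argument", "need at least 2 stages")
  if (length(n_cases) != length(z) || length(n_controls) != length(z))
    fw_stop("argument", "case/control counts required for every stage")
  if (any(!is.finite(z))) fw_stop("argument", "non-finite stage Z")
  neff <- effective_n(n_cases, n_controls)
  w <- switch(weight_mode, neff = neff, sqrt_neff = sqrt(neff),
              total_n = n_cases + n_controls)
  zc <- sum(w * z) / sqrt(sum(w^2))
  list(z_combined = zc, p_combined = 2 * stats::pnorm(-abs(zc)), weights = w)
}

#' Transcriptome-wide multiple-testing flags
#'
#' Bonferroni threshold alpha / (n_genes * n_tissues) over all gene-tissue
#' tests, plus Benjamini-Hochberg FDR over the supplied p-values.
#'
#' @param p p-value vector (one per gene-tissue test)
#' @param n_genes,n_tissues Bonferroni denominators (counts >= 1)
#' @param alpha family-wise level (default 0.05)
#' @param fdr_level BH level (default 0.05)
#' @return data.frame with p, p_BH, sig_BH, sig_bonferroni; the Bonferroni
#'   threshold is attached as attribute "bonferroni_threshold"
#' @export
multiple_testing <- function(p, n_genes, n_tissues = 1L, alpha = 0.05,
                             fdr_level = 0.05) {
  if (n_genes < 1 || n_tissues < 1) fw_stop("argument", "counts must be >= 1")
  thr <- alpha / (n_genes * n_tissues)
  out <- data.frame(p = p, p_BH = stats::p.adjust(p, method = "BH"))
  out$sig_BH <- out$p_BH < fdr_level
  out$sig_bonferroni <- out$p < thr
  attr(out, "bonferroni_threshold") <- thr
  out
}

#' Gene-level fine-mapping posterior inclusion probabilities
#'
#' Applies the configuration-enumeration machinery of [compute_cpp()] at the
#' gene level: TWAS Z-scores play the role of marginal statistics and the
#' predicted-expression correlation matrix plays the role of LD. The null
#' (no causal gene) configuration is always included, so PIPs need not sum
#' to 1. The 90%-credible gene set accumulates genes by descending PIP
#' (normalized over genes) until the target mass is reached.
#'
#' @param z per-gene TWAS Z-scores in a region (<= 15 genes)
#' @param gene_correlation predicted-expression correlation matrix
#' @param prior_causal per-gene causal prior; default 1/(number of genes)
#' @param K maximum causal genes per configuration (default: all, i.e.
#'   exhaustive subset enumeration)
#' @param ncp_scale non-centrality scale of a causal gene effect
#' @param ridge diagonal regularization
#' @param level credible level (default 0.90)
#' @return object of class `gene_pip_result`: `genes`, `pip`,
#'   `in_credible`, `level`, configuration table
#' @export
gene_pip <- function(z, gene_correlation, prior_causal = NULL, K = NULL,
                     ncp_scale = 5.2, ridge = 1e-4, level = 0.90) {
  m <- length(z)
  if (m > 15) fw_stop("size", "exact enumeration is capped at 15 genes")
  if (is.null(K)) K <- m
  if (is.null(prior_causal)) prior_causal <- 1 / m
  enum <- enum_config_posterior(z, gene_correlation, K = K,
                                prior = rep_len(prior_causal, m),
                                ncp_scale = ncp_scale, ridge = ridge)
  pip <- enum$alpha
  ord <- order(-pip)
  share <- cumsum(pip[ord]) / sum(pip)
  n_keep <- which(share >= level - 1e-9)[1]
  if (is.na(n_keep)) n_keep <- m
  theta <- integer(m)
  theta[ord[seq_len(n_keep)]] <- 1L
  genes <- if (!is.null(colnames(gene_correlation))) colnames(gene_correlation)
           else paste0("gene_", seq_len(m))
  structure(list(genes = genes, pip = pip, in_credible = theta,
                 level = level,
                 configs = list(sets = enum$sets, posterior = enum$posterior)),
            class = "gene_pip_result")
}
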