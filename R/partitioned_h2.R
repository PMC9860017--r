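# Stratified LD-score regression: annotation LD scores, the partitioned
# chi-square regression E[chi2_j] = N sum_c tau_c l(j,c) + N b + 1,
# enrichment, tau* standardization and block-jackknife inference.
#
# LD scores use squared correlations r2_jk (with the usual finite-sample
# bias adjustment when estimated from a panel); a strict `squared = FALSE`
# mode summing raw r_jk exists for unit testing only, since the chi-square
# regression is only coherent with r2.

#' Annotation-stratified LD scores
#'
#' Computes l(j, c) = sum_k a_c(k) * r2_jk, the annotation-weighted tagging
#' of SNP j, including the self term k = j. When `x` is a genotype panel the
#' correlations are estimated from it and bias-adjusted with
#' r2_adj = r2 - (1 - r2) / (n - 2).
#'
#' @param x an LD correlation matrix with SNP dimnames, or a
#'   `genotype_panel` to estimate one from
#' @param annotations annotation data.frame (snp/chr/bp + columns) or an
#'   m x C matrix aligned with the SNPs of `x`
#' @param squared use squared correlations (default, the only mode coherent
#'   with the chi-square regression); `FALSE` sums raw correlations
#' @return object of class `ldscore_matrix`: `L` (m x C score matrix),
#'   `M` (per-annotation SNP content, sum of annotation values), `sd`
#'   (per-annotation standard deviation), `snps`
#' @export
ld_scores <- function(x, annotations, squared = TRUE) {
  if (inherits(x, "genotype_panel")) {
    n <- nrow(x$X)
    R <- panel_ld_matrix(x)
    R2 <- R^2
    R2 <- R2 - (1 - R2) / (n - 2)   # finite-sample bias adjustment
    diag(R2) <- 1
    snps <- x$snps$snp
  } else {
    if (nrow(x) != ncol(x)) fw_stop("argument", "LD matrix must be square")
    snps <- colnames(x)
    if (is.null(snps)) snps <- paste0("snp_", seq_len(ncol(x)))
    R2 <- if (squared) x^2 else x
  }
  if (!squared && inherits(x, "genotype_panel"))
    fw_stop("argument", "strict r mode is only available for explicit matrices")
  A <- annotation_matrix(annotations, snps)
  L <- R2 %*% A
  structure(list(L = L, M = colSums(A), sd = apply(A, 2, stats::sd),
                 annotations = A, snps = snps),
            class = "ldscore_matrix")
}

#' Partitioned-heritability regression
#'
#' Weighted least squares of per-SNP chi-square statistics on
#' {N * l(j, c)} with a free intercept, estimating the per-annotation
#' per-SNP heritability coefficients tau_c and the confounding intercept
#' 1 + N b. Default regression weights are the standard LDSC
#' heteroskedasticity/overcounting weights
#' 1 / (l_base * (1 + N * h2bar * l_base / M)^2) computed from a first-pass
#' unweighted fit; `weights_mode = "ols"` gives plain OLS (used by the
#' exactness oracles). Standard errors, Z and one-sided p-values come from a
#' delete-one-block jackknife over contiguous SNP blocks; enrichment is
#' jackknifed alongside for binary annotations.
#'
#' @param sumstats sumstats data.frame (needs `snp`, `z` or `chi2`, `n`)
#' @param ldscores an `ldscore_matrix` from [ld_scores()]
#' @param weights_mode "ldsc" (default) or "ols"
#' @param n_blocks jackknife block count (default 200, capped at the SNP
#'   count)
#' @param base_col index or name of the base annotation column used for the
#'   LDSC weights (default 1)
#' @return object of class `tau_estimate`: data.frame `coef` with columns
#'   annotation, tau, tau_se, tau_z, p_one_sided, tau_star, enrichment,
#'   enrichment_se, M_annot, sd_annot; plus `intercept`, `intercept_se`,
#'   `h2` (= sum_c tau_c M_c) and bookkeeping fields
#' @export
regress_partitioned <- function(sumstats, ldscores,
                                weights_mode = c("ldsc", "ols"),
                                n_blocks = 200L, base_col = 1L) {
  weights_mode <- match.arg(weights_mode)
  idx <- match(sumstats$snp, ldscores$snps)
  if (anyNA(idx))
    fw_stop("integrity", paste0("sumstat SNP absent from LD scores: ",
                                sumstats$snp[which(is.na(idx))[1]]))
  L <- ldscores$L[idx, , drop = FALSE]
  A <- ldscores$annotations[idx, , drop = FALSE]
  chi2 <- if (!is.null(sumstats$chi2)) sumstats$chi2 else sumstats$z^2
  N <- sumstats$n
  m <- length(chi2); C <- ncol(L)
  if (m < C + 1)
    fw_stop("argument", "need at least one more SNP than annotations")
  X <- cbind(L * N, intercept = 1)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[-seq_len(qx$rank)]]
    fw_stop("numeric", paste0("rank-deficient design; collinear annotation(s): ",
                              paste(dropped, collapse = ", ")))
  }
  M_tot <- length(ldscores$snps)
  w <- rep(1, m)
  if (weights_mode == "ldsc") {
    fit0 <- stats::lm.fit(X, chi2)
    tau0 <- fit0$coefficients[seq_len(C)]
    h2bar <- min(max(sum(tau0 * ldscores$M), 1e-9), 1)
    l_base <- pmax(L[, base_col], 1)
    w <- 1 / (l_base * (1 + N * h2bar * l_base / M_tot)^2)
  }

  binary <- apply(A, 2, function(a) all(a %in% c(0, 1)))
  fit_fun <- function(keep) {
    sw <- sqrt(w[keep])
    cf <- stats::lm.fit(X[keep, , drop = FALSE] * sw, chi2[keep] * sw)$coefficients
    tau <- cf[seq_len(C)]
    sig2 <- drop(A %*% tau)          # per-SNP variance under the fitted model
    h2 <- sum(sig2)
    enr <- rep(NA_real_, C)
    for (cc in which(binary)) {
      Mc <- sum(A[, cc])
      if (Mc > 0 && abs(h2) > 1e-300)
        enr[cc] <- (sum(sig2[A[, cc] == 1]) / h2) / (Mc / m)
    }
    c(tau, cf[C + 1L], enr)
  }
  full <- fit_fun(seq_len(m))
  jk <- block_jackknife(fit_fun, n_items = m,
                        n_blocks = min(n_blocks, max(2L, m %/% 2L)),
                        estimate = full)
  tau <- full[seq_len(C)]
  h2 <- sum(tau * ldscores$M)
  sd_annot <- ldscores$sd
  tau_star <- ifelse(sd_annot > 0 & h2 > 0,
                     M_tot * sd_annot / h2 * tau, ifelse(tau == 0, 0, NA))
  coef <- data.frame(
    annotation = colnames(L), tau = tau,
    tau_se = jk$se[seq_len(C)], tau_z = jk$z[seq_len(C)],
    p_one_sided = jk$p[seq_len(C)],
    tau_star = tau_star,
    enrichment = full[(C + 2L):(2L * C + 1L)],
    enrichment_se = jk$se[(C + 2L):(2L * C + 1L)],
    M_annot = ldscores$M, sd_annot = sd_annot,
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(coef = coef, intercept = unname(full[C + 1L]),
                 intercept_se = jk$se[C + 1L], h2 = h2, M = M_tot,
                 n_blocks = jk$n_blocks, weights_mode = weights_mode),
            class = "tau_estimate")
}

#' Standardized per-annotation effect size tau*
#'
#' tau* = (M * sd_annot / h2) * tau: the per-SNP heritability change
#' associated with a one-standard-deviation increase of the annotation,
#' normalized by total SNP heritability so values compare across traits.
#'
#' @param tau per-annotation coefficient(s)
#' @param M reference SNP count
#' @param sd_annot standard deviation of the annotation values (> 0)
#' @param h2 total SNP heritability (> 0)
#' @export
standardize_tau <- function(tau, M, sd_annot, h2) {
  if (any(h2 <= 0)) fw_stop("argument", "h2 must be > 0")
  if (any(sd_annot <= 0)) fw_stop("argument", "sd_annot must be > 0")
  M * sd_annot / h2 * tau
}

#' Delete-one-block jackknife
#'
#' Splits items 1..n into contiguous blocks, evaluates `statistic_fn` on the
#' data with each block deleted, and returns jackknife standard errors
#' SE^2 = (B-1)/B * sum_b (theta_(-b) - mean)^2 per component, with
#' Z = estimate/SE and one-sided upper-tail (default) or two-sided normal
#' p-values.
#'
#' @param statistic_fn function(keep_indices) -> numeric vector
#' @param n_items number of items
#' @param n_blocks number of contiguous blocks (>= 2)
#' @param estimate optional full-data estimate (computed if missing)
#' @param two_sided report two-sided p-values instead of one-sided
#' @return list with `estimate`, `se`, `z`, `p`, `n_blocks`
#' @export
block_jackknife <- function(statistic_fn, n_items, n_blocks = 200L,
                            estimate = NULL, two_sided = FALSE) {
  if (n_blocks < 2L) fw_stop("argument", "need at least 2 jackknife blocks")
  n_blocks <- min(n_blocks, n_items)
  bounds <- floor(seq(0, n_items, length.out = n_blocks + 1L))
  if (is.null(estimate)) estimate <- statistic_fn(seq_len(n_items))
  reps <- matrix(NA_real_, n_blocks, length(estimate))
  for (b in seq_len(n_blocks)) {
    del <- (bounds[b] + 1L):bounds[b + 1L]
    reps[b, ] <- statistic_fn(setdiff(seq_len(n_items), del))
  }
  centre <- colMeans(reps)
  se <- sqrt((n_blocks - 1) / n_blocks *
               colSums(sweep(reps, 2, centre)^2))
  z <- ifelse(se > 0, estimate / se, ifelse(estimate == 0, 0, Inf))
  p <- if (two_sided) 2 * stats::pnorm(-abs(z)) else stats::pnorm(z, lower.tail = FALSE)
  list(estimate = estimate, se = se, z = z, p = p, n_blocks = n_blocks)
}

#' Per-annotation heritability enrichment
#'
#' enrichment_c = (h2_c / h2) / (M_c / M), where h2_c sums the fitted
#' per-SNP variances over the members of a binary annotation. Continuous
#' annotations have no defined SNP share; their effect size is reported as
#' tau* instead, and requesting enrichment for one is an error.
#'
#' @param tau fitted per-annotation coefficients (or a `tau_estimate`)
#' @param annotations the annotation matrix/data.frame the model was fitted
#'   on
#' @param which_annot columns to report (default: all)
#' @return data.frame with annotation, M_annot, h2_share, snp_share,
#'   enrichment
#' @export
enrichment <- function(tau, annotations, which_annot = NULL) {
  if (inherits(tau, "tau_estimate")) tau <- tau$coef$tau
  A <- if (is.matrix(annotations)) annotations else
    as.matrix(annotations[, setdiff(names(annotations), c("snp", "chr", "bp")),
                          drop = FALSE])
  if (is.null(which_annot)) which_annot <- colnames(A)
  bad <- which_annot[!vapply(which_annot, function(cc)
    all(A[, cc] %in% c(0, 1)), logical(1))]
  if (length(bad) > 0)
    fw_stop("argument", paste0("enrichment is defined for binary annotations ",
                               "only; report tau_star for: ",
                               paste(bad, collapse = ", ")))
  sig2 <- drop(A %*% tau)
  h2 <- sum(sig2); m <- nrow(A)
  out <- lapply(which_annot, function(cc) {
    members <- A[, cc] == 1
    data.frame(annotation = cc, M_annot = sum(members),
               h2_share = sum(sig2[members]) / h2,
               snp_share = sum(members) / m,
               enrichment = (sum(sig2[members]) / h2) / (sum(members) / m),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Conditional effect-size model for a focus annotation
#'
#' Fits one joint regression containing the baseline annotations plus a
#' single focus annotation and reports the focus annotation's tau*,
#' jackknife Z and one-sided p. When several focus annotations are given
#' they are fitted one at a time, each conditional on the same baseline
#' (never all foci jointly).
#'
#' @param sumstats sumstats data.frame
#' @param ldscores `ldscore_matrix` containing baseline and focus columns
#' @param focus character vector of focus annotation name(s)
#' @param baseline character vector of baseline annotation names
#' @param ... passed to [regress_partitioned()]
#' @return data.frame with one row per focus annotation: tau, tau_se,
#'   tau_star, z, p_one_sided
#' @export
conditional_model <- function(sumstats, ldscores, focus, baseline, ...) {
  if (any(focus %in% baseline))
    fw_stop("argument", "focus annotation is already in the baseline")
  missing_cols <- setdiff(c(focus, baseline), colnames(ldscores$L))
  if (length(missing_cols) > 0)
    fw_stop("integrity", paste0("unknown annotation(s): ",
                                paste(missing_cols, collapse = ", ")))
  rows <- lapply(focus, function(f) {
    cols <- c(baseline, f)
    sub <- structure(list(L = ldscores$L[, cols, drop = FALSE],
                          M = ldscores$M[cols], sd = ldscores$sd[cols],
                          annotations = ldscores$annotations[, cols, drop = FALSE],
                          snps = ldscores$snps),
                     class = "ldscore_matrix")
    fit <- regress_partitioned(sumstats, sub, ...)
    k <- match(f, fit$coef$annotation)
    data.frame(annotation = f, tau = fit$coef$tau[k],
               tau_se = fit$coef$tau_se[k], tau_star = fit$coef$tau_star[k],
               z = fit$coef$tau_z[k], p_one_sided = fit$coef$p_one_sided[k],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Multiple-testing adjustment for annotation scans
#'
#' Post-processing for a vector of per-annotation p-values: Benjamini-
#' Hochberg FDR flags at the given FDR level and Bonferroni flags at
#' `alpha / n_tests`.
#'
#' @param p p-value vector
#' @param fdr_level BH false-discovery-rate level (default 0.05)
#' @param alpha family-wise level for Bonferroni (default 0.05)
#' @param n_tests Bonferroni denominator (default `length(p)`)
#' @return data.frame with p, p_BH, sig_BH, sig_bonferroni
#' @export
adjust_annotation_p <- function(p, fdr_level = 0.05, alpha = 0.05,
                                n_tests = length(p)) {
  p_bh <- stats::p.adjust(p, method = "BH")
  data.frame(p = p, p_BH = p_bh, sig_BH = p_bh < fdr_level,
             sig_bonferroni = p < alpha / n_tests)
}
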