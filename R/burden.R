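# Rare-variant genic burden association: variant classification, mask
# construction, per-transcript burden with the >= 5-carrier inclusion rule,
# Firth-penalized logistic regression, and inverse-variance-weighted
# cross-cohort meta-analysis.

DISRUPTIVE_TERMS <- c("frameshift_variant", "frame_shift",
                      "splice_site_variant", "splice_acceptor_variant",
                      "splice_donor_variant", "splice_acceptor",
                      "splice_variant", "exon_loss_variant", "stop_gained",
                      "start_lost", "start_loss", "transcription_ablation")
MISSENSE_TERMS <- c("missense_variant", "missense")
KNOWN_TERMS <- c(DISRUPTIVE_TERMS, MISSENSE_TERMS, "synonymous_variant",
                 "structural", "intron_variant", "stop_retained_variant")

#' Classify rare variants into burden classes
#'
#' Assigns each variant to one of \{disruptive, damaging, missense, other\}:
#' disruptive if the consequence is frame-shift, splice-site, exon loss,
#' stop gained, start loss or transcription ablation; otherwise damaging if
#' it is missense and every supplied prediction-algorithm flag calls it
#' deleterious (unanimity over whatever flags are present — the algorithm
#' count is a property of the input); otherwise missense if missense;
#' otherwise other. Unknown consequence terms are classified "other" with a
#' warning, never dropped.
#'
#' @param variants data.frame with a `consequence` column and the
#'   deleteriousness flag columns
#' @param algorithm_cols names of the 0/1 flag columns; default: all columns
#'   starting with "alg"
#' @return `variants` with a `class` column added
#' @export
classify_variants <- function(variants, algorithm_cols = NULL) {
  if (is.null(algorithm_cols))
    algorithm_cols <- grep("^alg", names(variants), value = TRUE)
  cons <- variants$consequence
  unknown <- setdiff(unique(cons), KNOWN_TERMS)
  if (length(unknown) > 0)
    warning("unknown consequence term(s) classified as 'other': ",
            paste(unknown, collapse = ", "))
  cls <- rep("other", length(cons))
  cls[cons %in% MISSENSE_TERMS] <- "missense"
  if (length(algorithm_cols) > 0) {
    flags <- as.matrix(variants[, algorithm_cols, drop = FALSE])
    unanimous <- rowSums(flags == 1) == ncol(flags)
    cls[cls == "missense" & unanimous] <- "damaging"
  }
  cls[cons %in% DISRUPTIVE_TERMS] <- "disruptive"
  variants$class <- cls
  variants
}

#' Burden mask constructor
#'
#' A mask is an allele-frequency threshold (0.01 or 0.005 by convention)
#' plus one of the nested class families: disruptive; disruptive +
#' damaging; disruptive + damaging + missense.
#'
#' @param maf_threshold allele-frequency cutoff
#' @param classes character vector of qualifying classes
#' @param allow_nonstandard permit thresholds other than 0.01/0.005
#' @export
burden_mask <- function(maf_threshold = 0.01,
                        classes = c("disruptive", "damaging", "missense"),
                        allow_nonstandard = FALSE) {
  if (!allow_nonstandard && !maf_threshold %in% c(0.01, 0.005))
    fw_stop("argument", "maf_threshold must be 0.01 or 0.005")
  families <- list(c("disruptive"),
                   c("disruptive", "damaging"),
                   c("disruptive", "damaging", "missense"))
  ok <- any(vapply(families, function(f) setequal(f, classes), logical(1)))
  if (!ok)
    fw_stop("argument", "classes must be one of the nested families")
  structure(list(maf_threshold = maf_threshold, classes = classes),
            class = "burden_mask")
}

#' Per-individual, per-transcript burden counts
#'
#' burden(i, t) is the number of mask-qualifying variant sites in transcript
#' t at which individual i carries at least one alternate allele
#' (site-count convention: homozygotes count once; `mode = "dosage"` sums
#' allele counts instead). Masking uses the external (gnomAD-style) allele
#' frequency when a `gnomad_af` column is present, else the cohort allele
#' frequency. Transcripts with fewer than 5 non-zero-burden individuals are
#' flagged excluded.
#'
#' @param geno individuals x variants dosage matrix
#' @param variants classified variant table (needs `transcript`, `class`
#'   and an AF column)
#' @param mask a `burden_mask`
#' @param mode "site" (default) or "dosage"
#' @param min_carriers inclusion threshold (default 5)
#' @return list with `burden` (individuals x transcripts), `included`
#'   (logical per transcript), `qualifying` (logical per variant), `mask`
#' @export
build_burden <- function(geno, variants, mask, mode = c("site", "dosage"),
                         min_carriers = 5L) {
  mode <- match.arg(mode)
  if (is.null(variants$class))
    fw_stop("argument", "variants must be classified first (classify_variants)")
  af <- if (!is.null(variants$gnomad_af)) variants$gnomad_af
        else colMeans(geno) / 2
  qual <- variants$class %in% mask$classes & af < mask$maf_threshold
  transcripts <- unique(variants$transcript)
  carrier <- if (mode == "site") (geno > 0) * 1L else geno
  burden <- vapply(transcripts, function(t) {
    cols <- which(variants$transcript == t & qual)
    if (length(cols) == 0) numeric(nrow(geno))
    else rowSums(carrier[, cols, drop = FALSE])
  }, numeric(nrow(geno)))
  if (is.null(dim(burden))) burden <- matrix(burden, ncol = length(transcripts))
  colnames(burden) <- transcripts
  rownames(burden) <- rownames(geno)
  included <- colSums(burden > 0) >= min_carriers
  list(burden = burden, included = included, qualifying = qual, mask = mask)
}

# penalized log-likelihood: l(beta) + 0.5 log det X'WX
firth_pll <- function(X, y, beta) {
  eta <- drop(X %*% beta)
  p <- stats::plogis(eta)
  W <- p * (1 - p)
  ll <- sum(y * eta - log1p(exp(eta)))
  XtWX <- crossprod(X * sqrt(W))
  ch <- chol(XtWX)
  ll + sum(log(diag(ch)))
}

# Firth Newton iterations; `fixed` optionally pins coefficients (for
# profile-likelihood confidence limits): a named list idx -> value
firth_fit_core <- function(X, y, beta0 = NULL, fixed_idx = integer(0),
                           fixed_val = numeric(0), max_iter = 100L,
                           tol = 1e-10) {
  k <- ncol(X)
  beta <- if (is.null(beta0)) numeric(k) else beta0
  beta[fixed_idx] <- fixed_val
  free <- setdiff(seq_len(k), fixed_idx)
  pll <- firth_pll(X, y, beta)
  for (iter in seq_len(max_iter)) {
    p <- stats::plogis(drop(X %*% beta))
    W <- p * (1 - p)
    XW <- X * sqrt(W)
    XtWX <- crossprod(XW)
    XtWXinv <- tryCatch(solve(XtWX), error = function(e) NULL)
    if (is.null(XtWXinv))
      fw_stop("numeric", "singular information matrix in Firth fit")
    h <- rowSums((XW %*% XtWXinv) * XW)
    U <- drop(crossprod(X, y - p + h * (0.5 - p)))
    if (length(free) == 0) break
    step <- numeric(k)
    step[free] <- solve(XtWX[free, free, drop = FALSE], U[free])
    if (max(abs(U[free])) < tol) break
    # step-halving on the penalized log-likelihood
    fac <- 1
    repeat {
      cand <- beta + fac * step
      pll_new <- firth_pll(X, y, cand)
      if (pll_new >= pll - 1e-12 || fac < 1e-4) break
      fac <- fac / 2
    }
    if (fac < 1e-4 && pll_new < pll)
      fw_stop("convergence", paste0("Firth step-halving failed at iteration ",
                                    iter, "; max |score| = ",
                                    format(max(abs(U[free])))))
    beta <- beta + fac * step
    pll <- max(pll, pll_new)
  }
  p <- stats::plogis(drop(X %*% beta))
  W <- p * (1 - p)
  XtWX <- crossprod(X * sqrt(W))
  list(beta = beta, pll = firth_pll(X, y, beta),
       vcov = solve(XtWX), iterations = iter,
       converged = iter < max_iter)
}

#' Firth-penalized logistic regression for a genic burden
#'
#' Maximizes the Jeffreys-prior-penalized log-likelihood
#' l(beta) + 1/2 log det I(beta) by Newton iteration with the hat-matrix
#' score correction and step-halving, which guarantees finite estimates
#' even under complete separation. Standard errors come from the penalized
#' information. The confidence interval for the burden coefficient uses the
#' profile penalized likelihood by default (more accurate for sparse
#' tables); `ci = "wald"` selects the Wald interval. Both the penalized
#' likelihood-ratio p-value and the Wald p-value are reported.
#'
#' @param burden per-individual burden counts
#' @param case_status 0/1 outcome
#' @param covariates optional numeric matrix/data.frame of covariates
#' @param ci "profile" (default), "wald", or "none" to skip interval
#'   construction (fast path for large scans)
#' @param level confidence level (default 0.95)
#' @param max_iter Newton iteration cap
#' @return object of class `burden_result`: `beta`, `se`, `or`, `ci_low`,
#'   `ci_high`, `p` (penalized LRT), `p_wald`, carrier counts per arm,
#'   convergence diagnostics
#' @export
firth_logistic <- function(burden, case_status, covariates = NULL,
                           ci = c("profile", "wald", "none"), level = 0.95,
                           max_iter = 100L) {
  ci <- match.arg(ci)
  y <- as.numeric(case_status)
  if (sum(y == 1) < 1 || sum(y == 0) < 1)
    fw_stop("argument", "need at least one case and one control")
  X <- cbind(intercept = 1, burden = as.numeric(burden))
  if (!is.null(covariates)) {
    Cm <- as.matrix(covariates)
    keep <- apply(Cm, 2, function(v) stats::sd(v) > 0)
    X <- cbind(X, Cm[, keep, drop = FALSE])
  }
  if (qr(X)$rank < ncol(X))
    fw_stop("numeric", "design matrix is rank deficient")
  fit <- firth_fit_core(X, y, max_iter = max_iter)
  j <- 2L  # burden coefficient
  beta <- fit$beta[j]
  se <- sqrt(fit$vcov[j, j])
  zcrit <- stats::qnorm(1 - (1 - level) / 2)

  # penalized likelihood-ratio test: burden coefficient pinned at 0
  fit0 <- firth_fit_core(X, y, beta0 = fit$beta, fixed_idx = j,
                         fixed_val = 0, max_iter = max_iter)
  lrt <- max(0, 2 * (fit$pll - fit0$pll))
  p_lrt <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  p_wald <- 2 * stats::pnorm(-abs(beta / se))

  if (ci == "none") {
    ci_low <- NA_real_
    ci_high <- NA_real_
  } else if (ci == "wald") {
    ci_low <- beta - zcrit * se
    ci_high <- beta + zcrit * se
  } else {
    target <- stats::qchisq(level, 1)
    prof_dev <- function(b) {
      pf <- firth_fit_core(X, y, beta0 = fit$beta, fixed_idx = j,
                           fixed_val = b, max_iter = max_iter)
      2 * (fit$pll - pf$pll) - target
    }
    find_limit <- function(dir) {
      for (k in c(0.5, 1, 2, 4, 8, 16, 32)) {
        b <- beta + dir * k * se
        if (prof_dev(b) > 0)
          return(stats::uniroot(prof_dev, sort(c(beta, b)),
                                tol = 1e-6)$root)
      }
      beta + dir * 32 * se  # profile flat; report the bracket edge
    }
    ci_low <- find_limit(-1)
    ci_high <- find_limit(1)
  }
  carriers <- as.numeric(burden) > 0
  structure(list(beta = beta, se = se, or = exp(beta),
                 ci_low = exp(ci_low), ci_high = exp(ci_high),
                 p = p_lrt, p_wald = p_wald,
                 n_carriers_case = sum(carriers & y == 1),
                 n_carriers_control = sum(carriers & y == 0),
                 converged = fit$converged, iterations = fit$iterations,
                 ci_type = ci, coefficients = fit$beta),
            class = "burden_result")
}

#' Per-transcript burden scan of a cohort
#'
#' Runs classification, mask construction, burden building and Firth
#' regression over every transcript of a rare-variant cohort, honouring the
#' >= 5-carrier inclusion rule.
#'
#' @param cohort a `rare_cohort` (or list with `geno`, `variants`, `pheno`)
#' @param mask a `burden_mask`
#' @param covariate_cols phenotype columns used as covariates (default all
#'   except iid/case)
#' @param ... passed to [firth_logistic()]
#' @return data.frame: transcript, included, n_carriers_case,
#'   n_carriers_control, beta, se, or, ci_low, ci_high, p, p_wald
#' @export
burden_scan <- function(cohort, mask,
                        covariate_cols = NULL, ...) {
  variants <- cohort$variants
  if (is.null(variants$class)) variants <- classify_variants(variants)
  bb <- build_burden(cohort$geno, variants, mask)
  if (is.null(covariate_cols))
    covariate_cols <- setdiff(names(cohort$pheno), c("iid", "case"))
  covs <- if (length(covariate_cols) > 0)
    as.matrix(cohort$pheno[, covariate_cols, drop = FALSE]) else NULL
  rows <- lapply(colnames(bb$burden), function(t) {
    base <- data.frame(transcript = t, included = bb$included[[t]],
                       stringsAsFactors = FALSE)
    if (!bb$included[[t]])
      return(cbind(base, n_carriers_case = NA, n_carriers_control = NA,
                   beta = NA, se = NA, or = NA, ci_low = NA, ci_high = NA,
                   p = NA, p_wald = NA))
    r <- firth_logistic(bb$burden[, t], cohort$pheno$case, covs, ...)
    cbind(base, n_carriers_case = r$n_carriers_case,
          n_carriers_control = r$n_carriers_control,
          beta = r$beta, se = r$se, or = r$or, ci_low = r$ci_low,
          ci_high = r$ci_high, p = r$p, p_wald = r$p_wald)
  })
  do.call(rbind, rows)
}

#' Inverse-variance-weighted meta-analysis of log odds ratios
#'
#' beta_meta = sum(beta_j / SE_j^2) / sum(1 / SE_j^2),
#' SE_meta = (sum 1/SE_j^2)^(-1/2); OR, 95% CI and a two-sided normal p
#' follow. With a single cohort the estimate passes through with a warning.
#'
#' @param beta per-cohort log odds ratios
#' @param se per-cohort standard errors (> 0)
#' @param level confidence level (default 0.95)
#' @return list with `beta`, `se`, `or`, `ci_low`, `ci_high`, `p`
#' @export
ivw_meta <- function(beta, se, level = 0.95) {
  if (length(beta) != length(se) || length(beta) < 1)
    fw_stop("argument", "beta and se must be non-empty and equal length")
  if (any(!is.finite(se)) || any(se <= 0))
    fw_stop("argument", "all standard errors must be finite and > 0")
  if (length(beta) == 1) warning("single cohort: IVW meta is a passthrough")
  w <- 1 / se^2
  b <- sum(w * beta) / sum(w)
  s <- sqrt(1 / sum(w))
  zcrit <- stats::qnorm(1 - (1 - level) / 2)
  list(beta = b, se = s, or = exp(b),
       ci_low = exp(b - zcrit * s), ci_high = exp(b + zcrit * s),
       p = 2 * stats::pnorm(-abs(b / s)))
}

#' Recover (log OR, SE) from a printed OR and confidence interval
#'
#' For results reported only as OR with a symmetric-on-the-log-scale
#' confidence interval: beta = log(OR) and
#' SE = log(ci_high / ci_low) / (2 z), with z the normal quantile of the
#' interval's level.
#'
#' @param or odds ratio
#' @param ci_low,ci_high confidence bounds
#' @param level level of the printed interval (default 0.95)
#' @return list with `beta`, `se`
#' @export
logor_from_ci <- function(or, ci_low, ci_high, level = 0.95) {
  zcrit <- stats::qnorm(1 - (1 - level) / 2)
  list(beta = log(or), se = log(ci_high / ci_low) / (2 * zcrit))
}

#' Genome-wide Q-Q summary and inflation factor
#'
#' Sorted observed -log10 p against expected -log10((rank - 0.5)/n), plus
#' the genomic inflation factor lambda = median observed chi-square /
#' median expected chi-square.
#'
#' @param p p-values (>= 10)
#' @return list with `table` (expected, observed, rank) and `lambda`
#' @export
genomewide_qq <- function(p) {
  if (length(p) < 10) fw_stop("argument", "need at least 10 p-values")
  n <- length(p)
  obs <- sort(p)
  expd <- (seq_len(n) - 0.5) / n
  lambda <- stats::median(stats::qchisq(p, 1, lower.tail = FALSE)) /
    stats::qchisq(0.5, 1)
  list(table = data.frame(rank = seq_len(n),
                          expected = -log10(expd),
                          observed = -log10(obs)),
       lambda = lambda)
}
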