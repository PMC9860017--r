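# Variant classification, masks, burden construction, Firth regression,
# IVW meta-analysis, Q-Q summaries.

test_that("variant classes follow the consequence/unanimity rules", {
  v <- data.frame(
    consequence = c("frameshift_variant", "missense_variant",
                    "missense_variant", "synonymous_variant", "weird_term"),
    alg1 = c(1, 1, 1, 1, 1), alg2 = c(0, 1, 0, 1, 1),
    stringsAsFactors = FALSE)
  expect_warning(cls <- classify_variants(v)$class, "weird_term")
  expect_equal(cls, c("disruptive", "damaging", "missense", "other", "other"))
  # unanimity is over whatever flags are supplied
  expect_equal(suppressWarnings(
    classify_variants(v, algorithm_cols = "alg1"))$class[3], "damaging")
})

test_that("burden masks are restricted to the nested families", {
  expect_error(burden_mask(0.02), class = "finewas_argument_error")
  expect_error(burden_mask(0.01, c("damaging", "missense")),
               class = "finewas_argument_error")
  m <- burden_mask(0.005, c("disruptive", "damaging"))
  expect_equal(m$maf_threshold, 0.005)
})

burden_fixture <- function() {
  variants <- data.frame(
    chr = "22", pos = 1:6, id = paste0("v", 1:6), ref = "C", alt = "T",
    transcript = c("t1", "t1", "t1", "t2", "t2", "t2"),
    gnomad_af = c(0.001, 0.001, 0.02, 0.004, 0.007, 0.001),
    consequence = c("frameshift_variant", "missense_variant",
                    "missense_variant", "stop_gained", "missense_variant",
                    "synonymous_variant"),
    alg1 = c(1, 1, 1, 1, 0, 1), alg2 = c(1, 1, 1, 1, 1, 1),
    stringsAsFactors = FALSE)
  geno <- rbind(c(1, 1, 0, 0, 0, 0),   # 2 qualifying sites in t1
                c(2, 0, 1, 0, 0, 0),   # homozygote counts once
                c(0, 0, 0, 1, 1, 2),
                c(0, 0, 0, 0, 0, 0))
  rownames(geno) <- paste0("i", 1:4)
  list(variants = classify_variants(variants), geno = geno)
}

test_that("burden counts qualifying sites and applies the 5-carrier rule", {
  fx <- burden_fixture()
  mask <- burden_mask(0.01, c("disruptive", "damaging", "missense"))
  bb <- build_burden(fx$geno, fx$variants, mask)
  # v3 fails the MAF filter, v6 is synonymous
  expect_equal(unname(bb$burden[, "t1"]), c(2, 1, 0, 0))
  expect_equal(unname(bb$burden[, "t2"]), c(0, 0, 2, 0))
  expect_false(any(bb$included))   # < 5 carriers everywhere
  # dosage mode counts the homozygote twice
  bd <- build_burden(fx$geno, fx$variants, mask, mode = "dosage")
  expect_equal(unname(bd$burden[, "t1"]), c(2, 2, 0, 0))
})

test_that("burden matches a per-individual loop oracle and masks are nested", {
  co <- simulate_rare_cohort(150, 150, n_genes = 3, per_gene_or = 1,
                             variant_maf_spec = list(n_variants = 12,
                                                     maf_range = c(1e-3, 9e-3)),
                             seed = 91)
  v <- classify_variants(co$variants)
  masks <- list(burden_mask(0.01, "disruptive"),
                burden_mask(0.01, c("disruptive", "damaging")),
                burden_mask(0.01, c("disruptive", "damaging", "missense")),
                burden_mask(0.005, c("disruptive", "damaging", "missense")))
  prev <- NULL
  for (mask in masks[1:3]) {
    bb <- build_burden(co$geno, v, mask)
    # loop oracle on a subset of individuals
    for (i in seq(1, 300, by = 37)) for (t in colnames(bb$burden)) {
      cnt <- 0
      for (k in seq_len(nrow(v)))
        if (v$transcript[k] == t && v$class[k] %in% mask$classes &&
            v$gnomad_af[k] < mask$maf_threshold && co$geno[i, k] > 0)
          cnt <- cnt + 1
      expect_equal(unname(bb$burden[i, t]), cnt)
    }
    if (!is.null(prev)) expect_true(all(bb$burden >= prev))
    prev <- bb$burden
  }
  # tightening the MAF never increases burden
  b3 <- build_burden(co$geno, v, masks[[3]])$burden
  b4 <- build_burden(co$geno, v, masks[[4]])$burden
  expect_true(all(b4 <= b3))
})

test_that("Firth estimate matches a penalized-likelihood grid search on a 2x2", {
  # carriers: 5 cases + 2 controls; non-carriers: 1 case + 10 controls
  y <- c(rep(1, 5), rep(0, 2), rep(1, 1), rep(0, 10))
  x <- c(rep(1, 7), rep(0, 11))
  fit <- firth_logistic(x, y)
  # independent fine-grid maximization of l(b0, b1) + 0.5 log det I
  pll <- function(b0, b1) {
    eta <- b0 + b1 * x
    p <- plogis(eta)
    X <- cbind(1, x)
    sum(y * eta - log1p(exp(eta))) +
      0.5 * as.numeric(determinant(crossprod(X * sqrt(p * (1 - p))))$modulus)
  }
  grid_b1 <- seq(1, 4.5, by = 1e-3)
  prof <- vapply(grid_b1, function(b1)
    optimize(function(b0) pll(b0, b1), c(-5, 1), maximum = TRUE,
             tol = 1e-8)$objective, numeric(1))
  b1_grid <- grid_b1[which.max(prof)]
  expect_equal(fit$beta, b1_grid, tolerance = 2e-3)
  # for the 2x2 table this coincides with the add-half estimate
  expect_equal(fit$or, (5.5 * 10.5) / (1.5 * 2.5), tolerance = 1e-3)
  expect_lt(fit$ci_low, fit$or)
  expect_gt(fit$ci_high, fit$or)
  expect_lt(fit$p, 0.05)
})

test_that("Firth returns finite estimates under complete separation", {
  y <- c(rep(1, 6), rep(0, 6))
  x <- c(rep(1, 6), rep(0, 6))
  fit <- firth_logistic(x, y)
  expect_true(is.finite(fit$beta))
  expect_true(is.finite(fit$se))
  expect_true(is.finite(fit$ci_low) && is.finite(fit$ci_high))
  expect_true(fit$converged)
  # and from the generator's separation-style fixture
  co <- simulate_rare_cohort(80, 80, n_genes = 1, per_gene_or = 50,
                             variant_maf_spec = list(n_variants = 10,
                                                     maf_range = c(2e-3, 8e-3)),
                             covariate_spec = data.frame(
                               name = "sex", type = "binary", effect = 0),
                             baseline_logit = -2, seed = 93)
  b <- build_burden(co$geno, classify_variants(co$variants),
                    burden_mask(0.01, c("disruptive", "damaging", "missense")))
  fit2 <- firth_logistic(b$burden[, 1], co$pheno$case, ci = "wald")
  expect_true(is.finite(fit2$beta) && is.finite(fit2$se))
})

test_that("Firth near-null table estimates OR close to 1", {
  set.seed(95)
  x <- rbinom(2000, 1, 0.1)
  y <- rbinom(2000, 1, 0.5)
  fit <- firth_logistic(x, y, ci = "wald")
  expect_lt(abs(fit$beta), 3 * fit$se)
  expect_gt(fit$p, 0.001)
})

test_that("burden_scan respects inclusion flags and covariates", {
  co <- simulate_rare_cohort(200, 200, n_genes = 2, per_gene_or = c(4, 1),
                             variant_maf_spec = list(n_variants = 15,
                                                     maf_range = c(1e-3, 9e-3)),
                             covariate_spec = data.frame(
                               name = c("sex", "PC1"), type = c("binary", "normal"),
                               effect = c(0.2, 0)),
                             seed = 96)
  res <- burden_scan(co, burden_mask(0.01, c("disruptive", "damaging",
                                             "missense")), ci = "none")
  expect_equal(nrow(res), 2L)
  expect_true(all(res$included))
  expect_gt(res$beta[res$transcript == "ENST_1"], 0)
})

test_that("IVW meta-analysis: symmetry, dominance, loop oracle", {
  m <- ivw_meta(c(0.7, 0.7), c(0.2, 0.2))
  expect_equal(m$beta, 0.7)
  expect_equal(m$se, 0.2 / sqrt(2))
  expect_equal(m$or, exp(0.7))
  # permutation invariance and a scalar-loop oracle
  set.seed(97)
  b <- rnorm(5); s <- runif(5, 0.1, 1)
  m1 <- ivw_meta(b, s)
  perm <- sample(5)
  expect_equal(ivw_meta(b[perm], s[perm])$beta, m1$beta, tolerance = 1e-12)
  num <- 0; den <- 0
  for (j in 1:5) { num <- num + b[j] / s[j]^2; den <- den + 1 / s[j]^2 }
  expect_equal(m1$beta, num / den, tolerance = 1e-12)
  expect_equal(m1$se, 1 / sqrt(den), tolerance = 1e-12)
  # a vanishing SE dominates the combination
  m2 <- ivw_meta(c(0.3, 5), c(1e-6, 1))
  expect_equal(m2$beta, 0.3, tolerance = 1e-6)
  expect_warning(ivw_meta(0.5, 0.2), "single cohort")
  expect_error(ivw_meta(c(1, 2), c(0.1, -1)), class = "finewas_argument_error")
})

test_that("Q-Q summary is calibrated for uniform p and tolerates degeneracy", {
  set.seed(98)
  qq <- genomewide_qq(runif(5000))
  expect_lt(abs(qq$lambda - 1), 0.08)
  expect_equal(nrow(qq$table), 5000L)
  qq2 <- genomewide_qq(rep(0.5, 20))
  expect_true(is.finite(qq2$lambda))
  expect_error(genomewide_qq(runif(5)), class = "finewas_argument_error")
})
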