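# Cis-heritability screen, weight fitting, summary-based association,
# Stouffer meta-analysis, multiple testing, gene-level PIPs.

twas_eqtl_fixture <- function() {
  get_fixture("twas_eqtl", function() {
    p <- simulate_ld_panel(600, 120, block_size = c(1, 6), rho = 0.4,
                           seed = 61)
    simulate_eqtl_panel(p, n_genes = 6, causal_per_gene = 1, cis_h2 = 0.5,
                        seed = 62)
  })
}

test_that("perfect heritability: expression equal to one standardized SNP", {
  eq <- twas_eqtl_fixture()
  eq2 <- eq
  w <- eq$genes[[1]]$window
  xs <- scale(eq$panel$X[, w[3]])
  eq2$expr[, 1] <- xs
  est <- estimate_cis_h2(eq2, 1, n_perm = 0)
  # independent oracle: regression of off-diagonal products on relatedness
  Xs <- scale(eq$panel$X[, w])
  A <- tcrossprod(Xs) / length(w)
  y <- drop(scale(eq2$expr[, 1]))
  ut <- upper.tri(A)
  slope <- sum(A[ut] * (y %o% y)[ut]) / sum(A[ut]^2)
  expect_equal(est$h2, slope, tolerance = 1e-10)
  expect_gt(est$h2, 0.8)
})

test_that("null genes are excluded by the permutation screen", {
  p <- simulate_ld_panel(300, 200, block_size = c(1, 4), rho = 0.3, seed = 63)
  eq <- simulate_eqtl_panel(p, n_genes = 25, causal_per_gene = 1,
                            cis_h2 = 0, seed = 64)
  pvals <- vapply(1:25, function(g)
    estimate_cis_h2(eq, g, n_perm = 199, seed = g)$p, numeric(1))
  expect_gte(mean(pvals >= 0.01), 0.9)
})

test_that("degenerate expression raises a numeric error", {
  eq <- twas_eqtl_fixture()
  eq$expr[, 2] <- 1
  expect_error(estimate_cis_h2(eq, 2, n_perm = 0),
               class = "finewas_numeric_error")
})

test_that("top-eQTL weights select the true causal SNP under strong signal", {
  p <- simulate_ld_panel(800, 200, block_size = c(1, 4), rho = 0.3, seed = 65)
  eq <- simulate_eqtl_panel(p, n_genes = 20, causal_per_gene = 1,
                            cis_h2 = 0.8, seed = 66)
  hits <- vapply(1:20, function(g) {
    ws <- fit_weights(eq, g, method = "top_eqtl")
    sel <- eq$genes[[g]]$window[which(ws$w == 1)]
    sel == eq$genes[[g]]$causal
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("ridge weights equal the closed-form solve at fixed lambda", {
  eq <- twas_eqtl_fixture()
  lam <- 3
  ws <- fit_weights(eq, 3, method = "ridge", lambda_grid = lam)
  w <- eq$genes[[3]]$window
  Xs <- scale(eq$panel$X[, w])
  y <- drop(scale(eq$expr[, 3]))
  # independent route: eigendecomposition instead of direct solve
  ei <- eigen(crossprod(Xs), symmetric = TRUE)
  want <- ei$vectors %*% ((t(ei$vectors) %*% crossprod(Xs, y)) /
                            (ei$values + lam))
  expect_equal(unname(ws$w), drop(want), tolerance = 1e-10)
})

test_that("orthogonal predictors shrink marginal covariances by 1/(n-1+lambda)", {
  # build a synthetic eqtl panel whose standardized genotypes are orthogonal:
  # orthonormal columns orthogonal to the intercept stay orthogonal after
  # centering/scaling
  set.seed(85)
  n <- 40
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(n * 5), n, 5))))[, 2:6]
  Q <- Q * sqrt(n - 1)              # mean 0, sd 1, X'X = (n-1) I
  fake <- structure(list(
    expr = matrix(rnorm(n), n, 1, dimnames = list(NULL, "g1")),
    genes = list(list(id = "g1", window = 1:5, causal = 1, beta = 0)),
    panel = list(X = Q, snps = data.frame(snp = paste0("s", 1:5))),
    truth = NULL), class = "eqtl_panel")
  lam <- 7
  ws <- fit_weights(fake, 1, method = "ridge", lambda_grid = lam)
  y <- drop(scale(fake$expr[, 1]))
  Xs <- standardize_genotypes(Q)
  expect_equal(ws$w, drop(crossprod(Xs, y)) / (n - 1 + lam),
               tolerance = 1e-8)
})

test_that("small panels fall back from ridge to top-eQTL with a warning", {
  p <- simulate_ld_panel(20, 10, block_size = 2, rho = 0.2, seed = 67)
  eq <- simulate_eqtl_panel(p, n_genes = 1, causal_per_gene = 1,
                            cis_h2 = 0.5, seed = 68)
  expect_warning(ws <- fit_weights(eq, 1, method = "ridge"), "top_eqtl")
  expect_equal(ws$method, "top_eqtl")
})

test_that("TWAS association reduces correctly and is scale invariant", {
  m <- 8
  R <- rand_corr(m, seed = 69)
  set.seed(70)
  gwas <- data.frame(snp = paste0("s", 1:m), z = rnorm(m), n = 1e4)
  mkw <- function(w) list(snps = paste0("s", 1:m), w = w)
  # indicator weight recovers the single-SNP Z
  w <- numeric(m); w[4] <- 1
  expect_equal(twas_associate(mkw(w), gwas, R)$z, gwas$z[4])
  # identity LD gives w'z/||w||
  set.seed(71); wr <- rnorm(m)
  I <- diag(m); dimnames(I) <- dimnames(R)
  expect_equal(twas_associate(mkw(wr), gwas, I)$z,
               sum(wr * gwas$z) / sqrt(sum(wr^2)))
  # invariance under positive rescaling
  expect_equal(twas_associate(mkw(wr), gwas, R)$z,
               twas_associate(mkw(3.7 * wr), gwas, R)$z, tolerance = 1e-12)
})

test_that("Stouffer combination weights stages by effective sample size", {
  # equal weights reduce to z * sqrt(2) for two equal stages
  sm <- stouffer_meta(c(2, 2), c(100, 100), c(100, 100))
  expect_equal(sm$z_combined, 2 * sqrt(2))
  # reduces to the unweighted formula when all N_eff equal
  sm2 <- stouffer_meta(c(1.2, -0.4, 2.0), rep(50, 3), rep(150, 3))
  expect_equal(sm2$z_combined, sum(c(1.2, -0.4, 2.0)) / sqrt(3))
  expect_error(stouffer_meta(2, 100, 100), class = "finewas_argument_error")
  expect_error(stouffer_meta(c(1, 2), 100, c(100, 100)),
               class = "finewas_argument_error")
})

test_that("transcriptome-wide Bonferroni threshold and BH flags", {
  out <- multiple_testing(c(1e-7, 1), n_genes = 1000, n_tissues = 10)
  expect_equal(attr(out, "bonferroni_threshold"), 5e-6)
  expect_equal(out$sig_bonferroni, c(TRUE, FALSE))
  expect_false(any(multiple_testing(rep(1, 5), 5)$sig_bonferroni))
  # BH flags equal a hand-rolled step-up procedure
  set.seed(73)
  p <- runif(30)^2
  out2 <- multiple_testing(p, n_genes = 30)
  ord <- order(p)
  k <- max(c(0, which(p[ord] <= 0.05 * seq_along(p) / length(p))))
  want <- rep(FALSE, 30)
  if (k > 0) want[ord[seq_len(k)]] <- TRUE
  expect_equal(out2$sig_BH, want)
})

test_that("gene PIPs: evidence limit, exchangeability, enumeration oracle", {
  gp <- gene_pip(10, matrix(1, 1, 1))
  expect_gte(gp$pip, 0.99)
  gp2 <- gene_pip(c(4, 4), matrix(1, 2, 2))
  expect_equal(gp2$pip[1], gp2$pip[2], tolerance = 1e-9)

  R <- rand_corr(4, seed = 74)
  set.seed(75)
  z <- rnorm(4, sd = 3)
  gp4 <- gene_pip(z, R, K = 2)
  orc <- oracle_enum_cpp(z, R, K = 2, ncp_scale = 5.2, ridge = 1e-4,
                         prior = rep(1 / 4, 4))
  expect_equal(gp4$pip, orc$alpha, tolerance = 1e-8)
  expect_gte(sum(gp4$pip[gp4$in_credible == 1]) / sum(gp4$pip), 0.9)
  expect_error(gene_pip(rnorm(16), diag(16)), class = "finewas_size_error")
})

test_that("two-stage TWAS detects a true expression-mediated effect", {
  p <- get_fixture("twostage_panel", function()
    simulate_ld_panel(2000, 30, block_size = c(1, 6), rho = 0.4, seed = 81))
  eq <- get_fixture("twostage_eqtl", function()
    simulate_eqtl_panel(get_fixture("twostage_panel", NULL), n_genes = 1,
                        causal_per_gene = 1, cis_h2 = 0.4, seed = 82))
  Xs <- scale(p$X)
  R <- cor(p$X); dimnames(R) <- list(p$snps$snp, p$snps$snp)
  ws <- fit_weights(eq, 1, method = "ridge")
  causal <- eq$genes[[1]]$causal
  beta <- eq$genes[[1]]$beta
  sim_stage <- function(effect, seed) {
    set.seed(seed)
    gexp <- drop(Xs[, causal, drop = FALSE] %*% beta)
    y <- effect * gexp + rnorm(2000, sd = sqrt(1 - effect^2 * 0.4))
    z <- drop(crossprod(Xs, y)) / (sqrt(2000) * sd(y))
    data.frame(snp = p$snps$snp, z = z, n = 2000)
  }
  set.seed(83)
  hits <- replicate(20, {
    r <- sample.int(1e6, 1)
    z1 <- twas_associate(ws, sim_stage(0.15, r), R)$z
    z2 <- twas_associate(ws, sim_stage(0.15, r + 1), R)$z
    sm <- stouffer_meta(c(z1, z2), c(1000, 1000), c(1000, 1000))
    sm$p_combined < 0.05 / 10
  })
  expect_gte(mean(hits), 0.8)
  # a stage-1-only signal is not replicated under a null second stage
  set.seed(84)
  null_z2 <- replicate(20, abs(twas_associate(
    ws, sim_stage(0, sample.int(1e6, 1)), R)$z))
  expect_lte(mean(null_z2 > 1.96), 0.25)
})
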