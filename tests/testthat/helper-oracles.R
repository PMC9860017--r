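# Shared fixtures (cached across test files) and independent oracle
# implementations used to cross-check the package's vectorized code paths.

.fixtures <- new.env(parent = emptyenv())

get_fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# random positive-definite correlation matrix
rand_corr <- function(m, seed) {
  set.seed(seed)
  B <- matrix(rnorm(m * (m + 5)), m)
  R <- stats::cov2cor(tcrossprod(B) / (m + 5))
  dimnames(R) <- list(paste0("s", seq_len(m)), paste0("s", seq_len(m)))
  R
}

# independent multivariate-normal log-density route: determinant() + solve()
# (the package uses a Cholesky backsolve)
mvn_logdens <- function(z, Sigma) {
  ld <- as.numeric(determinant(Sigma, logarithm = TRUE)$modulus)
  -0.5 * ld - 0.5 * drop(t(z) %*% solve(Sigma) %*% z)
}

# brute-force configuration-enumeration fine-mapping oracle (explicit loops,
# subsets up to size 2), mirroring the model: z ~ N(0, R + s^2 R_C R_C^T)
oracle_enum_cpp <- function(z, R, K, ncp_scale, ridge, prior) {
  m <- length(z)
  Rs <- (R + t(R)) / 2 + ridge * diag(m)
  sets <- list(integer(0))
  for (i in seq_len(m)) sets[[length(sets) + 1L]] <- i
  if (K >= 2 && m >= 2)
    for (i in 1:(m - 1)) for (j in (i + 1):m)
      sets[[length(sets) + 1L]] <- c(i, j)
  lp <- numeric(length(sets))
  for (s in seq_along(sets)) {
    C <- sets[[s]]
    Sig <- Rs
    for (a in C) Sig <- Sig + ncp_scale^2 * (Rs[, a] %o% Rs[, a])
    lp[s] <- mvn_logdens(z, Sig) + sum(log(prior[C]))
  }
  post <- exp(lp - max(lp)); post <- post / sum(post)
  alpha <- numeric(m)
  for (s in seq_along(sets)) alpha[sets[[s]]] <- alpha[sets[[s]]] + post[s]
  list(sets = sets, posterior = post, alpha = alpha)
}

# small shared panel for cheap unit tests
small_panel <- function() {
  get_fixture("small_panel", function()
    simulate_ld_panel(500, 100, block_size = c(2, 10), rho = 0.6, seed = 42))
}
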