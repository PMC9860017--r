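# QTL effect-size meta-analysis, enumeration-based fine-mapping with causal
# posterior probabilities (CPP) and credible sets, and construction of the
# MaxCPP and binding-site annotations consumed by partitioned heritability.

#' Inverse-variance-weighted fixed-effect meta-analysis Z-score
#'
#' Combines per-study effect sizes for one variant into a fixed-effect
#' meta-analytic Z:
#' \deqn{z_{FE} = \sum_j w_j \beta_j / \sqrt{\sum_j w_j}, \quad
#'       w_j = 1 / se_j^2.}
#' With a single study this reduces to \eqn{\beta / se}; it is equivalent to
#' a weighted average of the per-study z-scores.
#'
#' @param beta per-study effect sizes
#' @param se per-study standard errors (> 0)
#' @return the meta-analytic Z-score (scalar)
#' @export
fixed_effect_meta <- function(beta, se) {
  if (length(beta) == 0L) fw_stop("argument", "at least one study is required")
  if (length(beta) != length(se))
    fw_stop("argument", "beta and se must have equal length")
  if (any(se <= 0)) fw_stop("argument", "all standard errors must be > 0")
  w <- 1 / se^2
  sum(w * beta) / sqrt(sum(w))
}

#' Causal posterior probabilities by exact configuration enumeration
#'
#' Fine-maps a region from marginal Z-scores and its LD matrix by
#' enumerating every causal configuration of size at most `K` (including the
#' null configuration). Under configuration C the Z-vector is modelled as
#' multivariate normal with covariance
#' \eqn{R + s^2 R_C R_C^\top} where \eqn{R_C} are the LD columns of the
#' causal SNPs and \eqn{s} is the non-centrality scale of a standardized
#' causal effect. The posterior over configurations combines this likelihood
#' with a product prior (`prior_causal` per causal slot), and the per-SNP
#' CPP is the posterior mass of all configurations containing the SNP.
#'
#' The LD matrix is symmetrized and ridge-regularized (`R + ridge * I`) for
#' invertibility. Enumeration is capped (default m <= 50, K <= 3).
#'
#' @param z marginal Z-scores for the region
#' @param R LD correlation matrix (m x m)
#' @param K maximum number of causal SNPs per configuration
#' @param prior_causal per-SNP prior probability of causality per
#'   configuration slot; default 1/m
#' @param ncp_scale non-centrality scale of a causal effect (default 5.2)
#' @param ridge diagonal regularization added to R
#' @param level credible level for the reported credible set
#' @param max_configs enumeration cap on the number of configurations
#' @return object of class `finemap_result`: `snps`, `alpha` (CPP),
#'   `in_credible` (theta flags), `level`, `K` and the configuration table
#'   (`configs`: list of index sets and their normalized posteriors)
#' @export
compute_cpp <- function(z, R, K = 1L, prior_causal = NULL, ncp_scale = 5.2,
                        ridge = 1e-4, level = 0.95, max_configs = 30000L) {
  m <- length(z)
  if (!is.matrix(R) || nrow(R) != m || ncol(R) != m)
    fw_stop("argument", "R must be an m x m matrix matching z")
  n_configs <- sum(choose(m, 0:K))
  if (m > 50 || K > 3 || n_configs > max_configs)
    fw_stop("size", paste0("enumeration of ", n_configs, " configurations ",
                           "exceeds the cap; shrink the region or K"))
  if (is.null(prior_causal)) prior_causal <- 1 / m
  enum <- enum_config_posterior(z, R, K = K,
                                prior = rep_len(prior_causal, m),
                                ncp_scale = ncp_scale, ridge = ridge)
  sets <- enum$sets; post <- enum$posterior; alpha <- enum$alpha
  cs <- credible_set(list(sets = sets, posterior = post), level = level,
                     n_snps = m)
  snps <- if (!is.null(colnames(R))) colnames(R) else paste0("snp_", seq_len(m))
  structure(list(snps = snps, alpha = alpha, in_credible = cs$theta,
                 level = level, K = K,
                 configs = list(sets = sets, posterior = post)),
            class = "finemap_result")
}

# shared enumeration core: posterior over causal configurations of size <= K
# under z ~ N(0, R + ncp^2 R_C R_C^T), product prior over causal slots, null
# configuration included with prior 1 (empty product). Used at SNP level by
# compute_cpp and at gene level by gene_pip.
enum_config_posterior <- function(z, R, K, prior, ncp_scale, ridge) {
  m <- length(z)
  Rs <- (R + t(R)) / 2 + diag(ridge, m)
  sets <- list(integer(0))
  for (k in seq_len(K))
    sets <- c(sets, utils::combn(m, k, simplify = FALSE))
  loglik <- vapply(sets, function(C) {
    Sigma <- Rs
    if (length(C) > 0) {
      Rc <- Rs[, C, drop = FALSE]
      Sigma <- Sigma + ncp_scale^2 * tcrossprod(Rc)
    }
    ch <- tryCatch(chol(Sigma), error = function(e) NULL)
    if (is.null(ch))
      fw_stop("numeric", "correlation matrix not positive definite after regularization")
    -sum(log(diag(ch))) - 0.5 * sum(backsolve(ch, z, transpose = TRUE)^2)
  }, numeric(1))
  logprior <- vapply(sets, function(C) sum(log(prior[C])), numeric(1))
  lp <- loglik + logprior
  post <- exp(lp - max(lp))
  post <- post / sum(post)
  alpha <- numeric(m)
  for (i in seq_along(sets)) alpha[sets[[i]]] <- alpha[sets[[i]]] + post[i]
  list(sets = sets, posterior = post, alpha = alpha)
}

#' Credible set from a configuration posterior table
#'
#' Sorts configurations by posterior (descending, ties broken by generation
#' order, i.e. ascending SNP index) and accumulates them until the
#' cumulative posterior reaches `level`. The credible set is the union of
#' SNPs appearing in any retained configuration, honouring the guarantee
#' that it contains all causal variants with probability at least `level`.
#'
#' @param configs list with `sets` (list of integer index vectors) and
#'   `posterior` (normalized posterior per configuration)
#' @param level credible level (default 0.95)
#' @param n_snps number of SNPs in the region (for the theta vector length);
#'   inferred from the sets if missing
#' @return list with `snps` (sorted indices in the set), `theta` (0/1 per
#'   SNP) and `mass` (cumulative posterior retained)
#' @export
credible_set <- function(configs, level = 0.95, n_snps = NULL) {
  post <- configs$posterior
  if (abs(sum(post) - 1) > 1e-6)
    fw_stop("argument", "configuration posteriors must be normalized")
  if (is.null(n_snps))
    n_snps <- max(c(0L, unlist(configs$sets)))
  ord <- order(-post)  # stable: ties keep ascending-index generation order
  cum <- cumsum(post[ord])
  n_keep <- which(cum >= level - 1e-9)[1]
  if (is.na(n_keep)) n_keep <- length(ord)
  keep <- ord[seq_len(n_keep)]
  snps <- sort(unique(unlist(configs$sets[keep])))
  theta <- integer(n_snps)
  theta[snps] <- 1L
  list(snps = snps, theta = theta, mass = cum[n_keep])
}

#' MaxCPP annotation from per-gene fine-mapping results
#'
#' For SNP j the annotation value is the maximum CPP over all genes whose
#' credible set contains j (`a_j = max_i alpha_ji` over genes i with
#' `theta_ji = 1`), and 0 when no credible set contains the SNP. Restricting
#' `gene_subset` (e.g. to genes depleted of protein-truncating variants)
#' yields the constrained-gene variant of the annotation.
#'
#' @param finemap_results named list of `finemap_result` objects, one per
#'   gene, sharing a SNP naming scheme
#' @param snp_index character vector of SNP identifiers defining the output
#'   order
#' @param gene_subset optional character vector of gene names to restrict
#'   the maximum to; names absent from `finemap_results` produce a warning
#' @return numeric vector of annotation values in [0, 1], named by SNP
#' @export
max_cpp_annotation <- function(finemap_results, snp_index,
                               gene_subset = NULL) {
  genes <- names(finemap_results)
  if (is.null(genes)) genes <- as.character(seq_along(finemap_results))
  if (!is.null(gene_subset)) {
    unknown <- setdiff(gene_subset, genes)
    if (length(unknown) > 0)
      warning("gene_subset contains genes absent from the panel: ",
              paste(unknown, collapse = ", "))
    keep <- genes %in% gene_subset
    finemap_results <- finemap_results[keep]
  }
  a <- stats::setNames(numeric(length(snp_index)), snp_index)
  for (fr in finemap_results) {
    hit <- fr$in_credible == 1L
    if (!any(hit)) next
    ids <- fr$snps[hit]
    vals <- fr$alpha[hit]
    pos <- match(ids, snp_index)
    ok <- !is.na(pos)
    a[pos[ok]] <- pmax(a[pos[ok]], vals[ok])
  }
  a
}

#' Binding-site annotations from interval sets
#'
#' Builds one binary annotation column per RNA-binding protein (or any
#' interval set): SNP k gets value 1 iff its 1-based position falls within a
#' site extended by `flank` bases on both sides. Overlapping sites are
#' merged before flanking, so nested or abutting peaks count once.
#'
#' @param sites a named list of `GRanges` (one per RBP) or a single
#'   `GRanges` whose `name` metadata column labels the RBP
#' @param snps data.frame with columns `snp`, `chr`, `bp` (1-based)
#' @param flank flank width in bases added to each side of a site
#' @return data.frame in annotation layout: `snp`, `chr`, `bp` plus one 0/1
#'   column per RBP
#' @export
rbp_annotation <- function(sites, snps, flank = 100L) {
  if (!is.list(sites) || inherits(sites, "GRanges")) {
    nm <- sites$name
    if (is.null(nm)) nm <- rep("site", length(sites))
    sites <- split(sites, nm)
  }
  snp_gr <- GenomicRanges::GRanges(
    seqnames = snps$chr,
    ranges = IRanges::IRanges(start = snps$bp, width = 1L))
  out <- snps[, c("snp", "chr", "bp")]
  for (rbp in names(sites)) {
    merged <- GenomicRanges::reduce(sites[[rbp]], ignore.strand = TRUE)
    ext <- GenomicRanges::trim(suppressWarnings(merged + flank))
    hit <- IRanges::overlapsAny(snp_gr, ext, ignore.strand = TRUE)
    out[[rbp]] <- as.integer(hit)
  }
  out
}
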