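#' Correlation-matrix recipes and PSD repair
#'
#' Helpers to build valid correlation matrices for the synthetic-data
#' generator: a block-exchangeable matrix (`corr_block`), a hub-and-spoke
#' matrix (`corr_hub_spoke`), and a random positive semi-definite matrix via
#' random orthogonal mixing (`corr_random_psd`). `nearest_psd` repairs a
#' slightly indefinite user matrix by clipping negative eigenvalues at zero
#' and rescaling to unit diagonal, with a warning.
#'
#' @param n_genes number of genes (matrix dimension).
#' @param block_genes indices (or count) of genes forming the correlated
#'   block.
#' @param r within-block correlation, in (-1, 1).
#' @param background_r correlation among and toward non-block genes.
#' @name corr_recipes
NULL

#' @rdname corr_recipes
#' @export
corr_block <- function(n_genes, block_genes, r, background_r = 0) {
  if (length(block_genes) == 1L && block_genes >= 1 &&
      block_genes == as.integer(block_genes) && block_genes <= n_genes) {
    block_genes <- seq_len(block_genes)
  }
  stopifnot(all(block_genes >= 1), all(block_genes <= n_genes))
  R <- matrix(background_r, n_genes, n_genes)
  R[block_genes, block_genes] <- r
  diag(R) <- 1
  check_corr_matrix(R)
  R
}

#' @rdname corr_recipes
#' @param hub index of the hub gene.
#' @param spokes indices of the spoke genes.
#' @param r_hub hub-spoke correlation, in (0, 1). Spoke-spoke correlation
#'   is `r_hub^2` (the one-factor, hub-mediated value): a pure star with
#'   uncorrelated spokes is only positive semi-definite for
#'   `r_hub <= 1/sqrt(n_spokes)`, while the factor construction is valid
#'   for any `|r_hub| < 1`.
#' @export
corr_hub_spoke <- function(n_genes, hub, spokes, r_hub, background_r = 0) {
  stopifnot(hub >= 1, hub <= n_genes, !hub %in% spokes,
            all(spokes >= 1), all(spokes <= n_genes))
  R <- matrix(background_r, n_genes, n_genes)
  R[spokes, spokes] <- r_hub^2
  R[hub, spokes] <- r_hub
  R[spokes, hub] <- r_hub
  diag(R) <- 1
  check_corr_matrix(R)
  R
}

#' @rdname corr_recipes
#' @param seed integer seed for the random orthogonal basis.
#' @param eig_spread positive spread of the eigenvalue spectrum; larger gives
#'   stronger correlations.
#' @export
corr_random_psd <- function(n_genes, seed, eig_spread = 2) {
  stopifnot(eig_spread > 0)
  set.seed(as_seed(seed))
  Q <- qr.Q(qr(matrix(stats::rnorm(n_genes^2), n_genes)))
  lam <- exp(eig_spread * seq(-1, 1, length.out = n_genes))
  S <- Q %*% (lam * t(Q))
  stats::cov2cor(S)
}

#' @rdname corr_recipes
#' @param R a symmetric matrix intended as a correlation matrix.
#' @param tol eigenvalue tolerance below which repair is triggered.
#' @export
nearest_psd <- function(R, tol = 1e-10) {
  e <- eigen((R + t(R)) / 2, symmetric = TRUE)
  if (min(e$values) >= -tol) return(R)
  warning(sprintf("indefinite correlation matrix (min eigenvalue %.3g) %s",
                  min(e$values), "repaired by eigenvalue clipping"))
  lam <- pmax(e$values, 0)
  S <- e$vectors %*% (lam * t(e$vectors))
  R2 <- stats::cov2cor(S)
  (R2 + t(R2)) / 2
}

# Validate symmetry, unit diagonal, PSD (eigenvalues >= -1e-10); report the
# offending eigenvalue on failure.
check_corr_matrix <- function(R, tol = 1e-10) {
  if (!isSymmetric(unname(R), tol = 1e-8)) stop("correlation matrix is not symmetric")
  if (any(abs(diag(R) - 1) > 1e-8)) stop("correlation matrix diagonal is not 1")
  ev <- eigen((R + t(R)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol) {
    stop(sprintf("correlation matrix is not positive semi-definite (eigenvalue %.6g)",
                 min(ev)))
  }
  invisible(TRUE)
}

# Clamp arbitrary integer-ish seed into R's 32-bit range.
as_seed <- function(seed) {
  s <- as.numeric(seed) %% 2147483647
  as.integer(s)
}

# Draw n samples (columns) from mean mu and covariance with correlation R and
# per-gene sd; marginals Gaussian (noise_df = Inf) or scaled-t with noise_df
# degrees of freedom rescaled to unit variance (requires noise_df > 2).
rmvn_corr <- function(n, mu, R, sd = NULL, noise_df = Inf) {
  G <- length(mu)
  e <- eigen((R + t(R)) / 2, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  L <- e$vectors %*% (sqrt(lam) * t(e$vectors))
  if (is.infinite(noise_df)) {
    Z <- matrix(stats::rnorm(G * n), G, n)
  } else {
    if (noise_df <= 2) stop("noise_df must exceed 2 (finite variance)")
    Z <- matrix(stats::rt(G * n, df = noise_df), G, n) *
      sqrt((noise_df - 2) / noise_df)
  }
  X <- L %*% Z
  if (!is.null(sd)) X <- X * sd
  X + mu
}

#' Specify a rewired synthetic cohort
#'
#' A rewiring specification states the world a synthetic cohort is drawn
#' from: every group shares one mean vector (so the only signal is in the
#' correlation structure) while each group has its own correlation matrix.
#' This mirrors the headline structure of rewired transcriptomes, where
#' mean-equality tests are null but correlation-equality tests are not.
#'
#' @param n_genes number of genes G.
#' @param group_sizes integer vector of per-group sample counts, each >= 2.
#' @param corr_matrices list of G x G correlation matrices, one per group
#'   (recycled if one is given). Each must be symmetric with unit diagonal
#'   and eigenvalues >= -1e-10.
#' @param mean_vector shared per-gene mean (default 0).
#' @param sd_vector optional per-gene standard deviations (default 1),
#'   mimicking intensity heterogeneity.
#' @param noise_df marginal distribution: `Inf` (default) for Gaussian,
#'   finite (> 2) for unit-variance scaled-t marginals to stress rank-based
#'   stages.
#' @param seed integer seed; identical seed gives identical output.
#' @return object of class `RewiringSpec`.
#' @export
rewiring_spec <- function(n_genes, group_sizes, corr_matrices,
                          mean_vector = rep(0, n_genes),
                          sd_vector = NULL, noise_df = Inf, seed = 1L) {
  stopifnot(n_genes >= 1, length(group_sizes) >= 1)
  if (any(group_sizes < 2)) {
    stop("every group needs at least 2 samples (correlations undefined below)")
  }
  if (is.matrix(corr_matrices)) corr_matrices <- list(corr_matrices)
  if (length(corr_matrices) == 1L) {
    corr_matrices <- rep(corr_matrices, length(group_sizes))
  }
  stopifnot(length(corr_matrices) == length(group_sizes))
  for (R in corr_matrices) {
    stopifnot(nrow(R) == n_genes, ncol(R) == n_genes)
    check_corr_matrix(R)
  }
  stopifnot(length(mean_vector) == n_genes)
  if (!is.null(sd_vector)) stopifnot(length(sd_vector) == n_genes,
                                     all(sd_vector > 0))
  structure(list(n_genes = n_genes, group_sizes = as.integer(group_sizes),
                 corr_matrices = corr_matrices, mean_vector = mean_vector,
                 sd_vector = sd_vector, noise_df = noise_df,
                 seed = as_seed(seed)),
            class = "RewiringSpec")
}

#' Generate a rewired synthetic cohort
#'
#' Draws `sum(group_sizes)` samples: samples of group g come from the shared
#' mean vector and the g-th correlation matrix (unit variances unless
#' `sd_vector` is set). Group mean vectors are identical by construction, so
#' any detectable group difference is rewiring.
#'
#' @param spec a [rewiring_spec()].
#' @return list with `matrix` (an [expression_matrix()], G x n) and `groups`
#'   (integer group label per sample).
#' @export
generate_rewired_cohort <- function(spec) {
  stopifnot(inherits(spec, "RewiringSpec"))
  set.seed(spec$seed)
  blocks <- vector("list", length(spec$group_sizes))
  for (g in seq_along(spec$group_sizes)) {
    blocks[[g]] <- rmvn_corr(spec$group_sizes[g], spec$mean_vector,
                             spec$corr_matrices[[g]], sd = spec$sd_vector,
                             noise_df = spec$noise_df)
  }
  X <- do.call(cbind, blocks)
  groups <- rep(seq_along(spec$group_sizes), spec$group_sizes)
  em <- expression_matrix(X, paste0("g", seq_len(spec$n_genes)),
                          paste0("s", seq_len(ncol(X))))
  list(matrix = em, groups = groups)
}

#' Specify and generate a hub-structured cohort
#'
#' `hub_spec` states a hub-and-spoke correlation structure: one hub gene
#' correlated at `r_hub` with each spoke gene, spokes correlated at
#' `r_hub^2` among themselves (hub-mediated, see [corr_hub_spoke()]), and
#' all other correlations at `background_r`. The implied matrix must be
#' positive semi-definite (a single spoke at `r_hub = 1` is rejected as a
#' degenerate duplication).
#' `generate_hub_cohort` draws samples from it so that centrality-recovery
#' of planted hubs can be tested.
#'
#' @param genes character vector of gene identifiers.
#' @param hub_gene the hub's identifier (must be in `genes`).
#' @param spoke_genes identifiers of the spokes.
#' @param r_hub target hub-spoke correlation in (0, 1].
#' @param background_r off-hub correlation in [0, 1).
#' @return `hub_spec`: object of class `HubSpec`.
#' @export
hub_spec <- function(genes, hub_gene, spoke_genes, r_hub, background_r = 0) {
  genes <- as.character(genes)
  stopifnot(hub_gene %in% genes, all(spoke_genes %in% genes),
            !hub_gene %in% spoke_genes,
            r_hub > 0, r_hub <= 1, background_r >= 0, background_r < 1)
  if (r_hub == 1) {
    stop("r_hub = 1 duplicates the hub exactly (degenerate correlation)")
  }
  R <- corr_hub_spoke(length(genes), match(hub_gene, genes),
                      match(spoke_genes, genes), r_hub, background_r)
  structure(list(genes = genes, hub_gene = hub_gene,
                 spoke_genes = as.character(spoke_genes),
                 r_hub = r_hub, background_r = background_r, corr = R),
            class = "HubSpec")
}

#' @rdname hub_spec
#' @param spec a `HubSpec`.
#' @param n_samples number of samples to draw.
#' @param seed integer seed.
#' @return `generate_hub_cohort`: an [expression_matrix()].
#' @export
generate_hub_cohort <- function(spec, n_samples, seed = 1L) {
  stopifnot(inherits(spec, "HubSpec"), n_samples >= 2)
  set.seed(as_seed(seed))
  X <- rmvn_corr(n_samples, rep(0, length(spec$genes)), spec$corr)
  expression_matrix(X, spec$genes, paste0("s", seq_len(n_samples)))
}

#' Generate mutation labels with a stated cluster association
#'
#' Binary labels per sample whose prevalence differs between clusters by
#' exactly `odds_ratio` on the logit scale: the first cluster level carries
#' the base rate and each subsequent level adds `log(odds_ratio)` to the
#' logit. `odds_ratio = 1` gives labels independent of the clustering, the
#' null world in which mutation status does not explain cluster membership.
#'
#' @param cluster_labels vector of cluster assignments.
#' @param odds_ratio positive odds ratio between successive cluster levels.
#' @param base_rate P(label = 1) in the reference cluster.
#' @param seed integer seed.
#' @return integer 0/1 labels, named by `names(cluster_labels)` if present.
#' @export
generate_mutation_labels <- function(cluster_labels, odds_ratio,
                                     base_rate = 0.5, seed = 1L) {
  stopifnot(odds_ratio > 0, base_rate > 0, base_rate < 1)
  f <- factor(cluster_labels)
  if (nlevels(f) < 2L) {
    warning("single cluster present; labels drawn from the base rate")
  }
  set.seed(as_seed(seed))
  eta <- stats::qlogis(base_rate) + log(odds_ratio) * (as.integer(f) - 1L)
  p <- stats::plogis(eta)
  out <- as.integer(stats::runif(length(p)) < p)
  names(out) <- names(cluster_labels)
  out
}
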