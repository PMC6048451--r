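#' Topological overlap similarity
#'
#' From a soft-thresholded adjacency a_ij = |r_ij|^beta (diagonal 0), the
#' topological overlap of genes i and j is
#' TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij),
#' with k_i the connectivity sum_j a_ij; TOM_ii = 1 by convention.
#'
#' @param adjacency symmetric adjacency matrix in [0, 1] with zero
#'   diagonal.
#' @return symmetric TOM matrix in [0, 1], unit diagonal.
#' @export
tom_similarity <- function(adjacency) {
  A <- as.matrix(adjacency)
  diag(A) <- 0
  k <- rowSums(A)
  L <- A %*% A
  denom <- outer(k, k, pmin) + 1 - A
  TOM <- (L + A) / denom
  diag(TOM) <- 1
  TOM
}

#' Detect co-expression modules by topological overlap clustering
#'
#' Weighted co-expression module detection: adjacency
#' a_ij = |spearman r_ij|^beta, topological overlap similarity
#' ([tom_similarity()]), average-linkage hierarchical clustering on
#' 1 - TOM, and a fixed cut into exactly `k` modules. Constant genes are
#' excluded with a warning before clustering. Deterministic.
#'
#' @param x expression matrix.
#' @param k number of modules (>= 2, at most the number of genes).
#' @param beta soft-threshold exponent (default 6).
#' @param cor_method correlation method.
#' @return object of class `ModulePartition`: list with `labels` (named
#'   integer vector gene -> module in 1..k), `k`, `sizes`.
#' @export
detect_modules <- function(x, k, beta = 6, cor_method = "spearman") {
  x <- as_expression_matrix(x)
  const <- apply(unclass(x), 1L, function(v) length(unique(v)) == 1L)
  if (any(const)) {
    warning("constant gene(s) excluded from module detection: ",
            paste(rownames(x)[const], collapse = ", "))
    x <- x[!const, , drop = FALSE]
  }
  stopifnot(k >= 2, nrow(x) >= k)
  C <- spearman_corr(x, method = cor_method)
  A <- abs(C$r)^beta
  diag(A) <- 0
  TOM <- tom_similarity(A)
  hc <- stats::hclust(stats::as.dist(1 - TOM), method = "average")
  labels <- stats::cutree(hc, k = k)
  names(labels) <- rownames(x)
  structure(list(labels = labels, k = as.integer(k),
                 sizes = as.integer(table(factor(labels, levels = 1:k)))),
            class = "ModulePartition")
}

#' @export
print.ModulePartition <- function(x, ...) {
  cat(sprintf("ModulePartition: %d genes in %d modules (sizes %s)\n",
              length(x$labels), x$k, paste(x$sizes, collapse = ", ")))
  invisible(x)
}

as_partition <- function(x) {
  if (inherits(x, "ModulePartition")) return(x)
  labels <- x
  stopifnot(!is.null(names(labels)))
  labels <- as.integer(labels)
  names(labels) <- names(x)
  structure(list(labels = labels, k = max(labels),
                 sizes = as.integer(table(factor(labels,
                                                 levels = 1:max(labels))))),
            class = "ModulePartition")
}

#' Match modules across two partitions by maximal overlap
#'
#' For each module of the reference partition, finds the module of the
#' other partition maximising the size of the gene intersection. Ties go
#' to the lower module label (logged via message).
#'
#' @param partition_ref,partition_other `ModulePartition` objects over a
#'   shared gene universe.
#' @return data.frame: ref_module, ref_size, matched_module, overlap.
#' @export
match_modules <- function(partition_ref, partition_other) {
  pr <- as_partition(partition_ref)
  po <- as_partition(partition_other)
  shared <- intersect(names(pr$labels), names(po$labels))
  if (length(shared) == 0L) stop("disjoint gene universes")
  a <- pr$labels[shared]
  b <- po$labels[shared]
  tab <- table(factor(a, levels = 1:pr$k), factor(b, levels = 1:po$k))
  best <- apply(tab, 1L, which.max)   # which.max takes the lower index on ties
  ties <- vapply(seq_len(pr$k), function(m)
    sum(tab[m, ] == max(tab[m, ])) > 1L, logical(1))
  if (any(ties)) {
    message("overlap tie broken toward the lower module label for ref ",
            "module(s): ", paste(which(ties), collapse = ", "))
  }
  data.frame(ref_module = seq_len(pr$k),
             ref_size = as.integer(table(factor(a, levels = 1:pr$k))),
             matched_module = as.integer(best),
             overlap = tab[cbind(seq_len(pr$k), best)],
             row.names = NULL)
}

#' Permutation null for cross-partition module overlap
#'
#' Permutes the gene labels of the other partition B times; for each
#' reference module records the maximal overlap attainable against the
#' permuted partition, yielding a null overlap distribution per module and
#' an empirical p-value with the (count + 1)/(B + 1) convention.
#'
#' @param partition_ref,partition_other `ModulePartition` objects.
#' @param B number of permutations (default 1000, >= 99).
#' @param seed integer seed.
#' @return data.frame ref_module, ref_size, matched_module, overlap,
#'   null_mean, p; the per-module null distributions are attached as the
#'   `null_overlaps` attribute (B x k matrix, the beanplot's data).
#' @export
overlap_permutation_null <- function(partition_ref, partition_other,
                                     B = 1000, seed = 1L) {
  stopifnot(B >= 99)
  pr <- as_partition(partition_ref)
  po <- as_partition(partition_other)
  obs <- match_modules(pr, po)
  shared <- intersect(names(pr$labels), names(po$labels))
  a <- factor(pr$labels[shared], levels = 1:pr$k)
  b <- po$labels[shared]
  set.seed(as_seed(seed))
  null_mat <- matrix(NA_real_, B, pr$k)
  for (i in seq_len(B)) {
    bp <- factor(sample(b), levels = 1:po$k)
    tab <- table(a, bp)
    null_mat[i, ] <- apply(tab, 1L, max)
  }
  obs$null_mean <- colMeans(null_mat)
  obs$p <- vapply(seq_len(pr$k), function(m)
    empirical_pvalue(obs$overlap[m], null_mat[, m]), numeric(1))
  attr(obs, "null_overlaps") <- null_mat
  obs
}

#' Per-module rewiring test on intersecting genes
#'
#' Steiger correlation-equality test on a module's intersection gene set
#' between two label classes, with label permutations (delegating to
#' [permutation_equivalence_test()]). Intersections of fewer than 3 genes
#' cannot support a matrix test and yield an NA result entry rather than
#' an error, mirroring module tables where small intersections are
#' reported as NA.
#'
#' @param x expression matrix.
#' @param labels binary sample labels (each class >= 4 samples).
#' @param genes the intersecting gene set to test.
#' @param n_perm label permutations (default 1000).
#' @param seed integer seed.
#' @param cor_method correlation method.
#' @return an `EquivTestResult`, or a list with `statistic = NA` and
#'   `skipped = TRUE` when the intersection is too small.
#' @export
module_rewiring_test <- function(x, labels, genes, n_perm = 1000, seed = 1L,
                                 cor_method = "spearman") {
  x <- as_expression_matrix(x)
  genes <- intersect(genes, rownames(x))
  if (length(genes) < 3L) {
    return(list(statistic_name = "steiger_chisq", statistic = NA_real_,
                df = NA_integer_, p_simulated = NA_real_,
                n_null = NA_integer_, skipped = TRUE,
                n_genes = length(genes)))
  }
  res <- permutation_equivalence_test(x[genes, , drop = FALSE], labels,
                                      method = "steiger", n_perm = n_perm,
                                      seed = seed, cor_method = cor_method)
  res$skipped <- FALSE
  res$n_genes <- length(genes)
  res
}
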