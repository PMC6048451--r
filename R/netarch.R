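#' Build a thresholded correlation network
#'
#' Edge rule: gene pair (i, j) is connected iff the two-sided p-value of
#' its Spearman correlation is at most `alpha` (default 0.05, raw — no
#' multiple-testing correction, matching the within-network convention);
#' the edge weight is r_ij^2. Isolated genes stay in the node set.
#'
#' @param x expression matrix (>= 4 samples) or a `CorrMatrix` with
#'   p-values.
#' @param alpha edge-retention p-value threshold.
#' @param cor_method correlation method when `x` is an expression matrix.
#' @return object of class `GeneNetwork`: list with `nodes`, `edges`
#'   (data.frame gene_i, gene_j, r, r2, p), `weights` (G x G symmetric
#'   matrix of retained r^2, 0 elsewhere), `alpha`.
#' @export
build_network <- function(x, alpha = 0.05, cor_method = "spearman") {
  C <- as_corr(x, method = cor_method)
  if (is.null(C$p)) stop("a CorrMatrix without p-values cannot be thresholded")
  G <- nrow(C$r)
  keep <- C$p <= alpha & upper.tri(C$r)
  idx <- which(keep, arr.ind = TRUE)
  W <- matrix(0, G, G, dimnames = list(C$gene_ids, C$gene_ids))
  if (nrow(idx)) {
    W[idx] <- C$r[idx]^2
    W[idx[, c(2, 1), drop = FALSE]] <- C$r[idx]^2
  }
  edges <- data.frame(gene_i = C$gene_ids[idx[, 1L]],
                      gene_j = C$gene_ids[idx[, 2L]],
                      r = C$r[idx], r2 = C$r[idx]^2, p = C$p[idx],
                      stringsAsFactors = FALSE)
  structure(list(nodes = C$gene_ids, edges = edges, weights = W,
                 alpha = alpha, n_samples = C$n_samples),
            class = "GeneNetwork")
}

#' @export
print.GeneNetwork <- function(x, ...) {
  cat(sprintf("GeneNetwork: %d nodes, %d edges (alpha = %g)\n",
              length(x$nodes), nrow(x$edges), x$alpha))
  invisible(x)
}

#' Node centralities of a gene network
#'
#' Four per-gene centralities on the weighted graph:
#' \describe{
#'   \item{degree}{weighted degree (strength): row sums of the weight
#'     matrix.}
#'   \item{closeness}{Wasserman-Faust within-component closeness
#'     ((reachable - 1)^2 / ((n - 1) * sum of distances)) with
#'     shortest-path distances on edge lengths 1/w; isolated nodes get 0.}
#'   \item{betweenness}{unnormalized shortest-path betweenness on 1/w edge
#'     lengths, with fractional credit split over tied shortest paths
#'     (Brandes accounting).}
#'   \item{eigenvector}{principal eigenvector of the weight matrix,
#'     computed on the largest connected component and max-normalized to
#'     1; nodes outside that component get 0.}
#' }
#'
#' @param net a `GeneNetwork` (or expression matrix, passed to
#'   [build_network()]).
#' @return data.frame with columns gene, degree, closeness, betweenness,
#'   eigenvector.
#' @export
centralities <- function(net) {
  if (!inherits(net, "GeneNetwork")) net <- build_network(net)
  nodes <- net$nodes
  nG <- length(nodes)
  out <- data.frame(gene = nodes, degree = 0, closeness = 0,
                    betweenness = 0, eigenvector = 0,
                    stringsAsFactors = FALSE)
  if (nrow(net$edges) == 0L) {
    warning("empty edge set: all centralities are 0")
    return(out)
  }
  out$degree <- rowSums(net$weights)
  g <- igraph::graph_from_adjacency_matrix(net$weights, mode = "undirected",
                                           weighted = TRUE)
  len <- 1 / igraph::E(g)$weight
  D <- igraph::distances(g, weights = len)
  reach <- rowSums(is.finite(D)) # includes self
  sumd <- rowSums(ifelse(is.finite(D), D, 0))
  cl <- ifelse(reach > 1 & sumd > 0,
               (reach - 1)^2 / ((nG - 1) * sumd), 0)
  out$closeness <- as.vector(cl)
  out$betweenness <- as.vector(igraph::betweenness(g, weights = len,
                                                   normalized = FALSE))
  comp <- igraph::components(g)
  big <- which.max(comp$csize)
  members <- which(comp$membership == big)
  ev <- rep(0, nG)
  if (length(members) > 1L) {
    sub <- net$weights[members, members, drop = FALSE]
    e <- eigen(sub, symmetric = TRUE)
    v <- abs(e$vectors[, 1L])
    ev[members] <- v / max(v)
  }
  out$eigenvector <- ev
  out
}

#' Consensus hub from centrality records
#'
#' For each of the four centrality metrics the top-1 gene is taken (ties
#' within a metric keep all tied genes); the consensus hub is the modal
#' gene over the four top lists, with all modal genes reported on ties.
#'
#' @param records data.frame from [centralities()].
#' @return list with `per_metric` (named list of top genes) and
#'   `consensus` (character vector, usually length 1).
#' @export
consensus_hub <- function(records) {
  stopifnot(nrow(records) >= 1L)
  metrics <- c("degree", "closeness", "betweenness", "eigenvector")
  tops <- lapply(metrics, function(m) {
    v <- records[[m]]
    records$gene[v == max(v)]
  })
  names(tops) <- metrics
  votes <- table(unlist(lapply(tops, unique)))
  consensus <- names(votes)[votes == max(votes)]
  list(per_metric = tops, consensus = sort(consensus))
}

#' Cross-group centrality correlation
#'
#' Pearson correlation, per centrality metric, of the per-gene centrality
#' values between two groups' networks over their shared genes, plus the
#' arithmetic mean over the four metrics. A high average indicates stable
#' architecture; values near zero (or negative) indicate rewiring. A
#' metric constant in either group has no defined correlation; it is
#' reported as NA and excluded from the average with a warning.
#'
#' @param records_a,records_b data.frames from [centralities()].
#' @return named list: `per_metric` (named numeric, possibly NA) and
#'   `average`.
#' @export
centrality_correlation <- function(records_a, records_b) {
  shared <- intersect(records_a$gene, records_b$gene)
  if (length(shared) < 3L) stop("fewer than 3 shared genes")
  a <- records_a[match(shared, records_a$gene), ]
  b <- records_b[match(shared, records_b$gene), ]
  metrics <- c("degree", "closeness", "betweenness", "eigenvector")
  r <- vapply(metrics, function(m) {
    if (stats::sd(a[[m]]) == 0 || stats::sd(b[[m]]) == 0) {
      warning("constant ", m, " centrality in one group; excluded from average")
      return(NA_real_)
    }
    stats::cor(a[[m]], b[[m]])
  }, numeric(1))
  list(per_metric = r, average = mean(r, na.rm = TRUE))
}

#' Count Bonferroni-significant correlation pairs per group
#'
#' For a common pair universe (all unordered gene pairs, or, when
#' `subset_genes` is given, all pairs with at least one member in the
#' subset), counts how many pairs have a correlation significant at
#' `alpha / (number of pairs)` (Bonferroni) in each of two cohorts, and
#' how many are significant in both.
#'
#' @param expr_a,expr_b expression matrices over the identical gene
#'   universe.
#' @param subset_genes optional gene subset anchoring the pairs.
#' @param alpha family-wise level (default 0.05).
#' @param cor_method correlation method.
#' @return list with `count_a`, `count_b`, `count_shared`, `n_pairs`,
#'   `threshold`, and percentages `pct_a`, `pct_b`, `pct_shared`.
#' @export
count_significant_pairs <- function(expr_a, expr_b, subset_genes = NULL,
                                    alpha = 0.05, cor_method = "spearman") {
  expr_a <- as_expression_matrix(expr_a)
  expr_b <- as_expression_matrix(expr_b)
  if (!identical(rownames(expr_a), rownames(expr_b))) {
    stop("the two cohorts must share the identical gene universe")
  }
  Ca <- spearman_corr(expr_a, method = cor_method)
  Cb <- spearman_corr(expr_b, method = cor_method)
  up <- upper.tri(Ca$r)
  if (!is.null(subset_genes)) {
    stopifnot(all(subset_genes %in% rownames(expr_a)))
    in_sub <- rownames(expr_a) %in% subset_genes
    anchored <- outer(in_sub, in_sub, "|")
    up <- up & anchored
  }
  n_pairs <- sum(up)
  thr <- alpha / n_pairs
  sig_a <- Ca$p[up] <= thr
  sig_b <- Cb$p[up] <= thr
  list(count_a = sum(sig_a), count_b = sum(sig_b),
       count_shared = sum(sig_a & sig_b), n_pairs = n_pairs,
       threshold = thr,
       pct_a = 100 * mean(sig_a), pct_b = 100 * mean(sig_b),
       pct_shared = 100 * mean(sig_a & sig_b))
}

#' Differential correlation between two groups
#'
#' Per gene pair, the difference of correlations and the Fisher-z
#' statistic z = (atanh r1 - atanh r2) / sqrt(1/(n1-3) + 1/(n2-3)) with a
#' two-sided normal p-value.
#'
#' @param R1,R2 `CorrMatrix` objects over the same genes (n > 3 each).
#' @return data.frame with gene_i, gene_j, r1, r2, diff, z, p (one row per
#'   unordered pair).
#' @export
differential_correlation <- function(R1, R2) {
  R1 <- as_corr(R1); R2 <- as_corr(R2)
  check_same_genes(R1, R2)
  if (R1$n_samples <= 3 || R2$n_samples <= 3) stop("need n > 3 per group")
  up <- which(upper.tri(R1$r), arr.ind = TRUE)
  r1 <- R1$r[up]; r2 <- R2$r[up]
  bad <- abs(r1) >= 1 | abs(r2) >= 1
  if (any(bad)) {
    stop("|r| = 1 for pair(s) ",
         paste(apply(up[bad, , drop = FALSE], 1L, function(b)
           paste(R1$gene_ids[b], collapse = "-")), collapse = ", "))
  }
  se <- sqrt(1 / (R1$n_samples - 3) + 1 / (R2$n_samples - 3))
  z <- (atanh(r1) - atanh(r2)) / se
  data.frame(gene_i = R1$gene_ids[up[, 1L]], gene_j = R1$gene_ids[up[, 2L]],
             r1 = r1, r2 = r2, diff = r1 - r2, z = z,
             p = 2 * stats::pnorm(abs(z), lower.tail = FALSE),
             stringsAsFactors = FALSE)
}

#' Strong edges and tail quantile of a correlation matrix
#'
#' `strong_edges` lists the gene pairs whose correlation is strictly below
#' `-threshold` or strictly above `threshold` (|r| > 0.7 by default).
#' `tail_quantile` returns the upper-tail quantile (default the 95th
#' percentile) of the off-diagonal upper-triangle coefficients by linear
#' interpolation.
#'
#' @param R a `CorrMatrix` (or expression matrix).
#' @param threshold strong-edge cutoff (strict inequality).
#' @return `strong_edges`: data.frame gene_i, gene_j, r.
#' @export
strong_edges <- function(R, threshold = 0.7) {
  R <- as_corr(R)
  up <- which(upper.tri(R$r) & abs(R$r) > threshold, arr.ind = TRUE)
  data.frame(gene_i = R$gene_ids[up[, 1L]], gene_j = R$gene_ids[up[, 2L]],
             r = R$r[up], stringsAsFactors = FALSE)
}

#' @rdname strong_edges
#' @param values numeric vector, or a `CorrMatrix` whose upper-triangle
#'   coefficients are used.
#' @param q quantile level (default 0.95).
#' @export
tail_quantile <- function(values, q = 0.95) {
  if (inherits(values, "CorrMatrix")) values <- values$r[upper.tri(values$r)]
  unname(stats::quantile(values, probs = q, type = 7))
}

#' Read an undirected gene-gene interaction table
#'
#' TSV with columns `gene_a`, `gene_b` and optionally `evidence_type`.
#' Pairs are undirected.
#'
#' @param path file path; default is the packaged synthetic fixture of
#'   previously reported melanoma co-expression edges.
#' @return data.frame gene_a, gene_b, evidence_type.
#' @export
read_interaction_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "known_interactions_synthetic.tsv",
                        package = "rewirekit", mustWork = TRUE)
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene_a", "gene_b") %in% names(df)))
  if (is.null(df$evidence_type)) df$evidence_type <- NA_character_
  df
}

#' Count strong edges previously reported in an interaction table
#'
#' Order-insensitive set intersection of the strong-edge pairs with an
#' undirected interaction table.
#'
#' @param pairs data.frame with gene_i, gene_j (e.g. from
#'   [strong_edges()]).
#' @param table data.frame with gene_a, gene_b.
#' @return list with `n_known` and `n_total`.
#' @export
count_known_edges <- function(pairs, table) {
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  n_total <- nrow(pairs)
  if (n_total == 0L || nrow(table) == 0L) {
    return(list(n_known = 0L, n_total = n_total))
  }
  known <- unique(key(as.character(table$gene_a), as.character(table$gene_b)))
  got <- key(as.character(pairs$gene_i), as.character(pairs$gene_j))
  list(n_known = sum(got %in% known), n_total = n_total)
}
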