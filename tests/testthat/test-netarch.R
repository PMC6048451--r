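test_that("edge rule: p <= alpha keeps the edge with weight r^2", {
  # construct a cohort with one strong and one null pair
  set.seed(12)
  n <- 30
  z <- rnorm(n)
  x <- expression_matrix(rbind(a = z + rnorm(n, sd = 0.3),
                               b = z + rnorm(n, sd = 0.3),
                               c = rnorm(n)),
                         c("a", "b", "c"), paste0("s", 1:n))
  net <- build_network(x, alpha = 0.05)
  C <- spearman_corr(x)
  ab <- net$edges[net$edges$gene_i == "a" & net$edges$gene_j == "b", ]
  expect_equal(nrow(ab), 1L)
  expect_equal(ab$r2, C$r["a", "b"]^2)
  # every retained edge satisfies the rule; every excluded pair violates it
  for (i in 1:2) for (j in (i + 1):3) {
    gi <- c("a", "b", "c")[i]; gj <- c("a", "b", "c")[j]
    present <- any(net$edges$gene_i == gi & net$edges$gene_j == gj)
    expect_identical(present, unname(C$p[gi, gj] <= 0.05))
  }
  # isolated nodes stay in the node set
  expect_identical(net$nodes, c("a", "b", "c"))
  expect_error(build_network(x[, 1:3]), ">= 4 samples")
})

test_that("edge set shrinks monotonically as alpha decreases", {
  spec <- rewiring_spec(10, c(25, 2), corr_block(10, 5, 0.5), seed = 8)
  x <- generate_rewired_cohort(spec)$matrix[, 1:25]
  counts <- sapply(c(0.2, 0.1, 0.05, 0.01, 0.001),
                   function(a) nrow(build_network(x, alpha = a)$edges))
  expect_true(all(diff(counts) <= 0))
})

test_that("star-graph centralities match closed forms", {
  # unit-weight star K_{1,3}: center g1
  W <- matrix(0, 4, 4, dimnames = list(paste0("g", 1:4), paste0("g", 1:4)))
  W[1, 2:4] <- W[2:4, 1] <- 1
  rec <- centralities(network_from_weights(W))
  expect_equal(rec$degree, c(3, 1, 1, 1))
  expect_equal(rec$betweenness, c(3, 0, 0, 0))
  expect_equal(rec$eigenvector, c(1, 1 / sqrt(3), 1 / sqrt(3), 1 / sqrt(3)),
               tolerance = 1e-10)
  # closeness with all nodes reachable: center 1, leaves (3)^2/(3*5)
  expect_equal(rec$closeness[1], 1)
  expect_equal(rec$closeness[2], 9 / (3 * 5))
})

test_that("betweenness matches exhaustive path enumeration on small graphs", {
  for (seed in 1:6) {
    n <- sample(4:7, 1)
    W <- random_weight_graph(n, seed = 100 + seed)
    rec <- centralities(network_from_weights(W))
    lengths <- ifelse(W > 0, 1 / W, Inf)
    diag(lengths) <- Inf
    expect_equal(rec$betweenness, oracle_betweenness(lengths),
                 tolerance = 1e-9, info = paste("seed", seed))
  }
})

test_that("centralities are invariant under node relabeling; degree equals
           row sums", {
  W <- random_weight_graph(6, seed = 42)
  rec <- centralities(network_from_weights(W))
  expect_equal(rec$degree, unname(rowSums(W)))
  perm <- c(4, 2, 6, 1, 3, 5)
  Wp <- W[perm, perm]
  recp <- centralities(network_from_weights(Wp))
  m <- match(rec$gene, recp$gene)
  for (metric in c("degree", "closeness", "betweenness", "eigenvector")) {
    expect_equal(rec[[metric]], recp[[metric]][m], tolerance = 1e-9)
  }
})

test_that("empty networks yield zero centralities with a warning", {
  W <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_warning(rec <- centralities(network_from_weights(W)), "empty")
  expect_true(all(rec$degree == 0 & rec$betweenness == 0))
})

test_that("consensus_hub takes the mode, reporting ties", {
  rec <- data.frame(gene = c("A", "B", "C"),
                    degree = c(3, 1, 1), closeness = c(1, 0.5, 0.2),
                    betweenness = c(5, 1, 0), eigenvector = c(1, 0.9, 0.1))
  expect_equal(consensus_hub(rec)$consensus, "A")
  # 2/1/1 split
  rec2 <- rec; rec2$betweenness <- c(0, 9, 1); rec2$eigenvector <- c(0.1, 0.2, 1)
  expect_equal(consensus_hub(rec2)$consensus, "A")
  # 2/2 split reports both
  rec3 <- rec; rec3$betweenness <- c(0, 9, 1); rec3$closeness <- c(0.1, 1, 0.2)
  expect_equal(consensus_hub(rec3)$consensus, c("A", "B"))
})

test_that("planted hub is the top degree-centrality node", {
  genes <- paste0("g", 1:12)
  hs <- hub_spec(genes, "g5", setdiff(genes, "g5")[1:10], r_hub = 0.7)
  x <- generate_hub_cohort(hs, 500, seed = 99)
  rec <- centralities(build_network(x))
  expect_equal(rec$gene[which.max(rec$degree)], "g5")
})

test_that("centrality_correlation: identity, nulls and degenerate metrics", {
  W <- random_weight_graph(7, seed = 17)
  rec <- centralities(network_from_weights(W))
  same <- centrality_correlation(rec, rec)
  expect_equal(unname(same$per_metric), rep(1, 4), tolerance = 1e-10)
  expect_equal(same$average, 1, tolerance = 1e-10)
  # independent permutation of values: near-zero average (null oracle)
  set.seed(3)
  recp <- rec
  for (m in c("degree", "closeness", "betweenness", "eigenvector")) {
    recp[[m]] <- sample(rec[[m]])
  }
  # with only 7 genes the correlation is noisy; just check it is not ~1
  expect_lt(abs(centrality_correlation(rec, recp)$average), 0.9)
  # constant metric: NA + warning + excluded from average
  recc <- rec; recc$closeness <- 1
  expect_warning(cc <- centrality_correlation(rec, recc), "constant")
  expect_true(is.na(cc$per_metric["closeness"]))
  expect_false(is.na(cc$average))
  expect_error(centrality_correlation(rec[1:2, ], rec[1:2, ]), "3 shared")
})

test_that("count_significant_pairs: identity, null and power behaviour", {
  set.seed(21)
  xa <- expression_matrix(matrix(rnorm(50 * 100), 50),
                          paste0("g", 1:50), paste0("s", 1:100))
  # identical data in both groups
  res <- count_significant_pairs(xa, xa)
  expect_identical(res$count_a, res$count_b)
  expect_identical(res$count_shared, res$count_a)
  expect_equal(res$n_pairs, choose(50, 2))
  # independent noise: Bonferroni keeps ~alpha expected hits overall
  tot <- 0L
  for (i in 1:10) {
    set.seed(100 + i)
    a <- expression_matrix(matrix(rnorm(50 * 100), 50),
                           paste0("g", 1:50), paste0("s", 1:100))
    b <- expression_matrix(matrix(rnorm(50 * 100), 50),
                           paste0("g", 1:50), paste0("s", 1:100))
    r <- count_significant_pairs(a, b)
    tot <- tot + r$count_a + r$count_b
  }
  expect_lte(tot, 3L)
  # planted block in group A only
  spec <- rewiring_spec(20, c(200, 200),
                        list(corr_block(20, 10, 0.9), diag(20)), seed = 5)
  cohort <- generate_rewired_cohort(spec)
  a <- cohort$matrix[, cohort$groups == 1]
  b <- cohort$matrix[, cohort$groups == 2]
  r <- count_significant_pairs(a, b)
  expect_gte(r$count_a, 45L)   # all 45 block pairs
  expect_lte(r$count_b, 2L)
  # subset anchoring restricts the pair universe
  rs <- count_significant_pairs(a, b, subset_genes = paste0("g", 1:2))
  expect_identical(rs$n_pairs, as.integer(choose(2, 2) + 2 * 18))
})

test_that("differential_correlation matches the Fisher-z formula", {
  R1 <- corr_matrix(matrix(c(1, 0.5, 0.5, 1), 2), 103,
                    gene_ids = c("a", "b"))
  R2 <- corr_matrix(diag(2), 103, gene_ids = c("a", "b"))
  d <- differential_correlation(R1, R2)
  expect_equal(d$z, atanh(0.5) / sqrt(0.02), tolerance = 1e-12)
  # equal correlations: z = 0, p = 1
  d0 <- differential_correlation(R1, R1)
  expect_equal(d0$z, 0)
  expect_equal(d0$p, 1)
  # matrix-wide null: z approximately standard normal (Pearson world)
  set.seed(14)
  G <- 46  # 1035 pairs
  za <- matrix(rnorm(G * 150), G); zb <- matrix(rnorm(G * 150), G)
  Ca <- corr_matrix(cor(t(za)), 150); Cb <- corr_matrix(cor(t(zb)), 150)
  dn <- differential_correlation(Ca, Cb)
  expect_gt(ks.test(dn$z, "pnorm")$p.value, 0.01)
})

test_that("strong_edges uses strict thresholds; tail_quantile interpolates", {
  r <- diag(3)
  r[1, 2] <- r[2, 1] <- 0.7    # exactly at threshold: excluded
  r[1, 3] <- r[3, 1] <- -0.71
  R <- corr_matrix(r, 20, gene_ids = c("a", "b", "c"))
  se <- strong_edges(R, 0.7)
  expect_equal(nrow(se), 1L)
  expect_equal(se$r, -0.71)
  # quantile convention: linear interpolation (type 7)
  expect_equal(tail_quantile(seq(0.01, 1, by = 0.01), 0.95), 0.9505)
  expect_equal(tail_quantile(rep(0.3, 10), 0.95), 0.3)
})

test_that("count_known_edges is order-insensitive", {
  pairs <- data.frame(gene_i = c("A", "C"), gene_j = c("B", "D"))
  expect_equal(count_known_edges(pairs, data.frame(gene_a = "B", gene_b = "A")),
               list(n_known = 1L, n_total = 2L))
  expect_equal(count_known_edges(pairs, data.frame(gene_a = character(0),
                                                   gene_b = character(0)))$n_known, 0L)
  tab <- data.frame(gene_a = c("A", "D"), gene_b = c("B", "C"))
  expect_equal(count_known_edges(pairs, tab)$n_known, 2L)
  # packaged fixture loads and names the six reported edge types
  fix <- read_interaction_table()
  expect_equal(nrow(fix), 6L)
  expect_equal(count_known_edges(data.frame(gene_i = "KRAS", gene_j = "RGL2"),
                                 fix)$n_known, 1L)
})
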