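test_that("spearman_corr matches hand rank computations", {
  x <- expression_matrix(rbind(a = 1:5, b = c(1, 2, 3, 5, 4),
                               c = c(2, 4, 6, 8, 10)),
                         c("a", "b", "c"), paste0("s", 1:5))
  C <- spearman_corr(x)
  # one swapped adjacent pair: r = 1 - 6*2/(5*24) = 0.9
  expect_equal(C$r["a", "b"], 0.9)
  # perfectly monotone pair
  expect_equal(C$r["a", "c"], 1)
  expect_equal(diag(C$r), rep(1, 3), ignore_attr = TRUE)
  expect_equal(diag(C$p), rep(0, 3), ignore_attr = TRUE)
  # p-value from the t approximation, df = n - 2
  tt <- 0.9 * sqrt(3 / (1 - 0.81))
  expect_equal(C$p["a", "b"], 2 * pt(tt, 3, lower.tail = FALSE))
  expect_error(spearman_corr(x[, 1:3]), ">= 4 samples")
})

test_that("constant genes are flagged and zeroed", {
  x <- expression_matrix(rbind(a = 1:6, flat = rep(2, 6)),
                         c("a", "flat"), paste0("s", 1:6))
  expect_warning(C <- spearman_corr(x), "flat")
  expect_equal(C$r["a", "flat"], 0)
  expect_equal(C$constant_genes, "flat")
})

test_that("steiger_test matches its closed form and the naive oracle", {
  R1 <- corr_matrix(matrix(c(1, 0.5, 0.5, 1), 2), 103)
  R2 <- corr_matrix(diag(2), 103)
  res <- steiger_test(R1, R2)
  expect_equal(res$statistic, atanh(0.5)^2 / 0.02, tolerance = 1e-12)
  expect_identical(res$df, 1)
  # identical matrices: statistic 0
  expect_equal(steiger_test(R1, R1)$statistic, 0)
  # random matrices against the independently coded sum
  set.seed(6)
  for (i in 1:5) {
    r1 <- cor(matrix(rnorm(80), 20, 4))
    r2 <- cor(matrix(rnorm(80), 20, 4))
    s <- steiger_test(corr_matrix(r1, 20), corr_matrix(r2, 25))
    expect_equal(s$statistic, oracle_steiger(r1, r2, 20, 25),
                 tolerance = 1e-10)
    # symmetry in the two groups
    expect_equal(s$statistic,
                 steiger_test(corr_matrix(r2, 25),
                              corr_matrix(r1, 20))$statistic)
  }
  # |r| = 1 off-diagonal names the pair
  Rbad <- corr_matrix(matrix(c(1, 1, 1, 1), 2), 10,
                      gene_ids = c("gx", "gy"))
  Rok <- corr_matrix(diag(2), 103, gene_ids = c("gx", "gy"))
  expect_error(steiger_test(Rbad, Rok), "gx-gy")
})

test_that("jennrich_test matches its closed form", {
  R1 <- corr_matrix(matrix(c(1, 0.3, 0.3, 1), 2), 50)
  R2 <- corr_matrix(matrix(c(1, -0.3, -0.3, 1), 2), 50)
  res <- jennrich_test(R1, R2)
  # pooled matrix is I, c = 25, Z = 5 (R1 - R2): chi^2 = tr(Z^2)/2 = 9
  expect_equal(res$statistic, 9, tolerance = 1e-12)
  expect_identical(res$df, 1)
  expect_equal(jennrich_test(R1, R1)$statistic, 0)
  # symmetry up to sign of the difference
  expect_equal(jennrich_test(R2, R1)$statistic, res$statistic)
})

test_that("jennrich singular pooled matrix advises shrinkage", {
  # perfectly correlated pair in both groups: pooled matrix singular
  R1 <- corr_matrix(matrix(c(1, 1, 1, 1), 2), 30)
  expect_error(jennrich_test(R1, R1), "shrinkage")
  # shrinkage makes it computable and flags the result
  res <- jennrich_test(R1, R1, shrinkage = 0.1)
  expect_equal(res$statistic, 0, tolerance = 1e-10)
  expect_equal(res$shrinkage, 0.1)
})

test_that("gene reordering leaves both statistics invariant", {
  set.seed(9)
  x <- matrix(rnorm(200), 5, dimnames = list(paste0("g", 1:5), NULL))
  y <- matrix(rnorm(200), 5, dimnames = list(paste0("g", 1:5), NULL))
  C1 <- spearman_corr(expression_matrix(x)); C2 <- spearman_corr(expression_matrix(y))
  perm <- c(3, 1, 5, 2, 4)
  C1p <- spearman_corr(expression_matrix(x[perm, ]))
  C2p <- spearman_corr(expression_matrix(y[perm, ]))
  expect_equal(steiger_test(C1, C2)$statistic,
               steiger_test(C1p, C2p)$statistic, tolerance = 1e-10)
  expect_equal(jennrich_test(C1, C2)$statistic,
               jennrich_test(C1p, C2p)$statistic, tolerance = 1e-10)
})

test_that("permutation test is reproducible and p sits on the stated grid", {
  spec <- rewiring_spec(6, c(10, 10), diag(6), seed = 21)
  x <- generate_rewired_cohort(spec)$matrix
  lab <- rep(0:1, each = 10)
  r1 <- permutation_equivalence_test(x, lab, "steiger", n_perm = 99, seed = 3)
  r2 <- permutation_equivalence_test(x, lab, "steiger", n_perm = 99, seed = 3)
  expect_identical(r1$p_simulated, r2$p_simulated)
  expect_true(r1$p_simulated >= 1 / 100 && r1$p_simulated <= 1)
  # label polarity does not matter
  r3 <- permutation_equivalence_test(x, 1 - lab, "steiger", n_perm = 99,
                                     seed = 3)
  expect_equal(r1$statistic, r3$statistic)
  expect_error(permutation_equivalence_test(x, c(rep(0, 17), rep(1, 3)),
                                            "steiger"), "too small")
})

test_that("exact enumeration matches a brute-force permutation distribution", {
  # n = 8 samples, 4 per class: 70 assignments, enumerated fully. Pearson
  # correlations: with 4-sample classes a Spearman of exactly +-1 occurs
  # in some assignments (rank-monotone splits) and the Fisher z diverges,
  # so the tiny-instance enumeration is a Pearson-world check.
  spec <- rewiring_spec(2, c(4, 4), diag(2), seed = 13)
  x <- generate_rewired_cohort(spec)$matrix
  lab <- rep(0:1, each = 4)
  res <- permutation_equivalence_test(x, lab, "steiger", exact = TRUE,
                                      cor_method = "pearson")
  expect_equal(res$n_null, choose(8, 4))
  # oracle: enumerate assignments independently and recompute the statistic
  vals <- apply(combn(8, 4), 2, function(i1) {
    r1 <- cor(t(unclass(x)[, i1]))
    r2 <- cor(t(unclass(x)[, -i1]))
    oracle_steiger(r1, r2, 4, 4)
  })
  expect_equal(sort(res$null_values), sort(vals), tolerance = 1e-10)
  expect_equal(res$p_simulated,
               mean(vals >= res$statistic - 1e-12))
})

test_that("permutation test has power against planted rewiring (scaled)", {
  hits <- 0L
  for (i in 1:5) {
    spec <- rewiring_spec(12, c(100, 100),
                          list(corr_block(12, 8, 0.8), diag(12)),
                          seed = 400 + i)
    cohort <- generate_rewired_cohort(spec)
    p <- permutation_equivalence_test(cohort$matrix, cohort$groups,
                                      "steiger", n_perm = 99,
                                      seed = 500 + i)$p_simulated
    if (p <= 0.01) hits <- hits + 1L
  }
  expect_equal(hits, 5L)
})
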