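test_that("rewired cohorts have the stated shape, labels and determinism", {
  G <- 224
  spec <- rewiring_spec(G, c(27, 7), diag(G), seed = 42)
  cohort <- generate_rewired_cohort(spec)
  expect_equal(dim(cohort$matrix), c(224, 34))
  expect_equal(cohort$groups, rep(1:2, c(27, 7)))
  # identical seed => identical output
  cohort2 <- generate_rewired_cohort(spec)
  expect_identical(unclass(cohort$matrix), unclass(cohort2$matrix))
  # different seed => different draws
  spec3 <- rewiring_spec(G, c(27, 7), diag(G), seed = 43)
  expect_false(identical(unclass(cohort$matrix),
                         unclass(generate_rewired_cohort(spec3)$matrix)))
})

test_that("invalid rewiring specs are rejected with diagnostics", {
  bad <- matrix(c(1, 0.9, 0.9, 1), 2)
  bad[1, 2] <- bad[2, 1] <- 1.5   # not a correlation matrix: indefinite
  expect_error(rewiring_spec(2, c(5, 5), bad), "positive semi-definite")
  expect_error(rewiring_spec(2, c(1, 5), diag(2)), "at least 2 samples")
  expect_error(rewiring_spec(3, c(5, 5), diag(2)))
})

test_that("empirical correlations converge to the planted block", {
  G <- 20
  RA <- corr_block(G, 10, 0.8)
  spec <- rewiring_spec(G, c(200, 200), list(RA, diag(G)), seed = 7)
  cohort <- generate_rewired_cohort(spec)
  XA <- cohort$matrix[, cohort$groups == 1]
  block_r <- cor(t(XA[1:10, ]))[upper.tri(diag(10))]
  expect_lt(abs(mean(block_r) - 0.8), 0.05)
  # equal-mean construction: per-gene group mean difference near 0
  d <- rowMeans(cohort$matrix[, cohort$groups == 1]) -
    rowMeans(cohort$matrix[, cohort$groups == 2])
  expect_lt(abs(mean(d)), 0.05)
})

test_that("sample correlations converge at roughly root-n rate", {
  G <- 10
  R <- corr_block(G, 5, 0.6)
  frob <- sapply(c(100, 1600), function(n) {
    errs <- sapply(1:8, function(i) {
      spec <- rewiring_spec(G, c(n, n), R, seed = 100 * n + i)
      X <- generate_rewired_cohort(spec)$matrix
      norm(cor(t(X[, 1:n])) - R, type = "F")
    })
    mean(errs)
  })
  # 16x the samples should shrink the error about 4x; allow slack
  expect_lt(frob[2], frob[1] / 2.5)
})

test_that("scaled-t marginals keep unit variance and target correlation", {
  G <- 6
  spec <- rewiring_spec(G, c(2000, 2000), corr_block(G, 3, 0.7),
                        noise_df = 5, seed = 11)
  X <- generate_rewired_cohort(spec)$matrix
  v <- apply(X[, 1:2000], 1, var)
  expect_true(all(abs(v - 1) < 0.25))
  expect_lt(abs(cor(X[1, 1:2000], X[2, 1:2000]) - 0.7), 0.06)
  expect_error(rewiring_spec(G, c(10, 10), diag(G), noise_df = 2) |>
                 generate_rewired_cohort(), "noise_df")
})

test_that("hub cohorts recover the hub and reject degenerate specs", {
  genes <- paste0("g", 1:12)
  hs <- hub_spec(genes, "g1", paste0("g", 2:11), r_hub = 0.7)
  x <- generate_hub_cohort(hs, 500, seed = 3)
  expect_equal(dim(x), c(12, 500))
  r_hub_emp <- mean(cor(x["g1", ], t(x[paste0("g", 2:11), ])))
  expect_lt(abs(r_hub_emp - 0.7), 0.07)
  # r_hub = 1 with one spoke is a degenerate duplication
  expect_error(hub_spec(genes, "g1", "g2", r_hub = 1), "degenerate")
  # PSD violation: background genes strongly tied to everything while
  # spokes stay nearly uncorrelated breaks transitivity bounds
  expect_error(hub_spec(genes, "g1", paste0("g", 2:11), r_hub = 0.1,
                        background_r = 0.9),
               "positive semi-definite")
})

test_that("r_hub = 0 background 0 gives exchangeable nodes (no hub)", {
  genes <- paste0("g", 1:8)
  hs <- hub_spec(genes, "g1", paste0("g", 2:7), r_hub = 1e-9)
  x <- generate_hub_cohort(hs, 2000, seed = 5)
  deg <- rowSums(abs(cor(t(unclass(x))))) - 1
  expect_lt(max(deg) - min(deg), 0.25 * mean(deg) + 0.3)
})

test_that("mutation labels respect the stated odds ratio", {
  cl <- rep(1:2, each = 5000)
  # odds_ratio = 1: logistic coefficient ~ 0
  y0 <- generate_mutation_labels(cl, odds_ratio = 1, seed = 9)
  f0 <- glm(y0 ~ factor(cl), family = binomial())
  expect_lt(abs(summary(f0)$coefficients[2, "z value"]), 3)
  # odds_ratio = e: recovered coefficient ~ 1
  y1 <- generate_mutation_labels(cl, odds_ratio = exp(1), seed = 9)
  f1 <- glm(y1 ~ factor(cl), family = binomial())
  expect_lt(abs(coef(f1)[2] - 1), 0.1)
  # determinism
  expect_identical(y0, generate_mutation_labels(cl, odds_ratio = 1, seed = 9))
  # single cluster: warning, base-rate draw
  expect_warning(generate_mutation_labels(rep(1, 10), 2), "single cluster")
})

test_that("nearest_psd repairs a slightly indefinite matrix", {
  R <- matrix(0.7, 3, 3); diag(R) <- 1
  R[1, 2] <- R[2, 1] <- -0.7   # indefinite combination
  expect_warning(R2 <- nearest_psd(R), "repaired")
  ev <- eigen(R2, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-10)
  expect_equal(diag(R2), rep(1, 3))
  # a valid matrix passes through untouched
  expect_identical(nearest_psd(diag(3)), diag(3))
})
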