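# Result container shared by all equivalence-style tests.
equiv_test_result <- function(statistic_name, statistic, df = NA_integer_,
                              p_asymptotic = NA_real_, p_simulated = NA_real_,
                              n_null = NA_integer_, extra = NULL) {
  out <- list(statistic_name = statistic_name, statistic = statistic,
              df = df, p_asymptotic = p_asymptotic,
              p_simulated = p_simulated, n_null = n_null)
  if (!is.null(extra)) out <- c(out, extra)
  class(out) <- "EquivTestResult"
  out
}

#' @export
print.EquivTestResult <- function(x, ...) {
  cat(sprintf("%s = %.4f", x$statistic_name, x$statistic))
  if (!is.na(x$df)) cat(sprintf(", df = %s", format(x$df)))
  if (!is.na(x$p_asymptotic)) cat(sprintf(", p = %.3g", x$p_asymptotic))
  if (!is.na(x$p_simulated)) {
    cat(sprintf(", simulated p = %.3g (n_null = %d)", x$p_simulated, x$n_null))
  }
  cat("\n")
  invisible(x)
}

#' Correlation matrix of an expression cohort
#'
#' `spearman_corr` computes the gene-by-gene Spearman (default) or Pearson
#' correlation matrix across samples together with matched two-sided
#' p-values from the t approximation t = r * sqrt((n-2)/(1-r^2)) on n - 2
#' degrees of freedom. Ties are handled by average ranks. A constant gene
#' (zero rank variance) gets correlation 0 against everything, is flagged
#' in the `constant_genes` attribute, and triggers a warning.
#'
#' @param x expression matrix (genes x samples), >= 4 samples.
#' @param method `"spearman"` (default, the pipeline's choice) or
#'   `"pearson"` (used by Gaussian calibration checks).
#' @return object of class `CorrMatrix`: list with `r` (G x G correlations),
#'   `p` (matched p-values, 0 on the diagonal), `n_samples`, `method`,
#'   `gene_ids`.
#' @export
spearman_corr <- function(x, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  x <- as_expression_matrix(x)
  n <- ncol(x)
  if (n < 4) stop("need >= 4 samples for a correlation matrix with p-values")
  Y <- t(unclass(x))
  const <- apply(Y, 2L, function(v) length(unique(v)) == 1L)
  if (any(const)) {
    warning("constant gene(s), correlations set to 0: ",
            paste(rownames(x)[const], collapse = ", "))
  }
  r <- suppressWarnings(stats::cor(Y, method = method))
  r[is.na(r)] <- 0
  diag(r) <- 1
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  p[abs(r) >= 1] <- 0
  diag(p) <- 0
  structure(list(r = r, p = p, n_samples = n, method = method,
                 gene_ids = rownames(x),
                 constant_genes = rownames(x)[const]),
            class = "CorrMatrix")
}

#' Construct a correlation matrix object directly
#'
#' For use when a correlation matrix and its sample size are already in
#' hand (e.g. a published matrix). Validates symmetry, unit diagonal and
#' range.
#'
#' @param r G x G correlation matrix.
#' @param n_samples sample size the matrix was estimated from.
#' @param method correlation method label.
#' @param gene_ids gene identifiers (default from dimnames).
#' @return a `CorrMatrix`.
#' @export
corr_matrix <- function(r, n_samples, method = "spearman",
                        gene_ids = rownames(r)) {
  r <- as.matrix(r)
  if (!isSymmetric(unname(r), tol = 1e-8)) stop("correlation matrix not symmetric")
  if (any(abs(diag(r) - 1) > 1e-8)) stop("diagonal must be 1")
  if (any(abs(r) > 1 + 1e-12)) stop("correlations must lie in [-1, 1]")
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(nrow(r)))
  dimnames(r) <- list(gene_ids, gene_ids)
  structure(list(r = r, p = NULL, n_samples = as.integer(n_samples),
                 method = method, gene_ids = gene_ids,
                 constant_genes = character(0)),
            class = "CorrMatrix")
}

as_corr <- function(x, method = "spearman") {
  if (inherits(x, "CorrMatrix")) return(x)
  spearman_corr(x, method = method)
}

check_same_genes <- function(R1, R2) {
  if (nrow(R1$r) != nrow(R2$r) || !identical(R1$gene_ids, R2$gene_ids)) {
    stop("the two correlation matrices must share the same genes in the same order")
  }
}

#' Steiger test of correlation-matrix equality
#'
#' Compares two correlation matrices entrywise via Fisher's z transform:
#' chi^2 = sum over gene pairs i < j of (z1_ij - z2_ij)^2 /
#' (1/(n1-3) + 1/(n2-3)), referred to a chi-square distribution on
#' G(G-1)/2 degrees of freedom. Emphasises the aggregate magnitude of
#' correlation differences.
#'
#' @param R1,R2 `CorrMatrix` objects over the same genes, each with more
#'   than 3 samples.
#' @return an `EquivTestResult` with `statistic_name = "steiger_chisq"`.
#' @export
steiger_test <- function(R1, R2) {
  R1 <- as_corr(R1); R2 <- as_corr(R2)
  check_same_genes(R1, R2)
  if (R1$n_samples <= 3 || R2$n_samples <= 3) {
    stop("Steiger test needs more than 3 samples per group")
  }
  G <- nrow(R1$r)
  up <- upper.tri(R1$r)
  r1 <- R1$r[up]; r2 <- R2$r[up]
  if (any(abs(r1) >= 1) || any(abs(r2) >= 1)) {
    idx <- which(up, arr.ind = TRUE)[abs(r1) >= 1 | abs(r2) >= 1, , drop = FALSE]
    stop("off-diagonal |r| = 1 for pair(s) ",
         paste(apply(idx, 1L, function(b)
           paste(R1$gene_ids[b], collapse = "-")), collapse = ", "),
         ": Fisher z diverges")
  }
  v <- 1 / (R1$n_samples - 3) + 1 / (R2$n_samples - 3)
  stat <- sum((atanh(r1) - atanh(r2))^2) / v
  df <- G * (G - 1) / 2
  equiv_test_result("steiger_chisq", stat, df = df,
                    p_asymptotic = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Jennrich test of correlation-matrix equality
#'
#' Standardises the difference of two correlation matrices against their
#' sample-size-weighted average: with Rbar = (n1 R1 + n2 R2)/(n1 + n2) and
#' c = n1 n2/(n1 + n2), Z = sqrt(c) Rbar^{-1} (R1 - R2), the statistic is
#' chi^2 = tr(Z^2)/2 - diag(Z)' S^{-1} diag(Z) where
#' S = I + Rbar * Rbar^{-1} (elementwise product), on G(G-1)/2 degrees of
#' freedom. Emphasises changes in correlation relative to the pooled
#' structure.
#'
#' When the pooled matrix is singular (possible when samples do not exceed
#' genes) a shrinkage option Rbar <- (1-lambda) Rbar + lambda I is
#' available; the result is then flagged approximate.
#'
#' @param R1,R2 `CorrMatrix` objects over the same genes.
#' @param shrinkage `NULL` (default, error on singular pooled matrix) or a
#'   shrinkage weight lambda in (0, 1), e.g. 0.1.
#' @return an `EquivTestResult` with `statistic_name = "jennrich_chisq"`.
#' @export
jennrich_test <- function(R1, R2, shrinkage = NULL) {
  R1 <- as_corr(R1); R2 <- as_corr(R2)
  check_same_genes(R1, R2)
  n1 <- R1$n_samples; n2 <- R2$n_samples
  G <- nrow(R1$r)
  Rbar <- (n1 * R1$r + n2 * R2$r) / (n1 + n2)
  shrunk <- FALSE
  if (!is.null(shrinkage)) {
    stopifnot(shrinkage > 0, shrinkage < 1)
    Rbar <- (1 - shrinkage) * Rbar + shrinkage * diag(G)
    shrunk <- TRUE
  }
  Rinv <- tryCatch(solve(Rbar), error = function(e) NULL)
  if (is.null(Rinv)) {
    stop("pooled correlation matrix is singular; enable shrinkage ",
         "(e.g. shrinkage = 0.1) or use the Steiger test")
  }
  cc <- n1 * n2 / (n1 + n2)
  Z <- sqrt(cc) * Rinv %*% (R1$r - R2$r)
  S <- diag(G) + Rbar * Rinv
  stat <- sum(diag(Z %*% Z)) / 2 -
    drop(t(diag(Z)) %*% solve(S, diag(Z)))
  df <- G * (G - 1) / 2
  equiv_test_result("jennrich_chisq", stat, df = df,
                    p_asymptotic = stats::pchisq(stat, df, lower.tail = FALSE),
                    extra = list(shrinkage = if (shrunk) shrinkage else 0))
}

#' Permutation test of correlation-matrix equality between labelled groups
#'
#' Computes the observed Steiger or Jennrich statistic between the two
#' label classes, then permutes the labels `n_perm` times (preserving class
#' sizes), recomputes the statistic, and reports the empirical p-value
#' under the (count + 1)/(N + 1) convention. With `exact = TRUE` and a
#' feasible number of distinct class assignments (`choose(n, n1)` up to
#' `exact_cap`), the full assignment distribution is enumerated instead.
#'
#' @param x expression matrix.
#' @param labels binary labels per sample (each class >= 4 samples).
#' @param method `"steiger"` or `"jennrich"`.
#' @param n_perm number of label permutations (default 10000).
#' @param seed integer seed.
#' @param cor_method correlation method, `"spearman"` (default) or
#'   `"pearson"`.
#' @param shrinkage passed to [jennrich_test()].
#' @param exact enumerate all class assignments instead of sampling.
#' @param exact_cap largest enumeration size allowed for `exact = TRUE`.
#' @return an `EquivTestResult`; the permutation null values are attached
#'   as `null_values`.
#' @export
permutation_equivalence_test <- function(x, labels,
                                         method = c("steiger", "jennrich"),
                                         n_perm = 10000, seed = 1L,
                                         cor_method = "spearman",
                                         shrinkage = NULL,
                                         exact = FALSE, exact_cap = 20000) {
  method <- match.arg(method)
  x <- as_expression_matrix(x)
  stopifnot(length(labels) == ncol(x))
  f <- factor(labels)
  if (nlevels(f) != 2L) stop("labels must have exactly 2 classes")
  sizes <- table(f)
  small <- names(sizes)[sizes < 4]
  if (length(small)) {
    stop("label class too small (need >= 4 samples): ",
         paste(small, collapse = ", "))
  }
  idx1 <- which(f == levels(f)[1L])
  stat_fun <- function(i1) {
    i2 <- setdiff(seq_len(ncol(x)), i1)
    C1 <- spearman_corr(x[, i1, drop = FALSE], method = cor_method)
    C2 <- spearman_corr(x[, i2, drop = FALSE], method = cor_method)
    if (method == "steiger") steiger_test(C1, C2)$statistic
    else jennrich_test(C1, C2, shrinkage = shrinkage)$statistic
  }
  observed <- stat_fun(idx1)
  n <- ncol(x)
  if (exact && choose(n, length(idx1)) <= exact_cap) {
    combs <- utils::combn(n, length(idx1))
    null_values <- apply(combs, 2L, stat_fun)
    # exact enumeration: p is the proportion of assignments (including the
    # observed one, which is in the enumeration) at least as extreme
    p <- mean(null_values >= observed - 1e-12)
    n_null <- ncol(combs)
  } else {
    set.seed(as_seed(seed))
    null_values <- vapply(seq_len(n_perm), function(b) {
      stat_fun(sample.int(n, length(idx1)))
    }, numeric(1))
    p <- empirical_pvalue(observed, null_values)
    n_null <- n_perm
  }
  res <- equiv_test_result(
    if (method == "steiger") "steiger_chisq" else "jennrich_chisq",
    observed, df = nrow(x) * (nrow(x) - 1) / 2,
    p_simulated = p, n_null = n_null,
    extra = list(null_values = null_values, exact = exact))
  res
}
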