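# Independent oracles used to check the package's implementations. Each is
# written from the defining formula, deliberately naive (enumeration or
# direct summation), and shares no code path with the package.

# Adjusted Rand index between two label vectors.
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  maxidx <- (si + sj) / 2
  if (maxidx == expected) return(1)
  (sij - expected) / (maxidx - expected)
}

# Exhaustive shortest-path betweenness with fractional credit: enumerate
# all simple paths per pair by depth-first search. lengths: matrix of edge
# lengths (Inf = no edge). Feasible for <= 7 nodes.
oracle_betweenness <- function(lengths) {
  n <- nrow(lengths)
  bt <- numeric(n)
  all_paths <- function(s, t) {
    out <- list()
    walk <- function(path, len) {
      v <- path[length(path)]
      if (v == t) { out[[length(out) + 1L]] <<- list(path = path, len = len); return() }
      for (u in seq_len(n)) {
        if (is.finite(lengths[v, u]) && !(u %in% path)) {
          walk(c(path, u), len + lengths[v, u])
        }
      }
    }
    walk(s, 0)
    out
  }
  for (s in 1:(n - 1)) for (t in (s + 1):n) {
    paths <- all_paths(s, t)
    if (length(paths) == 0L) next
    lens <- vapply(paths, `[[`, numeric(1), "len")
    shortest <- paths[abs(lens - min(lens)) < 1e-12]
    sigma <- length(shortest)
    for (p in shortest) {
      inner <- setdiff(p$path, c(s, t))
      bt[inner] <- bt[inner] + 1 / sigma
    }
  }
  bt
}

# Brute-force Benjamini-Hochberg step-up: literal definition,
# adj_i = min_{j: p_(j) >= p_(i)... } -- computed as min over j >= rank(i)
# of m * p_(j) / j, capped at 1.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj_sorted <- numeric(m)
  for (i in seq_len(m)) {
    adj_sorted[i] <- min(1, min(m * p[ord][i:m] / (i:m)))
  }
  out <- numeric(m)
  out[ord] <- adj_sorted
  out
}

# Steiger chi-square from the defining sum, written independently.
oracle_steiger <- function(r1, r2, n1, n2) {
  G <- nrow(r1)
  acc <- 0
  for (i in 1:(G - 1)) for (j in (i + 1):G) {
    acc <- acc + (atanh(r1[i, j]) - atanh(r2[i, j]))^2
  }
  acc / (1 / (n1 - 3) + 1 / (n2 - 3))
}

# Generate a small random connected weighted graph as a weight matrix
# (weights in (0, 1]), for betweenness cross-checks.
random_weight_graph <- function(n, seed) {
  set.seed(seed)
  W <- matrix(0, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (stats::runif(1) < 0.6) W[i, j] <- W[j, i] <- stats::runif(1, 0.1, 1)
  }
  # ensure connectivity via a ring
  for (i in 1:n) {
    j <- if (i == n) 1L else i + 1L
    if (W[i, j] == 0) W[i, j] <- W[j, i] <- stats::runif(1, 0.1, 1)
  }
  dimnames(W) <- list(paste0("g", 1:n), paste0("g", 1:n))
  W
}

# Wrap a weight matrix as a GeneNetwork without touching build_network.
network_from_weights <- function(W) {
  idx <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  structure(list(nodes = rownames(W),
                 edges = data.frame(gene_i = rownames(W)[idx[, 1]],
                                    gene_j = rownames(W)[idx[, 2]],
                                    r = sqrt(W[idx]), r2 = W[idx],
                                    p = rep(0, nrow(idx)),
                                    stringsAsFactors = FALSE),
                 weights = W, alpha = 0.05, n_samples = NA_integer_),
            class = "GeneNetwork")
}
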