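# Polynomial rolling hash of a character scalar, reported as 8 hex
# digits; stamps outputs with a configuration fingerprint without
# external deps. Kept below 2^31 so double arithmetic stays exact.
fnv1a_hash <- function(txt) {
  bytes <- utf8ToInt(paste(txt, collapse = "\n"))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

# Named per-stage substreams from one master seed (kept below 2^31).
stage_seed <- function(master, stage) {
  offs <- c(cluster = 11L, significance = 23L, network = 37L,
            modules = 41L, matequiv = 53L, simulate = 61L)
  as_seed(as.numeric(master) * 1009 + offs[[stage]])
}

#' Assemble a run configuration
#'
#' Collects the pipeline's tunable constants with defaults matching the
#' analysis' stated conventions: S = 1000 bootstrap simulations, N = 10000
#' label permutations, edge-retention alpha = 0.05, strong-edge threshold
#' 0.7, k = 2 mixture components, module counts 10 and 20.
#'
#' @param input path to an expression TSV (or an expression matrix).
#' @param panel optional gene-panel file or character vector.
#' @param annotation optional annotation TSV path or data.frame.
#' @param k mixture components.
#' @param S bootstrap simulations.
#' @param N label permutations.
#' @param alpha edge-retention p-value threshold.
#' @param strong_threshold strong-edge |r| cutoff.
#' @param module_k module counts to fit.
#' @param beta soft-threshold exponent for module detection.
#' @param seed master seed; per-stage substreams are derived from it.
#' @param outdir output directory.
#' @param drug_table optional drug-gene TSV path (`NULL` = packaged
#'   fixture).
#' @return object of class `RunConfig`.
#' @export
run_config <- function(input, panel = NULL, annotation = NULL, k = 2,
                       S = 1000, N = 10000, alpha = 0.05,
                       strong_threshold = 0.7, module_k = c(10, 20),
                       beta = 6, seed = 1L, outdir = ".",
                       drug_table = NULL) {
  structure(list(input = input, panel = panel, annotation = annotation,
                 k = k, S = S, N = N, alpha = alpha,
                 strong_threshold = strong_threshold, module_k = module_k,
                 beta = beta, seed = as_seed(seed), outdir = outdir,
                 drug_table = drug_table),
            class = "RunConfig")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose keys match the [run_config()] arguments.
#' @return a `RunConfig`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

# Fingerprint of the analysis parameters (not of file locations), so the
# same analysis produces byte-identical reports wherever it is written.
config_stamp <- function(config) {
  keys <- c("k", "S", "N", "alpha", "strong_threshold", "module_k",
            "beta", "seed")
  flat <- config[keys]
  txt <- paste(keys, vapply(flat, function(v)
    paste(format(v), collapse = ","), character(1)), sep = "=")
  fnv1a_hash(txt)
}

load_config_input <- function(config) {
  x <- config$input
  if (is.character(x)) x <- read_expression_tsv(x)
  x <- as_expression_matrix(x)
  if (!is.null(config$panel)) {
    panel <- config$panel
    if (length(panel) == 1L && file.exists(panel)) panel <- readLines(panel)
    x <- extract_panel(x, panel)$matrix
  }
  x
}

write_report_tsv <- function(df, path, config) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# rewirekit config=%s seed=%d",
                     config_stamp(config), config$seed), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

results_to_df <- function(results) {
  do.call(rbind, lapply(results, function(r) {
    data.frame(statistic_name = r$statistic_name,
               statistic = r$statistic,
               df = if (is.null(r$df) || is.na(r$df)) NA else r$df,
               p_asymptotic = if (is.null(r$p_asymptotic)) NA else r$p_asymptotic,
               p_simulated = if (is.null(r$p_simulated)) NA else r$p_simulated,
               n_null = if (is.null(r$n_null)) NA else r$n_null,
               stringsAsFactors = FALSE)
  }))
}

#' Run the unsupervised rewiring analysis
#'
#' Cluster samples with a k-component mixture, attach bootstrap
#' significance for the mean-equality, correlation-equality and
#' model-selection statistics, build one thresholded correlation network
#' per mixture group, call per-group consensus hubs, and map them to
#' candidate drugs. All outputs are written as TSV under
#' `config$outdir` with a config-hash/seed stamp, and also returned.
#'
#' @param config a [run_config()].
#' @return list with `labels`, `significance` (statistic table),
#'   `centrality` (per-group centrality + consensus + drugs table),
#'   `networks` (list of `GeneNetwork`), invisibly writing
#'   `labels.tsv`, `significance.tsv`, `centrality.tsv`.
#' @export
run_unsupervised <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  x <- load_config_input(config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  omni <- omnibus_rewiring_test(x, k = config$k, S = config$S,
                                seed = stage_seed(config$seed, "significance"))
  labels <- attr(omni, "labels")
  sig <- results_to_df(omni)
  drug_tab <- read_drug_gene_table(config$drug_table)
  groups <- sort(unique(labels))
  networks <- list(); cent_rows <- list()
  for (g in groups) {
    sel <- labels == g
    if (sum(sel) < 4L) next
    net <- build_network(x[, sel, drop = FALSE], alpha = config$alpha)
    networks[[paste0("K", g)]] <- net
    recs <- centralities(net)
    hub <- consensus_hub(recs)
    drugs <- map_genes_to_drugs(hub$consensus, drug_tab)
    cent_rows[[paste0("K", g)]] <- data.frame(
      group = paste0("K", g),
      degree_top = paste(hub$per_metric$degree, collapse = ", "),
      closeness_top = paste(hub$per_metric$closeness, collapse = ", "),
      betweenness_top = paste(hub$per_metric$betweenness, collapse = ", "),
      eigenvector_top = paste(hub$per_metric$eigenvector, collapse = ", "),
      consensus = paste(hub$consensus, collapse = ", "),
      drugs = paste(unique(unlist(drugs)), collapse = ", "),
      stringsAsFactors = FALSE)
  }
  cent <- do.call(rbind, cent_rows)
  write_labels_tsv(stats::setNames(labels, colnames(x)),
                   file.path(config$outdir, "labels.tsv"),
                   colname = "cluster")
  write_report_tsv(sig, file.path(config$outdir, "significance.tsv"), config)
  write_report_tsv(cent, file.path(config$outdir, "centrality.tsv"), config)
  list(labels = stats::setNames(labels, colnames(x)), significance = sig,
       centrality = cent, networks = networks)
}

#' Run the supervised rewiring analysis
#'
#' Stratifies samples by a binary annotation column and emits: the
#' Steiger and Jennrich equivalence tests with label-permutation p-values;
#' per-group centralities with the cross-group centrality correlation; and
#' a module-rewiring report (modules detected in the reference/wild-type
#' group at each `module_k`, matched by maximal overlap into the mutant
#' group, with permutation overlap p-values and per-module Steiger
#' rewiring tests on the intersections).
#'
#' @param config a [run_config()]; `config$annotation` must be set.
#' @param column annotation column holding the binary status.
#' @return list with `equivalence`, `centrality_correlation`, `modules`
#'   data.frames (also written as TSV under `config$outdir`).
#' @export
run_supervised <- function(config, column) {
  stopifnot(inherits(config, "RunConfig"))
  x <- load_config_input(config)
  ann <- config$annotation
  if (is.character(ann)) ann <- read_annotation_tsv(ann, x)
  stopifnot(is.data.frame(ann), column %in% names(ann))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  m <- match(colnames(x), ann$sample_id)
  if (anyNA(m)) stop("samples without annotation: ",
                     paste(colnames(x)[is.na(m)], collapse = ", "))
  status <- ann[[column]][m]
  if (length(unique(status)) != 2L) stop("annotation column must be binary")
  seedM <- stage_seed(config$seed, "matequiv")
  eq <- lapply(c("steiger", "jennrich"), function(meth) {
    permutation_equivalence_test(
      x, status, method = meth, n_perm = config$N, seed = seedM,
      shrinkage = if (meth == "jennrich" && ncol(x) <= nrow(x)) 0.1 else NULL)
  })
  eq_df <- results_to_df(eq)
  # per-group centralities and their cross-group correlation
  pos <- x[, status == sort(unique(status))[2L], drop = FALSE]
  neg <- x[, status == sort(unique(status))[1L], drop = FALSE]
  rec_pos <- centralities(build_network(pos, alpha = config$alpha))
  rec_neg <- centralities(build_network(neg, alpha = config$alpha))
  cc <- centrality_correlation(rec_pos, rec_neg)
  cc_df <- data.frame(metric = c(names(cc$per_metric), "average"),
                      r = c(unname(cc$per_metric), cc$average))
  # module report: reference partition is the first (wild-type-like) class
  seedB <- stage_seed(config$seed, "modules")
  mod_rows <- list()
  for (kk in config$module_k) {
    if (nrow(x) < kk) next
    pref <- detect_modules(neg, k = kk, beta = config$beta)
    pmut <- detect_modules(pos, k = kk, beta = config$beta)
    ov <- overlap_permutation_null(pref, pmut, B = max(99, min(config$N, 1000)),
                                   seed = seedB)
    for (mrow in seq_len(nrow(ov))) {
      genes <- names(pref$labels)[pref$labels == ov$ref_module[mrow]]
      genes <- intersect(genes,
                         names(pmut$labels)[pmut$labels == ov$matched_module[mrow]])
      rt <- module_rewiring_test(x, status, genes,
                                 n_perm = max(99, min(config$N, 1000)),
                                 seed = seedB + mrow)
      mod_rows[[length(mod_rows) + 1L]] <- data.frame(
        module_k = kk, module = ov$ref_module[mrow],
        size = ov$ref_size[mrow], matched_module = ov$matched_module[mrow],
        overlap = ov$overlap[mrow], overlap_p = ov$p[mrow],
        intersection_size = length(genes),
        rewiring_chisq = rt$statistic, rewiring_p = rt$p_simulated,
        stringsAsFactors = FALSE)
    }
  }
  mod_df <- do.call(rbind, mod_rows)
  write_report_tsv(eq_df, file.path(config$outdir, "equivalence.tsv"), config)
  write_report_tsv(cc_df, file.path(config$outdir,
                                    "centrality_correlation.tsv"), config)
  if (!is.null(mod_df)) {
    write_report_tsv(mod_df, file.path(config$outdir, "modules.tsv"), config)
  }
  list(equivalence = eq_df, centrality_correlation = cc_df,
       modules = mod_df)
}
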