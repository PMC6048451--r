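#' Construct an expression matrix
#'
#' The central data container: a genes x samples matrix of normalized
#' (log-intensity scale) expression values with unique gene and sample
#' identifiers. All downstream stages (clustering, correlation tests,
#' networks, modules) consume this object; most accept a plain numeric
#' matrix with dimnames as well.
#'
#' @param values numeric matrix, genes in rows, samples in columns.
#' @param gene_ids character vector of unique gene identifiers; defaults to
#'   `rownames(values)`.
#' @param sample_ids character vector of unique sample identifiers; defaults
#'   to `colnames(values)`.
#' @return a numeric matrix of class `ExpressionMatrix` with dimnames set.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values)) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("expression values must be numeric")
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(nrow(values)))
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(ncol(values)))
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != nrow(values)) {
    stop("gene_ids length (", length(gene_ids), ") != number of rows (",
         nrow(values), ")")
  }
  if (length(sample_ids) != ncol(values)) {
    stop("sample_ids length (", length(sample_ids), ") != number of columns (",
         ncol(values), ")")
  }
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene identifiers: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample identifiers: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)
    stop("non-finite expression values, e.g. at [",
         bad[1, 1], ",", bad[1, 2], "]")
  }
  dimnames(values) <- list(gene_ids, sample_ids)
  class(values) <- c("ExpressionMatrix", class(values))
  values
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat("ExpressionMatrix:", nrow(x), "genes x", ncol(x), "samples\n")
  invisible(x)
}

# Coerce input to a validated genes x samples matrix.
as_expression_matrix <- function(x) {
  if (inherits(x, "ExpressionMatrix")) return(x)
  expression_matrix(x)
}

#' Read an expression matrix from TSV
#'
#' Expected dialect: UTF-8, tab-separated, header row of sample identifiers,
#' first column named `gene_id` holding gene identifiers, remaining columns
#' numeric (scientific notation accepted). Missing or non-numeric cells are a
#' hard error listing the offending cells: the pipeline assumes complete
#' matrices.
#'
#' @param path file path.
#' @return an [expression_matrix()].
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "", comment.char = "")
  if (ncol(df) < 2) stop("expression TSV needs a gene_id column plus samples")
  gene_ids <- as.character(df[[1L]])
  vals <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(vals) <- "double"
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)
    msg <- apply(utils::head(bad, 10), 1L, function(b)
      paste0(gene_ids[b[1]], "/", colnames(vals)[b[2]]))
    stop("missing or non-numeric cells in ", path, ": ",
         paste(msg, collapse = ", "),
         if (nrow(bad) > 10) sprintf(" (and %d more)", nrow(bad) - 10) else "")
  }
  expression_matrix(vals, gene_ids, colnames(vals))
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression_tsv()]; round trips are value-exact to at
#' least 12 significant digits (values are written with 17 digits).
#'
#' @param x expression matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(x, path) {
  x <- as_expression_matrix(x)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("gene_id", colnames(x)), collapse = "\t"), con)
  body <- apply(format(unclass(x), digits = 17, trim = TRUE, scientific = NA),
                1L, paste, collapse = "\t")
  writeLines(paste(rownames(x), body, sep = "\t"), con)
  invisible(path)
}

#' Read a sample annotation table
#'
#' TSV with a `sample_id` first column and named binary mutation-status
#' columns (e.g. `BRAF`, `BRAF_V600E`, `KRAS`, `NRAS`). When `expr` is
#' supplied, annotated samples that do not resolve to a matrix column are
#' reported via a warning (never silently dropped).
#'
#' @param path file path.
#' @param expr optional expression matrix to match sample ids against.
#' @return data.frame with `sample_id` first.
#' @export
read_annotation_tsv <- function(path, expr = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "", comment.char = "")
  if (names(df)[1L] != "sample_id") {
    stop("annotation TSV must have 'sample_id' as its first column")
  }
  df$sample_id <- as.character(df$sample_id)
  if (!is.null(expr)) {
    expr <- as_expression_matrix(expr)
    unmatched <- setdiff(df$sample_id, colnames(expr))
    if (length(unmatched)) {
      warning("annotated samples not present in the expression matrix: ",
              paste(unmatched, collapse = ", "))
    }
  }
  df
}

#' Write sample labels as a two-column TSV
#'
#' @param labels vector of labels, named by sample id (or use `sample_ids`).
#' @param path output path.
#' @param sample_ids optional explicit sample identifiers.
#' @param colname name for the label column.
#' @return `path`, invisibly.
#' @export
write_labels_tsv <- function(labels, path, sample_ids = names(labels),
                             colname = "label") {
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_along(labels))
  df <- data.frame(sample_id = sample_ids, label = as.vector(labels),
                   stringsAsFactors = FALSE)
  names(df)[2L] <- colname
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Collapse probesets to genes by maximum average intensity
#'
#' Microarray platforms interrogate a gene with several probesets; for each
#' gene the probeset with the largest across-sample mean intensity is kept
#' and relabelled with the gene symbol. Probesets absent from the map, and
#' genes with no mapped probeset present in the matrix, are dropped and
#' reported. Exact ties in mean intensity are broken toward the
#' lexicographically smallest probeset id (and logged via message).
#'
#' Probesets annotated to several genes keep their composite label verbatim
#' (e.g. `"SYNGAP1, ZBTB9"`): downstream stages treat it as one node.
#'
#' @param x expression matrix keyed by probeset id.
#' @param probe_map data.frame with columns `probeset_id`, `gene_id`.
#' @return an [expression_matrix()] keyed by gene, with attributes
#'   `dropped_genes` (mapped genes with no probeset in the matrix) and
#'   `tied_genes` (genes whose winner was tie-broken).
#' @export
collapse_probesets <- function(x, probe_map) {
  x <- as_expression_matrix(x)
  if (!all(c("probeset_id", "gene_id") %in% names(probe_map))) {
    stop("probe_map needs columns 'probeset_id' and 'gene_id'")
  }
  probe_map <- probe_map[probe_map$probeset_id %in% rownames(x), , drop = FALSE]
  if (nrow(probe_map) == 0L) {
    stop("no probeset in the map matches the expression matrix")
  }
  dropped <- setdiff(unique(as.character(probe_map$gene_id)), character(0))
  means <- rowMeans(x)[probe_map$probeset_id]
  # deterministic winner: order by gene, then descending mean, then probeset id
  ord <- order(probe_map$gene_id, -means, probe_map$probeset_id)
  pm <- probe_map[ord, , drop = FALSE]
  keep <- !duplicated(pm$gene_id)
  winners <- pm[keep, , drop = FALSE]
  # detect exact ties between winner and runner-up
  tied <- character(0)
  if (any(!keep)) {
    runner <- pm[!keep & !duplicated(pm$gene_id[!keep]), , drop = FALSE]
    m <- match(runner$gene_id, winners$gene_id)
    tie <- means[runner$probeset_id] == means[winners$probeset_id[m]]
    tied <- unique(as.character(runner$gene_id[tie]))
    if (length(tied)) {
      message("tie in mean intensity broken by probeset id for: ",
              paste(tied, collapse = ", "))
    }
  }
  out <- x[winners$probeset_id, , drop = FALSE]
  res <- expression_matrix(unclass(out), winners$gene_id, colnames(x))
  attr(res, "dropped_genes") <- setdiff(unique(probe_map$gene_id),
                                        winners$gene_id)
  attr(res, "tied_genes") <- tied
  res
}

#' Restrict an expression matrix to a gene panel
#'
#' Row order follows the panel list. Panel genes absent from the matrix are
#' returned in `unmapped` and reported, never silently dropped. Duplicate
#' panel entries are deduplicated with a warning.
#'
#' @param x expression matrix.
#' @param panel character vector of gene identifiers.
#' @return list with `matrix` (the restricted [expression_matrix()]) and
#'   `unmapped` (panel genes not found).
#' @export
extract_panel <- function(x, panel) {
  x <- as_expression_matrix(x)
  panel <- as.character(panel)
  if (anyDuplicated(panel)) {
    warning("duplicate panel genes deduplicated: ",
            paste(unique(panel[duplicated(panel)]), collapse = ", "))
    panel <- unique(panel)
  }
  present <- panel[panel %in% rownames(x)]
  unmapped <- setdiff(panel, present)
  if (length(present) == 0L) stop("no panel gene maps to the matrix")
  if (length(unmapped)) {
    message(length(unmapped), " panel gene(s) not in matrix: ",
            paste(unmapped, collapse = ", "))
  }
  list(matrix = x[present, , drop = FALSE], unmapped = unmapped)
}

#' Packaged MAPK gene panel
#'
#' A 224-symbol gene panel shipped with the package, emulating a
#' WikiPathways-style MAPK (mitogen-activated protein kinase) pathway panel.
#' It mixes canonical MAPK-pathway symbols with synthetic filler symbols
#' (prefix `MAPKX`) and is intended for tests and examples, not biology.
#'
#' @return character vector of 224 gene symbols.
#' @export
mapk_panel <- function() {
  path <- system.file("extdata", "mapk_panel_224_synthetic.txt",
                      package = "rewirekit", mustWork = TRUE)
  readLines(path)
}
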