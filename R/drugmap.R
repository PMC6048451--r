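#' Read a drug-gene interaction table
#'
#' Two-column TSV (`gene_symbol`, `drug_name`), DGIdb-export style. Drug
#' names are uppercase-normalized, duplicate (gene, drug) rows dropped,
#' and gene lookups are case-insensitive. The packaged default is a small
#' synthetic fixture seeded with published gene-to-drug pairs for
#' proteasome, JAK, RAF/MEK and mTOR targets.
#'
#' @param path TSV path; `NULL` loads the packaged fixture.
#' @return object of class `DrugGeneTable` (a named list gene -> character
#'   vector of drugs).
#' @export
read_drug_gene_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "drug_gene_interactions_synthetic.tsv",
                        package = "rewirekit", mustWork = TRUE)
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene_symbol", "drug_name") %in% names(df)))
  gene <- toupper(trimws(df$gene_symbol))
  drug <- toupper(trimws(df$drug_name))
  keep <- !duplicated(paste(gene, drug, sep = "\r"))
  tab <- split(drug[keep], gene[keep])
  structure(tab, class = "DrugGeneTable")
}

#' Map genes to candidate drugs
#'
#' Exact-symbol, case-insensitive lookup of each gene in a drug-gene
#' interaction table. Composite node names (e.g. `"SYNGAP1, ZBTB9"`, a
#' probeset annotated to two genes) are split on commas and each symbol is
#' queried; results are pooled. Genes without any interaction map to
#' `"NA"`.
#'
#' @param genes character vector of gene symbols (composites allowed).
#' @param table a `DrugGeneTable` from [read_drug_gene_table()].
#' @return named list gene -> character vector of drug names (`"NA"` when
#'   empty).
#' @export
map_genes_to_drugs <- function(genes, table) {
  stopifnot(inherits(table, "DrugGeneTable"))
  out <- lapply(genes, function(g) {
    symbols <- toupper(trimws(strsplit(g, ",")[[1L]]))
    drugs <- unique(unlist(unclass(table)[symbols], use.names = FALSE))
    if (length(drugs) == 0L) "NA" else drugs
  })
  names(out) <- genes
  out
}
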