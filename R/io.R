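#' Read a normalized expression matrix from TSV
#'
#' Expects probes in rows and samples in columns, with a header row of sample
#' identifiers and the first column holding probe identifiers. Values are
#' log2-scale intensities (the convention of RMA-normalized microarray data).
#'
#' @param path TSV file path.
#' @return Numeric matrix with probe rownames and sample colnames.
#' @export
read_expression <- function(path) {
  df <- read_tsv(path)
  probes <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- probes
  stop_if_not(!anyDuplicated(rownames(m)), "duplicate probe identifiers in ", path)
  stop_if_not(!anyDuplicated(colnames(m)), "duplicate sample identifiers in ", path)
  stop_if_not(all(is.finite(m)), "non-finite expression values in ", path)
  m
}

#' Write an expression matrix to TSV
#'
#' @param matrix numeric matrix, probes in rows, samples in columns.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_expression <- function(matrix, path) {
  df <- data.frame(probe_id = rownames(matrix), matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Read a probe-to-gene map (columns `probe_id`, `gene_symbol`)
#' @param path TSV file path.
#' @return Data frame with columns `probe_id`, `gene_symbol`.
#' @export
read_probe_map <- function(path) {
  df <- read_tsv(path)
  stop_if_not(all(c("probe_id", "gene_symbol") %in% names(df)),
              "probe map must have columns probe_id and gene_symbol")
  df$gene_symbol <- norm_genes(df$gene_symbol)
  df
}

#' Read a sample annotation table (columns `sample_id`, `compound`, `role`, `replicate`)
#'
#' `role` is `treated` or `vehicle`; every treated sample names a compound.
#'
#' @param path TSV file path.
#' @return Data frame of the annotation.
#' @export
read_annotation <- function(path) {
  df <- read_tsv(path)
  need <- c("sample_id", "compound", "role", "replicate")
  stop_if_not(all(need %in% names(df)),
              "annotation must have columns ", paste(need, collapse = ", "))
  validate_annotation(df)
  df
}

validate_annotation <- function(annotation) {
  stop_if_not(any(annotation$role == "vehicle"),
              "annotation contains no vehicle sample")
  treated <- annotation[annotation$role == "treated", ]
  stop_if_not(all(nzchar(treated$compound)),
              "every treated sample must name a compound")
  invisible(annotation)
}

#' Write gene sets in GMT format
#'
#' One line per set: set name, description, then member genes, tab-separated.
#' Signature sets are written as two lines per compound, `<compound>_UP` and
#' `<compound>_DOWN`.
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional character vector of per-set descriptions
#'   (defaults to the set names).
#' @return The path, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = names(sets)) {
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file path.
#' @return Named list of character gene vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) if (length(p) > 2) p[-(1:2)] else character(0))
  names(sets) <- vapply(parts, `[[`, character(1), 1)
  sets
}

#' Write a network in SIF (simple interaction format) for Cytoscape
#'
#' @param from,to character vectors of node names (same length).
#' @param relation interaction type written in the middle column.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_sif <- function(from, to, relation, path) {
  writeLines(paste(from, relation, to, sep = "\t"), path)
  invisible(path)
}

#' Read a STRING-dialect protein-protein interaction edge list
#'
#' Accepts space- or tab-separated files with columns `protein1`, `protein2`,
#' `combined_score`; scores are integers on a 0-1000 scale in the file and are
#' normalized to `[0, 1]` on read (so a 0.9 threshold corresponds to 900).
#'
#' @param path edge list path.
#' @return Data frame with columns `gene_a`, `gene_b`, `score` (in `[0, 1]`).
#' @export
read_string_links <- function(path) {
  df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                          check.names = FALSE)
  need <- c("protein1", "protein2", "combined_score")
  stop_if_not(all(need %in% names(df)),
              "STRING links file must have columns ", paste(need, collapse = ", "))
  out <- data.frame(gene_a = norm_genes(df$protein1),
                    gene_b = norm_genes(df$protein2),
                    score = df$combined_score / 1000,
                    stringsAsFactors = FALSE)
  stop_if_not(all(out$score >= 0 & out$score <= 1),
              "combined_score outside the 0-1000 dialect range")
  stop_if_not(all(out$gene_a != out$gene_b), "self-loop in PPI edge list")
  out
}

#' Read a trait-to-MeSH mapping table
#'
#' Tab-separated with columns `trait`, `mesh_id`, `tree_numbers`
#' (semicolon-separated tree numbers) and optionally `term` (the MeSH term
#' name, used to label grouped diseases).
#'
#' @param path TSV file path.
#' @return Data frame with a list-column `tree_numbers`.
#' @export
read_mesh_map <- function(path) {
  df <- read_tsv(path)
  need <- c("trait", "mesh_id", "tree_numbers")
  stop_if_not(all(need %in% names(df)),
              "MeSH map must have columns ", paste(need, collapse = ", "))
  df$tree_numbers <- strsplit(as.character(df$tree_numbers), ";", fixed = TRUE)
  if (is.null(df$term)) df$term <- df$trait
  df
}
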