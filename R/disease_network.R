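#' Parse a GWAS-catalog-dialect association table
#'
#' Reads the NHGRI-EBI GWAS catalog TSV dialect. One association record is
#' produced per row; multi-gene cells are split on the catalog's separators
#' (`","` and `" - "`), empty and `intergenic` entries are dropped, and gene
#' symbols are uppercased.
#'
#' @param path path to the tab-separated catalog file; the header must
#'   contain `DISEASE/TRAIT` and `MAPPED_GENE`.
#' @param include_reported also union in the `REPORTED GENE(S)` column
#'   (default `FALSE`: the curated mapped-gene field is the primary source).
#' @return Data frame with one row per catalog row: `trait`, `study_id`, and
#'   list-column `genes`.
#' @export
parse_gwas_catalog <- function(path, include_reported = FALSE) {
  df <- read_tsv(path)
  for (col in c("DISEASE/TRAIT", "MAPPED_GENE")) {
    if (!col %in% names(df))
      stop("GWAS catalog file is missing required column '", col, "'",
           call. = FALSE)
  }
  cells <- as.character(df[["MAPPED_GENE"]])
  if (include_reported && "REPORTED GENE(S)" %in% names(df)) {
    cells <- paste(cells, df[["REPORTED GENE(S)"]], sep = ", ")
  }
  genes <- lapply(cells, split_gene_cell)
  study <- if ("PUBMEDID" %in% names(df)) as.character(df[["PUBMEDID"]]) else ""
  out <- data.frame(trait = as.character(df[["DISEASE/TRAIT"]]),
                    study_id = study, stringsAsFactors = FALSE)
  stop_if_not(all(nzchar(out$trait)), "empty DISEASE/TRAIT value in catalog")
  out$genes <- genes
  out
}

# Split a MAPPED_GENE cell on "," and " - "; drop blanks, "intergenic",
# and the catalog's NR placeholder; uppercase.
split_gene_cell <- function(cell) {
  if (is.na(cell)) return(character(0))
  parts <- trimws(strsplit(cell, ",|\\s-\\s")[[1]])
  parts <- parts[nzchar(parts)]
  parts <- parts[!tolower(parts) %in% c("intergenic", "nr", "na")]
  unique(norm_genes(parts))
}

#' Truncate a MeSH tree number to its Disease [C] level-3 term
#'
#' Returns the first three dot-separated components of the tree number when
#' the category is C (Diseases) and the depth is at least 3, and `NA`
#' otherwise (non-C categories, or terms above level 3). Vectorized.
#'
#' @param tree_number character vector of MeSH tree numbers, e.g.
#'   `"C14.907.489.631"`.
#' @return Character vector of level-3 ids (`"C14.907.489"`) or `NA`.
#' @export
mesh_level3 <- function(tree_number) {
  ok <- grepl("^[A-Z][0-9]{2}(\\.[0-9]{3})*$", tree_number)
  if (any(!ok)) stop("malformed MeSH tree number: ",
                     paste(tree_number[!ok], collapse = ", "), call. = FALSE)
  parts <- strsplit(tree_number, ".", fixed = TRUE)
  vapply(parts, function(p) {
    if (substr(p[1], 1, 1) == "C" && length(p) >= 3)
      paste(p[1:3], collapse = ".")
    else NA_character_
  }, character(1))
}

#' Aggregate association records into a disease-gene network
#'
#' Traits are grouped by their MeSH Disease [C] level-3 ancestors: each
#' level-3 term receives the union of the genes of every trait mapping under
#' it (a trait with tree numbers under several level-3 terms contributes to
#' each). Traits without a mapping, or whose tree numbers have no C-category
#' level-3 ancestor, are skipped with a message.
#'
#' @param records association records from [parse_gwas_catalog()].
#' @param mapping trait-to-MeSH mapping from [read_mesh_map()].
#' @return A `disease_network`: list with `genes` (named list, level-3 id ->
#'   gene vector), `provenance` (parallel list of `"catalog"` /
#'   `"ppi_expansion"` tags) and `labels` (named character, level-3 id ->
#'   label; the alphabetically first MeSH term name among contributing
#'   traits).
#' @export
aggregate_disease_genes <- function(records, mapping) {
  stop_if_not(any(records$trait %in% mapping$trait),
              "mapping covers no trait present in the records")
  map_idx <- match(records$trait, mapping$trait)
  unmapped <- unique(records$trait[is.na(map_idx)])
  if (length(unmapped))
    message("skipping ", length(unmapped), " trait(s) with no MeSH mapping")
  genes <- list()
  labels <- list()
  for (i in seq_len(nrow(records))) {
    mi <- map_idx[i]
    if (is.na(mi)) next
    lvl3 <- unique(mesh_level3(mapping$tree_numbers[[mi]]))
    lvl3 <- lvl3[!is.na(lvl3)]
    if (!length(lvl3)) next
    g <- norm_genes(records$genes[[i]])
    for (id in lvl3) {
      genes[[id]] <- union(genes[[id]], g)
      labels[[id]] <- union(labels[[id]], mapping$term[[mi]])
    }
  }
  ids <- sort(names(genes))
  structure(list(
    genes = lapply(genes[ids], sort),
    provenance = lapply(genes[ids], function(g) rep("catalog", length(sort(g)))),
    labels = setNames(vapply(labels[ids], function(l) sort(l)[1], character(1)), ids)
  ), class = "disease_network")
}

#' Expand disease gene sets with high-confidence PPI neighbors
#'
#' For each disease, candidate genes are the one-hop neighbors of its catalog
#' genes through edges whose score strictly exceeds `score_threshold`.
#' Candidates are ranked by the maximum edge score connecting them to the
#' seed set (ties broken by gene symbol, ascending) and at most `max_added`
#' are appended with provenance `"ppi_expansion"`. Seed genes are never
#' duplicated. Expansion is always computed from the catalog-provenance
#' genes, so re-expanding an expanded network does not compound.
#'
#' @param network a `disease_network`.
#' @param edges PPI edge data frame (`gene_a`, `gene_b`, `score` in `[0,1]`),
#'   as from [read_string_links()].
#' @param score_threshold strict lower bound on the combined score
#'   (default 0.9: an edge scoring exactly 0.9 is excluded).
#' @param max_added maximum genes appended per disease (default 100).
#' @return The expanded `disease_network`.
#' @export
expand_with_ppi <- function(network, edges, score_threshold = 0.9,
                            max_added = 100) {
  stop_if_not(score_threshold > 0 && score_threshold <= 1,
              "score_threshold must be in (0, 1]")
  stop_if_not(max_added >= 0, "max_added must be >= 0")
  keep <- edges$score > score_threshold
  ed <- edges[keep, , drop = FALSE]
  out <- network
  if (nrow(ed) == 0 || max_added == 0) {
    # no qualifying edges: expansion is the identity
    out$genes <- lapply(names(network$genes), function(id) {
      network$genes[[id]][network$provenance[[id]] == "catalog"]
    })
    names(out$genes) <- names(network$genes)
    out$provenance <- lapply(out$genes, function(g) rep("catalog", length(g)))
    return(out)
  }
  # undirected: index both directions
  all_edges <- data.frame(a = c(ed$gene_a, ed$gene_b),
                          b = c(ed$gene_b, ed$gene_a),
                          score = c(ed$score, ed$score),
                          stringsAsFactors = FALSE)
  by_a <- split(seq_len(nrow(all_edges)), all_edges$a)
  for (id in names(network$genes)) {
    seeds <- network$genes[[id]][network$provenance[[id]] == "catalog"]
    idx <- unlist(by_a[seeds], use.names = FALSE)
    if (!length(idx)) {
      out$genes[[id]] <- seeds
      out$provenance[[id]] <- rep("catalog", length(seeds))
      next
    }
    cand <- all_edges[idx, , drop = FALSE]
    cand <- cand[!cand$b %in% seeds, , drop = FALSE]
    if (nrow(cand)) {
      best <- tapply(cand$score, cand$b, max)
      ord <- order(-best, names(best))
      added <- names(best)[ord][seq_len(min(max_added, length(best)))]
    } else added <- character(0)
    out$genes[[id]] <- c(seeds, added)
    out$provenance[[id]] <- c(rep("catalog", length(seeds)),
                              rep("ppi_expansion", length(added)))
  }
  out
}

#' Summary counts of a disease-gene network
#'
#' @param network a `disease_network`.
#' @return List: `n_diseases`, `n_genes` (distinct), `n_interactions` (sum of
#'   per-disease set sizes), `avg_genes_per_disease` (rounded half away from
#'   zero).
#' @export
network_summary <- function(network) {
  n_int <- sum(lengths(network$genes))
  n_dis <- length(network$genes)
  list(n_diseases = n_dis,
       n_genes = length(unique(unlist(network$genes))),
       n_interactions = n_int,
       avg_genes_per_disease = summary_average(n_int, n_dis))
}

#' @export
print.disease_network <- function(x, ...) {
  s <- network_summary(x)
  cat("Disease-gene network\n",
      "  diseases:              ", s$n_diseases, "\n",
      "  distinct genes:        ", s$n_genes, "\n",
      "  disease-gene pairs:    ", s$n_interactions, "\n",
      "  avg genes per disease: ", s$avg_genes_per_disease, "\n", sep = "")
  invisible(x)
}

#' Genes of one disease (optionally restricted to catalog provenance)
#' @param network a `disease_network`.
#' @param disease_id level-3 MeSH id.
#' @param provenance `"all"`, `"catalog"` or `"ppi_expansion"`.
#' @return Character vector of gene symbols.
#' @export
disease_genes <- function(network, disease_id, provenance = "all") {
  g <- network$genes[[disease_id]]
  stop_if_not(!is.null(g), "unknown disease ", disease_id)
  if (provenance == "all") g else g[network$provenance[[disease_id]] == provenance]
}

#' Write a disease-gene network as an edge table and/or SIF
#' @param network a `disease_network`.
#' @param path output TSV path (columns `disease_id`, `disease_label`,
#'   `gene`, `provenance`).
#' @return The path, invisibly.
#' @export
write_disease_edges <- function(network, path) {
  rows <- lapply(names(network$genes), function(id) {
    data.frame(disease_id = id,
               disease_label = unname(network$labels[[id]]),
               gene = network$genes[[id]],
               provenance = network$provenance[[id]],
               stringsAsFactors = FALSE)
  })
  write_tsv(do.call(rbind, rows), path)
}
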