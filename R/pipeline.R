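#' Assemble a pipeline configuration
#'
#' @param expression,probe_map,annotation paths to the expression study TSVs.
#' @param catalog,mesh_map paths to the GWAS-catalog-dialect table and the
#'   trait-to-MeSH mapping.
#' @param ppi optional path to a STRING-dialect edge list; `NULL` disables
#'   PPI expansion.
#' @param output_dir directory for all emitted artifacts.
#' @param fc_threshold fold-change cut for signature calling (default 1.5).
#' @param ppi_score_threshold strict PPI score cut (default 0.9).
#' @param ppi_max_added per-disease cap on appended PPI genes (default 100).
#' @param universe_size optional override of the permutation universe size
#'   (e.g. 20,462 for a genome-wide scale); default: the measured universe.
#' @param n_perm permutations per pair (default 100,000).
#' @param seed master seed (default 1).
#' @param q_threshold significance cut (default 0.2).
#' @param min_overlap only test pairs with at least this observed overlap
#'   (default 0).
#' @param pseudocount use the (exceed+1)/(n_perm+1) p estimate (default
#'   `FALSE`).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(expression, probe_map, annotation, catalog,
                            mesh_map, ppi = NULL, output_dir,
                            fc_threshold = 1.5, ppi_score_threshold = 0.9,
                            ppi_max_added = 100, universe_size = NULL,
                            n_perm = 100000L, seed = 1L, q_threshold = 0.2,
                            min_overlap = 0L, pseudocount = FALSE) {
  cfg <- list(expression = expression, probe_map = probe_map,
              annotation = annotation, catalog = catalog,
              mesh_map = mesh_map, ppi = ppi, output_dir = output_dir,
              fc_threshold = fc_threshold,
              ppi_score_threshold = ppi_score_threshold,
              ppi_max_added = ppi_max_added, universe_size = universe_size,
              n_perm = as.integer(n_perm), seed = as.integer(seed),
              q_threshold = q_threshold, min_overlap = as.integer(min_overlap),
              pseudocount = pseudocount)
  for (f in c("expression", "probe_map", "annotation", "catalog", "mesh_map")) {
    stop_if_not(file.exists(cfg[[f]]), "input file not found: ", cfg[[f]])
  }
  if (!is.null(cfg$ppi))
    stop_if_not(file.exists(cfg$ppi), "input file not found: ", cfg$ppi)
  stop_if_not(cfg$fc_threshold > 1, "fc_threshold must be > 1")
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a flat YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]; entries in `overrides`
#' (e.g. parsed CLI flags) replace file values.
#'
#' @param path YAML file path.
#' @param overrides named list of values overriding the file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, overrides = list()) {
  vals <- yaml::read_yaml(path)
  vals[names(overrides)] <- overrides
  do.call(pipeline_config, vals)
}

#' Run the full pipeline: signatures, disease network, prioritization
#'
#' Executes the three analysis stages and writes every artifact into the
#' output directory: the signature GMT and compound-gene edge table, the
#' disease-gene edge table and SIF, the ranked pair table, the
#' significant-pair SIF, the compounds x diseases Z-score matrix, a plain-text
#' run summary and an echo of the effective configuration. Rerunning with the
#' same configuration and seed reproduces every artifact byte for byte.
#'
#' @param config a `pipeline_config`.
#' @return A `tcm_run_summary` (list of stage counts, significant pairs and
#'   elapsed seconds), invisibly. All counts are recomputable from the
#'   emitted files.
#' @export
run_pipeline <- function(config) {
  t0 <- Sys.time()
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$output_dir, f)

  message("stage signatures: reading expression study")
  expr <- read_expression(config$expression)
  pmap <- read_probe_map(config$probe_map)
  ann <- read_annotation(config$annotation)
  sigs <- build_signature_set(expr, pmap, ann, threshold = config$fc_threshold)
  ssum <- signature_summary(sigs)
  message("stage signatures: ", ssum$n_compounds, " compounds, ",
          ssum$n_interactions, " compound-gene pairs")
  write_signature_gmt(sigs, out("signatures.gmt"))
  write_signature_edges(sigs, out("compound_gene_edges.tsv"))

  message("stage disease-net: parsing catalog")
  records <- parse_gwas_catalog(config$catalog)
  mapping <- read_mesh_map(config$mesh_map)
  net <- aggregate_disease_genes(records, mapping)
  if (!is.null(config$ppi)) {
    edges <- read_string_links(config$ppi)
    net <- expand_with_ppi(net, edges,
                           score_threshold = config$ppi_score_threshold,
                           max_added = config$ppi_max_added)
  }
  nsum <- network_summary(net)
  message("stage disease-net: ", nsum$n_diseases, " diseases, ",
          nsum$n_interactions, " disease-gene pairs")
  write_disease_edges(net, out("disease_gene_edges.tsv"))
  dis_edges <- read_tsv(out("disease_gene_edges.tsv"))
  write_sif(dis_edges$disease_id, dis_edges$gene, "interacts",
            out("disease_gene_network.sif"))

  message("stage prioritize: testing all pairs at n_perm = ", config$n_perm)
  results <- prioritize_all(sigs, net,
                            n_perm = config$n_perm, seed = config$seed,
                            q_threshold = config$q_threshold,
                            min_overlap = config$min_overlap,
                            universe_size_override = config$universe_size,
                            pseudocount = config$pseudocount)
  write_pair_results(results, out("ranked_pairs.tsv"),
                     sif_path = out("significant_pairs.sif"))
  zmat <- export_heatmap_matrix(results)
  write_tsv(data.frame(compound = rownames(zmat), zmat, check.names = FALSE),
            out("heatmap_z.tsv"), na = "")

  summary <- structure(list(
    signatures = ssum, disease_network = nsum,
    n_pairs_tested = nrow(results),
    n_significant = sum(results$significant),
    q_threshold = config$q_threshold,
    n_perm = config$n_perm, seed = config$seed,
    output_dir = config$output_dir,
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  ), class = "tcm_run_summary")

  writeLines(summary_lines(summary), out("run_summary.txt"))
  echo <- unclass(config)
  echo$output_dir <- NULL  # artifacts elsewhere must not differ by location
  echo <- echo[!vapply(echo, is.null, logical(1))]
  yaml::write_yaml(echo, out("config_echo.yaml"))
  message("pipeline done: ", summary$n_significant, " significant pairs at q < ",
          config$q_threshold)
  invisible(summary)
}

summary_lines <- function(s) {
  c("Run summary",
    "",
    "Compound signature network",
    sprintf("  compounds:                %d", s$signatures$n_compounds),
    sprintf("  distinct target genes:    %d", s$signatures$n_target_genes),
    sprintf("  avg genes per compound:   %d", s$signatures$avg_genes_per_compound),
    sprintf("  compound-gene pairs:      %d", s$signatures$n_interactions),
    "",
    "Disease-gene network",
    sprintf("  diseases:                 %d", s$disease_network$n_diseases),
    sprintf("  distinct disease genes:   %d", s$disease_network$n_genes),
    sprintf("  avg genes per disease:    %d", s$disease_network$avg_genes_per_disease),
    sprintf("  disease-gene pairs:       %d", s$disease_network$n_interactions),
    "",
    "Prioritization",
    sprintf("  pairs tested:             %d", s$n_pairs_tested),
    sprintf("  permutations per pair:    %d", s$n_perm),
    sprintf("  seed:                     %d", s$seed),
    sprintf("  significant (q < %s):     %d", format(s$q_threshold),
            s$n_significant))
}

#' @export
print.tcm_run_summary <- function(x, ...) {
  writeLines(summary_lines(x))
  cat(sprintf("  elapsed:                  %.1f s\n", x$elapsed_sec))
  invisible(x)
}

#' Z-score matrix (compounds x diseases) for heatmap display
#'
#' @param results data frame from [prioritize_all()].
#' @return Numeric matrix over all compounds and diseases present in
#'   `results`; cells of untested pairs or undefined Z are `NA` (written as
#'   empty cells).
#' @export
export_heatmap_matrix <- function(results) {
  stop_if_not(nrow(results) > 0, "empty result table")
  cps <- sort(unique(results$compound))
  dis <- sort(unique(results$disease_id))
  m <- matrix(NA_real_, length(cps), length(dis), dimnames = list(cps, dis))
  m[cbind(match(results$compound, cps), match(results$disease_id, dis))] <-
    results$z
  m
}

#' Rank compounds against a submitted disease gene list
#'
#' The interactive query mode: a user-supplied list of disease genes is
#' tested against every compound signature with the same permutation scheme
#' used by the full pipeline, and compounds are returned ranked by p value,
#' then Z descending.
#'
#' @param genes character vector of submitted gene symbols.
#' @param signatures a `signature_set`.
#' @param universe gene universe (default: the signature set's).
#' @param n_perm permutations per compound (default 100,000).
#' @param seed master seed; each compound gets a substream.
#' @param pseudocount see [permutation_test()].
#' @return Data frame: `compound`, `K`, `n`, `overlap`, `p`, `z`, `q`.
#' @export
query_disease_genes <- function(genes, signatures,
                                universe = signatures$universe,
                                n_perm = 100000L, seed = 1L,
                                pseudocount = FALSE) {
  stop_if_not(length(genes) > 0, "empty gene list")
  uni <- unique(norm_genes(universe))
  query <- intersect(unique(norm_genes(genes)), uni)
  if (length(query) == 0)
    stop("none of the submitted genes is in the gene universe; ",
         "check the symbols against the measured genes", call. = FALSE)
  n <- length(query)
  rows <- lapply(names(signatures$signatures), function(cp) {
    targets <- intersect(compound_targets(signatures, cp), uni)
    g <- length(intersect(targets, query))
    pt <- permutation_test(length(targets), n, g, uni, n_perm = n_perm,
                           seed = seed_stream(seed, "query", cp),
                           pseudocount = pseudocount)
    data.frame(compound = cp, K = length(targets), n = n, overlap = g,
               p = pt$p, z = z_score(g, pt$mu, pt$sigma),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$q <- bh_adjust(res$p)
  res <- res[order(res$p, -res$z, na.last = TRUE), , drop = FALSE]
  rownames(res) <- NULL
  res
}
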