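#' Configuration for the synthetic study generator
#'
#' Defines a fully seeded synthetic analogue of a compound-perturbation
#' microarray study plus a GWAS-style disease catalog and a scored PPI graph,
#' with known planted structure. Defaults describe a small but realistic
#' study: a 2,000-gene universe, 20 compounds profiled in duplicate against
#' duplicate vehicle controls, 30 diseases, and 5 planted compound-disease
#' associations whose gene-set overlap (10) stands well above the background
#' hypergeometric overlap (~2 for these set sizes).
#'
#' @param n_genes gene universe size (default 2,000).
#' @param n_probes_per_gene maximum probes per gene; each gene gets 1 to this
#'   many probes (default 2).
#' @param n_compounds number of compounds (default 20).
#' @param n_replicates treated replicates per compound (default 2, the usual
#'   duplicate design).
#' @param n_vehicle_replicates vehicle replicates (default 2).
#' @param n_diseases number of diseases (default 30).
#' @param genes_per_disease inclusive range of disease gene-set sizes
#'   (default `c(30, 60)`).
#' @param signature_size inclusive range of planted differentially expressed
#'   genes per compound (default `c(80, 120)`).
#' @param planted_pairs data frame with columns `compound`, `disease`
#'   (1-based indices) and `overlap` (planted overlap count, `>= 1`);
#'   default: 5 diagonal pairs with overlap 10.
#' @param de_log2_effect planted effect size on the log2 scale; must exceed
#'   `log2(1.5)` so planted genes clear the default fold-change cut
#'   (default 1.0, i.e. 2-fold).
#' @param noise_sd Gaussian noise SD on the log2 scale (default 0.1; 0 gives
#'   exactly noiseless data).
#' @param ppi_density edge density of the random PPI graph (default 0.01).
#' @param ppi_high_frac fraction of edges scored above the high-confidence
#'   0.9 cut (default 0.25).
#' @param seed master seed; every artifact derives its own RNG substream from
#'   it, so outputs are byte-identical under a fixed seed.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_genes = 2000, n_probes_per_gene = 2,
                             n_compounds = 20, n_replicates = 2,
                             n_vehicle_replicates = 2, n_diseases = 30,
                             genes_per_disease = c(30, 60),
                             signature_size = c(80, 120),
                             planted_pairs = NULL,
                             de_log2_effect = 1.0, noise_sd = 0.1,
                             ppi_density = 0.01, ppi_high_frac = 0.25,
                             seed = 1L) {
  if (is.null(planted_pairs)) {
    k <- min(5L, n_compounds, n_diseases)
    planted_pairs <- data.frame(compound = seq_len(k), disease = seq_len(k),
                                overlap = rep(10L, k))
  }
  cfg <- list(n_genes = as.integer(n_genes),
              n_probes_per_gene = as.integer(n_probes_per_gene),
              n_compounds = as.integer(n_compounds),
              n_replicates = as.integer(n_replicates),
              n_vehicle_replicates = as.integer(n_vehicle_replicates),
              n_diseases = as.integer(n_diseases),
              genes_per_disease = as.integer(genes_per_disease),
              signature_size = as.integer(signature_size),
              planted_pairs = planted_pairs,
              de_log2_effect = de_log2_effect, noise_sd = noise_sd,
              ppi_density = ppi_density, ppi_high_frac = ppi_high_frac,
              seed = as.integer(seed))
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  counts <- c(cfg$n_genes, cfg$n_probes_per_gene, cfg$n_compounds,
              cfg$n_replicates, cfg$n_vehicle_replicates, cfg$n_diseases)
  stop_if_not(all(counts >= 1), "all counts must be strictly positive")
  stop_if_not(length(cfg$genes_per_disease) == 2 &&
                cfg$genes_per_disease[1] >= 1 &&
                diff(cfg$genes_per_disease) >= 0,
              "genes_per_disease must be a nondecreasing positive range")
  stop_if_not(length(cfg$signature_size) == 2 &&
                cfg$signature_size[1] >= 1 && diff(cfg$signature_size) >= 0,
              "signature_size must be a nondecreasing positive range")
  stop_if_not(cfg$signature_size[2] <= cfg$n_genes,
              "signature larger than the gene universe")
  stop_if_not(cfg$genes_per_disease[2] <= cfg$n_genes,
              "genes_per_disease exceeds the gene universe")
  stop_if_not(cfg$de_log2_effect > log2(1.5),
              "de_log2_effect must exceed log2(1.5) to clear the default cut")
  stop_if_not(cfg$noise_sd >= 0, "noise_sd must be >= 0")
  stop_if_not(cfg$ppi_density > 0 && cfg$ppi_density < 1,
              "ppi_density must lie in (0, 1)")
  pp <- cfg$planted_pairs
  stop_if_not(is.data.frame(pp) &&
                all(c("compound", "disease", "overlap") %in% names(pp)),
              "planted_pairs needs columns compound, disease, overlap")
  stop_if_not(all(pp$compound >= 1 & pp$compound <= cfg$n_compounds),
              "planted compound index out of range")
  stop_if_not(all(pp$disease >= 1 & pp$disease <= cfg$n_diseases),
              "planted disease index out of range")
  stop_if_not(all(pp$overlap >= 1), "planted overlap must be >= 1")
  stop_if_not(all(pp$overlap <= min(cfg$signature_size[1],
                                    cfg$genes_per_disease[1])),
              "planted overlap exceeds the smallest signature or disease set")
  per_disease <- tapply(pp$overlap, pp$disease, sum)
  stop_if_not(all(per_disease <= cfg$genes_per_disease[1]),
              "total planted overlap for a disease exceeds its smallest size")
  invisible(cfg)
}

# sample n values from an inclusive integer range; immune to R's
# length-one sample() surprise when lo == hi
sample_range <- function(range, n) {
  vals <- seq(range[1], range[2])
  if (length(vals) == 1) rep(vals, n) else sample(vals, n, replace = TRUE)
}

compound_ids <- function(cfg) sprintf("CMPD%02d", seq_len(cfg$n_compounds))
disease_level3_ids <- function(cfg) {
  d <- seq_len(cfg$n_diseases)
  sprintf("C%02d.%03d.%03d", ((d - 1) %/% 999) + 1, ((d - 1) %% 999) + 1, 500)
}

#' Planted ground truth derived deterministically from a config
#'
#' The truth is a pure function of the configuration (it has its own RNG
#' substream), so the expression, catalog, and PPI generators can all be
#' called independently and still agree on the planted structure. Every
#' planted pair's compound signature and disease set intersect in exactly the
#' configured overlap count: the overlapping genes are drawn from the
#' compound's signature and all remaining disease genes from outside the
#' signatures of that disease's planted compounds.
#'
#' @param config a `synthetic_config`.
#' @return A `tcm_ground_truth`: list with `genes` (universe), `signatures`
#'   (compound -> planted DE gene set), `directions` (compound -> named
#'   +1/-1 per gene), `disease_sets` (level-3 MeSH id -> gene set),
#'   `planted_pairs` (data frame with compound/disease identifiers and
#'   overlap counts).
#' @export
ground_truth <- function(config) {
  set.seed(seed_stream(config$seed, "truth"))
  genes <- sprintf("G%05d", seq_len(config$n_genes))
  cmpds <- compound_ids(config)
  dis_ids <- disease_level3_ids(config)

  sig_sizes <- sample_range(config$signature_size, config$n_compounds)
  signatures <- lapply(sig_sizes, function(k) sort(sample(genes, k)))
  names(signatures) <- cmpds
  directions <- lapply(signatures, function(s)
    setNames(sample(c(1, -1), length(s), replace = TRUE), s))

  dis_sizes <- sample_range(config$genes_per_disease, config$n_diseases)
  pp <- config$planted_pairs
  disease_sets <- vector("list", config$n_diseases)
  for (d in seq_len(config$n_diseases)) {
    rows <- pp[pp$disease == d, , drop = FALSE]
    if (nrow(rows) == 0) {
      disease_sets[[d]] <- sort(sample(genes, dis_sizes[d]))
      next
    }
    planted_sigs <- signatures[cmpds[rows$compound]]
    chosen <- character(0)
    for (r in seq_len(nrow(rows))) {
      own <- planted_sigs[[r]]
      others <- unlist(planted_sigs[-r], use.names = FALSE)
      pool <- setdiff(own, others)
      stop_if_not(length(pool) >= rows$overlap[r],
                  "cannot plant disjoint overlaps: signatures collide")
      chosen <- c(chosen, sample(pool, rows$overlap[r]))
    }
    filler_pool <- setdiff(genes, unlist(planted_sigs, use.names = FALSE))
    n_fill <- dis_sizes[d] - length(chosen)
    stop_if_not(n_fill >= 0, "planted overlap exceeds disease set size")
    disease_sets[[d]] <- sort(c(chosen, sample(filler_pool, n_fill)))
  }
  names(disease_sets) <- dis_ids

  structure(list(
    genes = genes,
    signatures = signatures,
    directions = directions,
    disease_sets = disease_sets,
    planted_pairs = data.frame(compound = cmpds[pp$compound],
                               disease_id = dis_ids[pp$disease],
                               overlap = pp$overlap,
                               stringsAsFactors = FALSE)
  ), class = "tcm_ground_truth")
}

#' Generate a synthetic replicated treated/vehicle expression study
#'
#' Vehicle samples are per-gene baseline (Uniform(4, 12) on the log2 scale,
#' mimicking normalized microarray ranges) plus Gaussian noise; each treated
#' sample additionally shifts the compound's planted signature genes by
#' `de_log2_effect` with the per-gene sign recorded in the ground truth.
#' Every gene carries at least one probe; probes of the same gene share the
#' gene's value up to a fixed per-probe offset, so the max-collapse rule
#' recovers identical fold changes.
#'
#' @param config a `synthetic_config`.
#' @param truth ground truth; defaults to `ground_truth(config)`.
#' @return List with `expression` (probe x sample log2 matrix), `probe_map`
#'   (`probe_id`, `gene_symbol`), `annotation` (`sample_id`, `compound`,
#'   `role`, `replicate`).
#' @export
generate_expression <- function(config, truth = ground_truth(config)) {
  set.seed(seed_stream(config$seed, "expression"))
  genes <- truth$genes
  n_probes_per <- sample(seq_len(config$n_probes_per_gene),
                         config$n_genes, replace = TRUE)
  gene_of_probe <- rep(seq_len(config$n_genes), n_probes_per)
  n_probes <- length(gene_of_probe)
  probe_ids <- sprintf("P%06d_AT", seq_len(n_probes))

  baseline <- runif(config$n_genes, 4, 12)
  probe_offset <- runif(n_probes, -0.5, 0.5)
  base_probe <- baseline[gene_of_probe] + probe_offset

  cmpds <- compound_ids(config)
  annotation <- rbind(
    data.frame(sample_id = sprintf("VEH_R%d", seq_len(config$n_vehicle_replicates)),
               compound = "DMSO", role = "vehicle",
               replicate = seq_len(config$n_vehicle_replicates),
               stringsAsFactors = FALSE),
    data.frame(sample_id = paste0(rep(cmpds, each = config$n_replicates), "_R",
                                  rep(seq_len(config$n_replicates),
                                      times = config$n_compounds)),
               compound = rep(cmpds, each = config$n_replicates),
               role = "treated",
               replicate = rep(seq_len(config$n_replicates),
                               times = config$n_compounds),
               stringsAsFactors = FALSE))

  m <- matrix(base_probe, nrow = n_probes, ncol = nrow(annotation))
  rownames(m) <- probe_ids
  colnames(m) <- annotation$sample_id
  gene_index <- setNames(seq_len(config$n_genes), genes)
  for (cp in cmpds) {
    dir <- truth$directions[[cp]]
    shift_gene <- numeric(config$n_genes)
    shift_gene[gene_index[names(dir)]] <- dir * config$de_log2_effect
    cols <- annotation$sample_id[annotation$compound == cp &
                                   annotation$role == "treated"]
    m[, cols] <- m[, cols] + shift_gene[gene_of_probe]
  }
  if (config$noise_sd > 0) {
    m <- m + matrix(rnorm(length(m), sd = config$noise_sd),
                    nrow = nrow(m))
  }
  list(expression = m,
       probe_map = data.frame(probe_id = probe_ids,
                              gene_symbol = genes[gene_of_probe],
                              stringsAsFactors = FALSE),
       annotation = annotation)
}

#' Generate a GWAS-catalog-dialect association table and trait-to-MeSH map
#'
#' Each planted disease gene set is split across 1-3 traits that all map to
#' the same level-3 MeSH Disease [C] term (via distinct depth-4 tree
#' numbers), and each trait's genes are spread over catalog rows of up to 3
#' genes joined with the catalog's `", "` separator; the first row of every
#' disease additionally carries an `intergenic` entry so the parser's drop
#' rule is exercised. Parsing and aggregating the two tables reproduces the
#' planted disease sets exactly.
#'
#' @inheritParams generate_expression
#' @return List with `catalog` (data frame in the NHGRI-EBI TSV dialect:
#'   `DISEASE/TRAIT`, `MAPPED_GENE`, `REPORTED GENE(S)`, `PUBMEDID`) and
#'   `mesh_map` (`trait`, `mesh_id`, `tree_numbers`, `term`).
#' @export
generate_disease_catalog <- function(config, truth = ground_truth(config)) {
  set.seed(seed_stream(config$seed, "catalog"))
  dis_ids <- disease_level3_ids(config)
  cat_rows <- list()
  map_rows <- list()
  pmid <- 20000000L
  for (d in seq_len(config$n_diseases)) {
    gset <- truth$disease_sets[[d]]
    n_traits <- sample(1:3, 1)
    n_traits <- min(n_traits, length(gset))
    split_idx <- sort(rep_len(seq_len(n_traits), length(gset)))
    trait_genes <- split(sample(gset), split_idx)
    for (t in seq_len(n_traits)) {
      trait <- sprintf("Synthetic trait %d%s", d, letters[t])
      map_rows[[length(map_rows) + 1]] <- data.frame(
        trait = trait,
        mesh_id = sprintf("D%06d", 100000L + d * 10L + t),
        tree_numbers = sprintf("%s.%03d", dis_ids[d], t),
        term = sprintf("Disease group %03d", d),
        stringsAsFactors = FALSE)
      tg <- trait_genes[[t]]
      chunks <- split(tg, ceiling(seq_along(tg) / 3))
      for (ch in seq_along(chunks)) {
        cell <- paste(chunks[[ch]], collapse = ", ")
        if (t == 1 && ch == 1) cell <- paste0(cell, ", intergenic")
        pmid <- pmid + 1L
        cat_rows[[length(cat_rows) + 1]] <- data.frame(
          `DISEASE/TRAIT` = trait, MAPPED_GENE = cell,
          `REPORTED GENE(S)` = "NR", PUBMEDID = pmid,
          check.names = FALSE, stringsAsFactors = FALSE)
      }
    }
  }
  list(catalog = do.call(rbind, cat_rows),
       mesh_map = do.call(rbind, map_rows))
}

#' Generate a random scored PPI edge list in the STRING links dialect
#'
#' An Erdos-Renyi graph over the gene universe: the number of edges is
#' binomial in the density, edges are sampled uniformly among unordered gene
#' pairs (no self-loops, no duplicates), and a configurable fraction of edges
#' receives a combined score above the 0.9 high-confidence cut (901-1000 on
#' the file's 0-1000 integer scale); the rest score 100-900, so an edge at
#' exactly 900 is possible and is excluded by the strict threshold.
#'
#' @inheritParams generate_expression
#' @return Data frame with columns `protein1`, `protein2`, `combined_score`
#'   (integer 0-1000).
#' @export
generate_ppi <- function(config, truth = ground_truth(config)) {
  set.seed(seed_stream(config$seed, "ppi"))
  N <- config$n_genes
  n_pairs <- N * (N - 1) / 2
  m <- rbinom(1, n_pairs, config$ppi_density)
  if (m == 0) {
    return(data.frame(protein1 = character(0), protein2 = character(0),
                      combined_score = integer(0), stringsAsFactors = FALSE))
  }
  k0 <- sort(sample(n_pairs, m)) - 1  # 0-based unordered-pair ranks
  # unrank lexicographically: i is the largest index with f(i) <= k0,
  # f(i) = i*(2N - i - 1)/2 pairs having first element < i
  i <- floor(((2 * N - 1) - sqrt((2 * N - 1)^2 - 8 * k0)) / 2)
  f <- function(i) i * (2 * N - i - 1) / 2
  i <- i - (f(i) > k0) + (f(i + 1) <= k0)
  j <- k0 - f(i) + i + 1
  stopifnot(all(i >= 0), all(j > i), all(j < N))
  high <- runif(m) < config$ppi_high_frac
  score <- integer(m)
  score[high] <- sample(901:1000, sum(high), replace = TRUE)
  score[!high] <- sample(100:900, sum(!high), replace = TRUE)
  data.frame(protein1 = truth$genes[i + 1], protein2 = truth$genes[j + 1],
             combined_score = score, stringsAsFactors = FALSE)
}

#' Generate the full synthetic study and write every artifact to disk
#'
#' @param config a `synthetic_config`.
#' @param dir output directory (created if needed).
#' @return List with `paths` (named paths of every written file), `truth`,
#'   and `config`, invisibly.
#' @export
simulate_study <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  truth <- ground_truth(config)
  expr <- generate_expression(config, truth)
  cat <- generate_disease_catalog(config, truth)
  ppi <- generate_ppi(config, truth)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             probe_map = file.path(dir, "probe_map.tsv"),
             annotation = file.path(dir, "annotation.tsv"),
             catalog = file.path(dir, "gwas_catalog.tsv"),
             mesh_map = file.path(dir, "mesh_map.tsv"),
             ppi = file.path(dir, "ppi_links.tsv"),
             planted_signatures = file.path(dir, "planted_signatures.gmt"),
             planted_disease_sets = file.path(dir, "planted_disease_sets.gmt"),
             planted_pairs = file.path(dir, "planted_pairs.tsv"))
  write_expression(expr$expression, paths["expression"])
  write_tsv(expr$probe_map, paths["probe_map"])
  write_tsv(expr$annotation, paths["annotation"])
  write_tsv(cat$catalog, paths["catalog"])
  write_tsv(cat$mesh_map, paths["mesh_map"])
  write_tsv(ppi, paths["ppi"])
  write_gmt(truth$signatures, paths["planted_signatures"])
  write_gmt(truth$disease_sets, paths["planted_disease_sets"])
  write_tsv(truth$planted_pairs, paths["planted_pairs"])
  invisible(list(paths = paths, truth = truth, config = config))
}
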