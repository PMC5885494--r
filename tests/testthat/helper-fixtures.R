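# Small synthetic configurations shared across test files.

tiny_config <- function(...) {
  defaults <- list(n_genes = 200, n_probes_per_gene = 2, n_compounds = 4,
                   n_replicates = 2, n_vehicle_replicates = 2, n_diseases = 5,
                   genes_per_disease = c(12, 20), signature_size = c(25, 35),
                   planted_pairs = data.frame(compound = 1:2, disease = 1:2,
                                              overlap = 8),
                   de_log2_effect = 1.0, noise_sd = 0, ppi_density = 0.02,
                   seed = 11)
  args <- list(...)
  defaults[names(args)] <- args
  do.call(synthetic_config, defaults)
}

# A hand-built condition matrix with a VEHICLE column.
cond_matrix <- function(treated, vehicle, genes = NULL, compound = "cmpd") {
  m <- cbind(treated, vehicle)
  colnames(m) <- c(compound, "VEHICLE")
  rownames(m) <- if (is.null(genes)) paste0("G", seq_along(treated)) else genes
  m
}

# Exact null of the overlap statistic by exhaustive enumeration of all
# subsets of size n from a universe of N with K marked elements.
enumerate_overlap_null <- function(N, K, n) {
  subsets <- utils::combn(N, n)
  colSums(subsets <= K)
}
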