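#' Collapse probe-level expression to gene level by maximum
#'
#' Probe sets mapping to the same gene are collapsed to a single row holding,
#' per sample, the maximum expression value across that gene's probes (the
#' usual choice for retaining power to detect changes in individual
#' isoforms). Probes with no gene mapping, and probes mapping to more than
#' one gene symbol, are dropped.
#'
#' @param matrix numeric probe x sample matrix of log2 intensities with probe
#'   rownames.
#' @param probe_map data frame with columns `probe_id`, `gene_symbol`.
#' @return Gene x sample numeric matrix with uppercase gene rownames.
#' @export
collapse_probes <- function(matrix, probe_map) {
  stop_if_not(is.matrix(matrix) && !is.null(rownames(matrix)),
              "expression matrix must have probe rownames")
  pm <- probe_map[probe_map$probe_id %in% rownames(matrix), , drop = FALSE]
  # probes hitting multiple distinct genes are ambiguous: drop, don't double count
  multi <- unique(pm$probe_id[duplicated(pm$probe_id)])
  if (length(multi)) {
    genes_per_probe <- tapply(pm$gene_symbol, pm$probe_id,
                              function(g) length(unique(g)))
    ambiguous <- names(genes_per_probe)[genes_per_probe > 1]
    pm <- pm[!pm$probe_id %in% ambiguous, , drop = FALSE]
    pm <- pm[!duplicated(pm$probe_id), , drop = FALSE]
  }
  stop_if_not(nrow(pm) > 0, "no probe in the matrix is covered by the probe map")
  m <- matrix[pm$probe_id, , drop = FALSE]
  genes <- norm_genes(pm$gene_symbol)
  idx <- split(seq_len(nrow(m)), genes)
  out <- vapply(idx, function(rows) {
    if (length(rows) == 1L) m[rows, ] else apply(m[rows, , drop = FALSE], 2, max)
  }, numeric(ncol(m)))
  out <- t(out)
  colnames(out) <- colnames(m)
  out[order(rownames(out)), , drop = FALSE]
}

#' Average replicate samples into one column per condition
#'
#' Treated replicates of each compound are averaged (arithmetic mean on the
#' log2 scale) into a single column; all vehicle samples are averaged into a
#' single column named `"VEHICLE"`.
#'
#' @param gene_matrix gene x sample matrix (as from [collapse_probes()]).
#' @param annotation sample annotation data frame (`sample_id`, `compound`,
#'   `role`, `replicate`).
#' @return Gene x condition matrix: one column per compound plus `"VEHICLE"`.
#' @export
average_replicates <- function(gene_matrix, annotation) {
  validate_annotation(annotation)
  stop_if_not(all(annotation$sample_id %in% colnames(gene_matrix)),
              "annotation names samples absent from the matrix")
  stop_if_not(!any(annotation$compound[annotation$role == "treated"] == "VEHICLE"),
              "compound label 'VEHICLE' is reserved")
  cond <- ifelse(annotation$role == "vehicle", "VEHICLE", annotation$compound)
  groups <- split(annotation$sample_id, cond)
  compounds <- setdiff(sort(names(groups)), "VEHICLE")
  missing <- vapply(groups, length, integer(1)) == 0L
  if (any(missing)) stop("compound with zero samples: ",
                         paste(names(groups)[missing], collapse = ", "),
                         call. = FALSE)
  out <- vapply(c(compounds, "VEHICLE"), function(cn) {
    cols <- gene_matrix[, groups[[cn]], drop = FALSE]
    rowMeans(cols)
  }, numeric(nrow(gene_matrix)))
  rownames(out) <- rownames(gene_matrix)
  out
}

#' Call a compound's differential-expression signature by fold change
#'
#' Fold change is computed on the linear scale from log2 values,
#' `FC = 2^(treated - vehicle)`. A gene is "up" iff `FC >= threshold` and
#' "down" iff `FC <= 1/threshold` (inclusive at both cuts); all other genes
#' are excluded.
#'
#' @param condition_matrix gene x condition matrix from
#'   [average_replicates()]; must contain a `"VEHICLE"` column.
#' @param compound compound column name.
#' @param threshold linear fold-change threshold, must exceed 1 (default 1.5).
#' @return List with character vectors `up` and `down` (disjoint).
#' @export
#' @examples
#' m <- rbind(A = c(6, 5), B = c(4, 5), C = c(5.3, 5))
#' colnames(m) <- c("cmpd", "VEHICLE")
#' call_signature(m, "cmpd")  # A up (FC 2), B down (FC 0.5), C excluded
call_signature <- function(condition_matrix, compound, threshold = 1.5) {
  stop_if_not(threshold > 1, "fold-change threshold must be > 1")
  stop_if_not(compound %in% colnames(condition_matrix),
              "no condition column for compound ", compound)
  stop_if_not("VEHICLE" %in% colnames(condition_matrix),
              "condition matrix has no VEHICLE column")
  # compare on the log2 scale: FC >= t  <=>  log2 difference >= log2(t),
  # which keeps the inclusive boundary exact in floating point
  ldiff <- condition_matrix[, compound] - condition_matrix[, "VEHICLE"]
  lt <- log2(threshold)
  genes <- rownames(condition_matrix)
  list(up = genes[ldiff >= lt], down = genes[ldiff <= -lt])
}

#' Build the full compound signature set (the compound-target gene network)
#'
#' Composes probe collapse, replicate averaging and fold-change signature
#' calling for every compound in the annotation, and records the measured
#' gene universe.
#'
#' @inheritParams collapse_probes
#' @inheritParams average_replicates
#' @inheritParams call_signature
#' @return A `signature_set`: list with `signatures` (named list of
#'   `list(up, down)` per compound), `universe` (all measured gene symbols),
#'   and `threshold`.
#' @export
build_signature_set <- function(matrix, probe_map, annotation, threshold = 1.5) {
  gm <- collapse_probes(matrix, probe_map)
  cm <- average_replicates(gm, annotation)
  compounds <- setdiff(colnames(cm), "VEHICLE")
  sigs <- lapply(compounds, function(cp) call_signature(cm, cp, threshold))
  names(sigs) <- compounds
  structure(list(signatures = sigs,
                 universe = rownames(gm),
                 threshold = threshold),
            class = "signature_set")
}

#' Target gene set of one compound (up and down genes pooled)
#' @param signature_set a `signature_set`.
#' @param compound compound identifier.
#' @return Character vector of target genes.
#' @export
compound_targets <- function(signature_set, compound) {
  s <- signature_set$signatures[[compound]]
  stop_if_not(!is.null(s), "unknown compound ", compound)
  union(s$up, s$down)
}

#' Summary counts of a signature set
#'
#' @param signature_set a `signature_set`.
#' @return List: `n_compounds`, `n_target_genes` (distinct genes),
#'   `n_interactions` (total compound-gene pairs), `avg_genes_per_compound`
#'   (rounded half away from zero).
#' @export
signature_summary <- function(signature_set) {
  targets <- lapply(names(signature_set$signatures),
                    function(cp) compound_targets(signature_set, cp))
  n_int <- sum(lengths(targets))
  list(n_compounds = length(targets),
       n_target_genes = length(unique(unlist(targets))),
       n_interactions = n_int,
       avg_genes_per_compound = summary_average(n_int, length(targets)))
}

#' @export
print.signature_set <- function(x, ...) {
  s <- signature_summary(x)
  cat("Compound signature set\n",
      "  compounds:            ", s$n_compounds, "\n",
      "  distinct target genes:", s$n_target_genes, "\n",
      "  compound-gene pairs:  ", s$n_interactions, "\n",
      "  fold-change threshold:", x$threshold, "\n",
      "  measured universe:    ", length(x$universe), " genes\n", sep = "")
  invisible(x)
}

#' Write a signature set as GMT (`<compound>_UP` / `<compound>_DOWN` sets)
#' @param signature_set a `signature_set`.
#' @param path output GMT path.
#' @return The path, invisibly.
#' @export
write_signature_gmt <- function(signature_set, path) {
  sets <- list()
  for (cp in names(signature_set$signatures)) {
    s <- signature_set$signatures[[cp]]
    sets[[paste0(cp, "_UP")]] <- s$up
    sets[[paste0(cp, "_DOWN")]] <- s$down
  }
  write_gmt(sets, path)
}

#' Write a signature set as a compound-gene edge table
#' @param signature_set a `signature_set`.
#' @param path output TSV path (columns `compound`, `gene`, `direction`).
#' @return The path, invisibly.
#' @export
write_signature_edges <- function(signature_set, path) {
  rows <- lapply(names(signature_set$signatures), function(cp) {
    s <- signature_set$signatures[[cp]]
    data.frame(compound = cp,
               gene = c(s$up, s$down),
               direction = rep(c("up", "down"), c(length(s$up), length(s$down))),
               stringsAsFactors = FALSE)
  })
  write_tsv(do.call(rbind, rows), path)
}
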