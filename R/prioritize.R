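#' Observed overlap between a compound target set and a disease gene set
#'
#' Both sets are intersected with the gene universe before counting, because
#' the permutation null draws from the universe.
#'
#' @param targets compound target genes (character).
#' @param disease_set disease genes (character).
#' @param universe gene universe (character vector of symbols).
#' @return Integer overlap count.
#' @export
overlap_count <- function(targets, disease_set, universe) {
  length(intersect(intersect(norm_genes(targets), norm_genes(disease_set)),
                   norm_genes(universe)))
}

universe_size <- function(universe) {
  if (is.numeric(universe) && length(universe) == 1) as.integer(universe)
  else length(unique(norm_genes(universe)))
}

#' Monte-Carlo permutation null for the overlap of one compound-disease pair
#'
#' Each permutation draws `n` genes uniformly without replacement from a
#' universe of `N` genes and counts the overlap with a fixed target set of
#' size `K` (by symmetry only the sizes matter). The nominal p value is the
#' fraction of permutations whose overlap strictly exceeds the observed
#' overlap; `mu` and `sigma` are the sample mean and sample standard
#' deviation (denominator `n_perm - 1`) of the permuted overlaps.
#'
#' @param K compound target set size (within the universe).
#' @param n disease gene set size (within the universe; the permutation draw
#'   size).
#' @param g_obs observed overlap, `0 <= g_obs <= min(K, n)`.
#' @param universe gene universe: a character vector of symbols or a single
#'   integer size `N`.
#' @param n_perm number of permutations (default 100,000).
#' @param seed RNG seed for this pair's draw stream.
#' @param pseudocount if `TRUE`, report `p = (exceed + 1) / (n_perm + 1)`
#'   instead of `exceed / n_perm`, guaranteeing a nonzero p. Default `FALSE`
#'   (the plain strict-exceedance estimate, which can be 0).
#' @return A `permutation_null`: list with `n_perm`, `g_obs`, `mu`, `sigma`,
#'   `n_exceed` (permutations with overlap > `g_obs`), `n_tie` (overlap ==
#'   `g_obs`), `p`, `K`, `n`, `N`, `seed`.
#' @export
permutation_test <- function(K, n, g_obs, universe, n_perm = 100000L,
                             seed = 1L, pseudocount = FALSE) {
  N <- universe_size(universe)
  stop_if_not(K >= 0 && K <= N, "K must satisfy 0 <= K <= N")
  stop_if_not(n >= 0 && n <= N, "n must satisfy 0 <= n <= N")
  stop_if_not(g_obs >= 0 && g_obs <= min(K, n),
              "g_obs must satisfy 0 <= g_obs <= min(K, n)")
  stop_if_not(n_perm >= 1, "n_perm must be >= 1")
  set.seed(as.integer(seed))
  counts <- perm_overlap_counts(N, as.integer(K), as.integer(n),
                                as.integer(n_perm))
  n_exceed <- sum(counts > g_obs)
  n_tie <- sum(counts == g_obs)
  p <- if (pseudocount) (n_exceed + 1) / (n_perm + 1) else n_exceed / n_perm
  structure(list(n_perm = as.integer(n_perm), g_obs = as.integer(g_obs),
                 mu = mean(counts), sigma = stats::sd(counts),
                 n_exceed = n_exceed, n_tie = n_tie, p = p,
                 K = as.integer(K), n = as.integer(n), N = N,
                 seed = as.integer(seed)),
            class = "permutation_null")
}

#' @export
print.permutation_null <- function(x, ...) {
  cat(sprintf(paste0("Permutation null (N=%d, K=%d, n=%d, %d permutations)\n",
                     "  observed overlap: %d\n  mu = %.4f, sigma = %.4f\n",
                     "  p = %.6g (%d exceed, %d tie)\n"),
              x$N, x$K, x$n, x$n_perm, x$g_obs, x$mu, x$sigma,
              x$p, x$n_exceed, x$n_tie))
  invisible(x)
}

#' Exact hypergeometric validator for the permutation null
#'
#' Drawing `n` genes without replacement from `N` and counting hits in a
#' fixed `K`-set is Hypergeometric(N, K, n); this returns the exact strict
#' upper tail `P(X > g_obs)`, mean `nK/N` and standard deviation, used as an
#' independent closed-form check of the Monte-Carlo estimate.
#'
#' @inheritParams permutation_test
#' @param N universe size.
#' @return List with `tail`, `mean`, `sd`.
#' @export
hypergeometric_oracle <- function(K, n, g_obs, N) {
  stop_if_not(K >= 0 && K <= N && n >= 0 && n <= N,
              "K and n must lie in [0, N]")
  stop_if_not(g_obs >= 0 && g_obs <= min(K, n),
              "g_obs must satisfy 0 <= g_obs <= min(K, n)")
  v <- n * (K / N) * (1 - K / N) * (N - n) / (N - 1)
  list(tail = stats::phyper(g_obs, K, N - K, n, lower.tail = FALSE),
       mean = n * K / N,
       sd = if (N == 1) 0 else sqrt(max(v, 0)))
}

#' Overlap Z-score against the permutation null
#'
#' @param g_obs observed overlap.
#' @param mu,sigma null mean and standard deviation.
#' @return `(g_obs - mu) / sigma`, or `NA` when `sigma` is 0 (degenerate
#'   null; such pairs are ranked last and excluded from significance calls).
#' @export
z_score <- function(g_obs, mu, sigma) {
  stop_if_not(all(sigma >= 0), "sigma must be >= 0")
  ifelse(sigma == 0, NA_real_, (g_obs - mu) / sigma)
}

#' Benjamini-Hochberg adjusted p values
#'
#' Standard step-up false-discovery-rate adjustment, returned in input order.
#'
#' @param p numeric vector of p values in `[0, 1]`.
#' @return Vector of q values, same order as `p`.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.04, 0.03, 0.002))  # 0.02 0.04 0.04 0.008
bh_adjust <- function(p) {
  stop_if_not(all(p >= 0 & p <= 1), "p values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Score every compound-disease pair and rank by significance
#'
#' For each pair, the observed overlap between the compound target set and
#' the disease gene set (both intersected with the universe) is compared
#' against the Monte-Carlo permutation null; BH correction is applied jointly
#' across all tested pairs. Each pair gets an independent RNG substream keyed
#' by `(seed, compound, disease)`, so the result is identical whatever order
#' pairs are processed in.
#'
#' @param signatures a `signature_set`.
#' @param diseases a `disease_network`.
#' @param universe gene universe (character vector); defaults to the
#'   signature set's measured universe.
#' @param n_perm permutations per pair (default 100,000).
#' @param seed master seed.
#' @param q_threshold significance cut on the q value (default 0.2).
#' @param min_overlap only pairs with observed overlap `>= min_overlap` are
#'   tested (default 0: all pairs).
#' @param universe_size_override use this universe size `N` for the
#'   permutation draws instead of `length(universe)` (e.g. a genome-wide
#'   20,462), keeping overlap counting inside the measured universe.
#' @param pseudocount see [permutation_test()].
#' @return Data frame sorted by `q`, then `p`, then `Z` descending (undefined
#'   `Z` last): columns `compound`, `disease_id`, `disease_label`, `K`, `n`,
#'   `overlap`, `p`, `z`, `q`, `significant`.
#' @export
prioritize_all <- function(signatures, diseases, universe = signatures$universe,
                           n_perm = 100000L, seed = 1L, q_threshold = 0.2,
                           min_overlap = 0L, universe_size_override = NULL,
                           pseudocount = FALSE) {
  stop_if_not(length(signatures$signatures) > 0, "empty signature set")
  stop_if_not(length(diseases$genes) > 0, "empty disease network")
  uni <- unique(norm_genes(universe))
  stop_if_not(length(uni) > 0, "empty gene universe")
  N <- if (is.null(universe_size_override)) length(uni)
       else as.integer(universe_size_override)
  stop_if_not(N >= length(uni), "universe size override smaller than universe")

  target_sets <- lapply(names(signatures$signatures), function(cp)
    intersect(compound_targets(signatures, cp), uni))
  names(target_sets) <- names(signatures$signatures)
  disease_sets <- lapply(diseases$genes, intersect, y = uni)
  n_dropped <- sum(lengths(diseases$genes)) - sum(lengths(disease_sets))
  if (n_dropped > 0)
    message(n_dropped, " disease-gene annotations outside the universe dropped")

  grid <- expand.grid(compound = names(target_sets),
                      disease_id = names(disease_sets),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    cp <- grid$compound[i]; di <- grid$disease_id[i]
    K <- length(target_sets[[cp]]); n <- length(disease_sets[[di]])
    g <- length(intersect(target_sets[[cp]], disease_sets[[di]]))
    if (g < min_overlap) return(NULL)
    pt <- permutation_test(K, n, g, N, n_perm = n_perm,
                           seed = seed_stream(seed, cp, di),
                           pseudocount = pseudocount)
    data.frame(compound = cp, disease_id = di,
               disease_label = unname(diseases$labels[[di]]),
               K = K, n = n, overlap = g, p = pt$p,
               z = z_score(g, pt$mu, pt$sigma),
               n_exceed = pt$n_exceed, n_tie = pt$n_tie,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  stop_if_not(!is.null(res) && nrow(res) > 0,
              "no pair passes the min_overlap filter")
  res$q <- bh_adjust(res$p)
  res$significant <- res$q < q_threshold & !is.na(res$z)
  ord <- order(res$q, res$p, -res$z, na.last = TRUE)
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_perm") <- as.integer(n_perm)
  attr(res, "universe_N") <- N
  res
}

#' Write ranked pair results as TSV and the significant pairs as SIF
#' @param results data frame from [prioritize_all()].
#' @param path output TSV path.
#' @param sif_path optional SIF path for significant compound-disease edges.
#' @return `path`, invisibly.
#' @export
write_pair_results <- function(results, path, sif_path = NULL) {
  cols <- c("compound", "disease_id", "disease_label", "K", "n", "overlap",
            "p", "z", "q", "significant")
  write_tsv(results[, cols], path, na = "")
  if (!is.null(sif_path)) {
    sig <- results[results$significant, , drop = FALSE]
    write_sif(sig$compound, sig$disease_id, "targets", sif_path)
  }
  invisible(path)
}
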