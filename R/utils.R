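#' Derive a reproducible RNG substream seed from a master seed and labels
#'
#' Hashes the master seed together with an arbitrary number of string labels
#' into an integer in `[0, 2^31 - 2]`, suitable for `set.seed()`. Keying
#' substreams by content (e.g. compound and disease identifiers) rather than
#' by iteration order makes results independent of the order in which pairs
#' are processed.
#'
#' The hash is a plain polynomial rolling hash over UTF-8 bytes modulo the
#' Mersenne prime 2^31 - 1, implemented in integer-exact double arithmetic so
#' it is identical on every platform.
#'
#' @param seed integer master seed.
#' @param ... character labels identifying the substream.
#' @return A single integer seed.
#' @export
#' @examples
#' seed_stream(1, "expression")
#' seed_stream(1, "compound_3", "disease_C04.588.180")
seed_stream <- function(seed, ...) {
  labels <- paste(c(format(as.integer(seed)), ...), collapse = "\x1f")
  bytes <- utf8ToInt(labels)
  mod <- 2147483647  # 2^31 - 1
  h <- 2166136261 %% mod
  for (b in bytes) {
    h <- (h * 131 + b) %% mod  # 131 * mod < 2^53: exact in doubles
  }
  as.integer(h)
}

#' Round half away from zero
#'
#' Base R's `round()` rounds halves to even; summary averages here use the
#' conventional round-half-away-from-zero so that printed per-entity averages
#' match simple arithmetic.
#'
#' @param x numeric vector.
#' @return Integer-valued numeric vector.
#' @export
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Average interactions per entity, rounded as printed in summary tables
#'
#' @param n_interactions total number of bipartite interactions.
#' @param n_entities number of entities (compounds or diseases).
#' @return Rounded average (half away from zero); 0 when `n_entities` is 0.
#' @export
#' @examples
#' summary_average(43839, 102)  # 430
#' summary_average(39262, 293)  # 134
summary_average <- function(n_interactions, n_entities) {
  if (n_entities == 0) return(0)
  round_half_up(n_interactions / n_entities)
}

# Normalize gene symbols: uppercase, trimmed. Applied before every set
# operation pipeline-wide.
norm_genes <- function(x) {
  toupper(trimws(x))
}

stop_if_not <- function(cond, ...) {
  if (!isTRUE(cond)) stop(..., call. = FALSE)
}

write_tsv <- function(df, path, na = "") {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = na)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", check.names = FALSE, quote = "",
                    stringsAsFactors = FALSE, ...)
}
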