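#' Put unordered gene pairs into canonical order
#'
#' Every pair table in netforge stores an unordered gene pair once, with the
#' lexicographically smaller identifier in `gene_a`. This helper enforces that
#' convention, drops nothing, and errors on self-pairs (a gene is never
#' co-functional with itself in this framework).
#'
#' @param pairs A data frame with character columns `gene_a` and `gene_b`.
#' @param dedup Collapse duplicate unordered pairs? If `FALSE` (default) the
#'   caller is responsible for uniqueness.
#' @return A tibble with the same columns, pairs canonically ordered.
#' @examples
#' canonical_pairs(tibble::tibble(gene_a = "g2", gene_b = "g1"))
#' @export
canonical_pairs <- function(pairs, dedup = FALSE) {
  .check_edges(pairs)
  a <- as.character(pairs$gene_a)
  b <- as.character(pairs$gene_b)
  if (any(a == b)) {
    bad <- which(a == b)[1L]
    abort(sprintf("self-pair not allowed: '%s' (row %d)", a[bad], bad))
  }
  swap <- a > b
  out <- as_tibble(pairs)
  out$gene_a <- ifelse(swap, b, a)
  out$gene_b <- ifelse(swap, a, b)
  if (dedup) out <- distinct(out, .data$gene_a, .data$gene_b, .keep_all = TRUE)
  out
}

# internal: a unique string key per unordered pair (gene ids never contain tab)
.pair_key <- function(gene_a, gene_b) {
  paste(pmin(gene_a, gene_b), pmax(gene_a, gene_b), sep = "\t")
}

#' Enumerate all unordered pairs of a gene vector
#'
#' @param genes Character vector of gene identifiers (made unique).
#' @return Tibble with columns `gene_a`, `gene_b`, each unordered pair once,
#'   canonically ordered.
#' @export
all_pairs <- function(genes) {
  genes <- sort(unique(as.character(genes)))
  n <- length(genes)
  if (n < 2L) {
    return(tibble(gene_a = character(), gene_b = character()))
  }
  idx <- combn(n, 2L)
  tibble(gene_a = genes[idx[1L, ]], gene_b = genes[idx[2L, ]])
}
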