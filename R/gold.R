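#' Filter annotation terms before gold-standard construction
#'
#' Very broad terms dominate pair counts (a term with k genes yields
#' C(k, 2) positive pairs) and bias the training set toward generic biology,
#' so terms with more than `max_term_size` genes are dropped. When a term
#' depth (`level`) is available — typically only for GO Biological Process —
#' terms outside `[min_level, max_level]` are dropped too: shallow terms are
#' too general, deep terms too specific. Sources without level metadata are
#' filtered on size only.
#'
#' @param ann Annotation tibble `(term, gene)`.
#' @param max_term_size Maximum number of genes a term may annotate
#'   (default 300).
#' @param min_level,max_level Inclusive term-depth range (defaults 2 and 10).
#' @param meta Optional tibble `(term, level)`; when `NULL` (default) the
#'   `term_meta` attribute of `ann` is used if it carries a `level` column,
#'   otherwise the level filter is skipped.
#' @return The filtered annotation tibble (with a warning if nothing
#'   survives).
#' @export
filter_terms <- function(ann, max_term_size = 300L, min_level = 2L,
                         max_level = 10L, meta = NULL) {
  stopifnot(max_term_size >= 2L, min_level <= max_level)
  if (is.null(meta)) meta <- attr(ann, "term_meta")
  keep <- ann %>%
    count(.data$term, name = "size") %>%
    filter(.data$size <= max_term_size) %>%
    pull("term")
  if (!is.null(meta) && "level" %in% names(meta)) {
    lev_ok <- meta %>%
      filter(.data$level >= min_level, .data$level <= max_level) %>%
      pull("term")
    keep <- intersect(keep, lev_ok)
  }
  out <- filter(ann, .data$term %in% keep)
  if (nrow(out) == 0L) warn("term filter removed every term")
  attr(out, "term_meta") <- attr(ann, "term_meta")
  out
}

#' Build gold-standard positive pairs
#'
#' Positive co-functional pairs are all unordered pairs of genes sharing at
#' least one annotation term; each pair is reported once however many terms
#' it shares.
#'
#' @param ann A (pre-filtered) annotation tibble `(term, gene)`.
#' @return Tibble `(gene_a, gene_b)` in canonical order.
#' @export
build_positives <- function(ann) {
  by_term <- split(unique(ann[c("term", "gene")])$gene, ann$term)
  pos <- purrr::map_dfr(by_term, function(genes) all_pairs(genes))
  if (nrow(pos) == 0L) return(tibble(gene_a = character(), gene_b = character()))
  distinct(pos, .data$gene_a, .data$gene_b) %>%
    arrange(.data$gene_a, .data$gene_b)
}

#' Build gold-standard negative pairs
#'
#' Negative pairs are unordered pairs of *annotated* genes that share no
#' annotation term. Together with [build_positives()] this partitions all
#' pairs of annotated genes.
#'
#' @inheritParams build_positives
#' @return Tibble `(gene_a, gene_b)` in canonical order.
#' @export
build_negatives <- function(ann) {
  genes <- sort(unique(ann$gene))
  all_pairs(genes) %>%
    anti_join(build_positives(ann), by = c("gene_a", "gene_b")) %>%
    arrange(.data$gene_a, .data$gene_b)
}

#' Construct a gold standard from an annotation set
#'
#' @inheritParams build_positives
#' @param filter Apply [filter_terms()] first?
#' @param ... Passed to [filter_terms()].
#' @return A `gold_standard` object: list with tibbles `positives` and
#'   `negatives` (columns `gene_a`, `gene_b`) and the character `universe`
#'   of annotated genes.
#' @export
build_gold_standard <- function(ann, filter = TRUE, ...) {
  if (filter) ann <- filter_terms(ann, ...)
  gold_standard(build_positives(ann), build_negatives(ann))
}

#' @param positives,negatives Pair tibbles `(gene_a, gene_b)`.
#' @rdname build_gold_standard
#' @export
gold_standard <- function(positives, negatives) {
  positives <- canonical_pairs(positives, dedup = TRUE) %>%
    select("gene_a", "gene_b")
  negatives <- canonical_pairs(negatives, dedup = TRUE) %>%
    select("gene_a", "gene_b") %>%
    anti_join(positives, by = c("gene_a", "gene_b"))
  structure(
    list(
      positives = arrange(positives, .data$gene_a, .data$gene_b),
      negatives = arrange(negatives, .data$gene_a, .data$gene_b),
      universe = sort(unique(c(positives$gene_a, positives$gene_b,
                               negatives$gene_a, negatives$gene_b)))
    ),
    class = "gold_standard"
  )
}

#' @export
print.gold_standard <- function(x, ...) {
  cat(sprintf("<gold_standard> %d positives, %d negatives, %d genes\n",
              nrow(x$positives), nrow(x$negatives), length(x$universe)))
  invisible(x)
}

#' Merge gold standards from several annotation sources
#'
#' Positives are the union of all sources' positives. A pair that is positive
#' anywhere is treated as positive overall — a shared annotation in any one
#' source is positive evidence — so merged negatives are the union of
#' negatives minus the merged positives.
#'
#' @param standards A list of `gold_standard` objects (length >= 1).
#' @return A merged `gold_standard`.
#' @export
merge_gold <- function(standards) {
  stopifnot(length(standards) >= 1L)
  pos <- distinct(bind_rows(lapply(standards, `[[`, "positives")))
  neg <- distinct(bind_rows(lapply(standards, `[[`, "negatives")))
  gold_standard(pos, neg)
}

# internal: label a pair table against a gold standard; unlabeled pairs get NA
.gold_label <- function(pairs, gold) {
  pairs <- canonical_pairs(pairs)
  key <- .pair_key(pairs$gene_a, pairs$gene_b)
  pos_key <- .pair_key(gold$positives$gene_a, gold$positives$gene_b)
  neg_key <- .pair_key(gold$negatives$gene_a, gold$negatives$gene_b)
  pairs$label <- ifelse(key %in% pos_key, "positive",
                        ifelse(key %in% neg_key, "negative", NA_character_))
  pairs
}
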