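# long (from, to, w) view of an undirected edge table: each edge twice
.edges_long <- function(net) {
  wc <- .weight_col(net)
  net <- canonical_pairs(net)
  tibble(
    from = c(net$gene_a, net$gene_b),
    to = c(net$gene_b, net$gene_a),
    w = rep(net[[wc]], 2L)
  )
}

#' Neighborhood-based gene prioritization
#'
#' Ranks candidate genes for a phenotype by the summed edge weight (LLS/WS)
#' of their direct connections to a set of guide genes known to be involved
#' in that phenotype. Guide genes themselves are never candidates; genes
#' with no guide connection are not listed. When at least two guides are in
#' the network, the leave-one-out ROC AUC of the guide set ([loo_auc()]) is
#' reported as the predictive-power estimate, with AUC > 0.7 flagged as
#' good.
#'
#' @param net Edge table with a weight column.
#' @param guides Character vector of guide gene ids; guides absent from the
#'   network are dropped with a message.
#' @param top Size of the highlighted head of the ranking (default 100).
#' @return A `prioritization` object: list with `candidates` (tibble
#'   `gene, score, rank, top`), `auc`, `auc_good`, `guides_used`.
#' @export
neighborhood_scores <- function(net, guides, top = 100L) {
  .check_edges(net)
  genes <- unique(c(net$gene_a, net$gene_b))
  guides_in <- intersect(unique(guides), genes)
  if (length(guides_in) == 0L) abort("no guide gene is present in the network")
  if (length(guides_in) < length(unique(guides))) {
    inform(sprintf("%d guide gene(s) absent from the network were dropped",
                   length(unique(guides)) - length(guides_in)))
  }
  long <- .edges_long(net)
  cand <- long %>%
    filter(.data$to %in% guides_in, !(.data$from %in% guides_in)) %>%
    group_by(gene = .data$from) %>%
    summarise(score = sum(.data$w), .groups = "drop") %>%
    filter(.data$score > 0) %>%
    arrange(desc(.data$score), .data$gene) %>%
    mutate(rank = row_number(), top = .data$rank <= top)
  auc <- if (length(guides_in) >= 2L) loo_auc(net, guides_in) else NA_real_
  structure(
    list(
      candidates = cand,
      auc = auc,
      auc_good = isTRUE(auc > 0.7),
      guides_used = sort(guides_in)
    ),
    class = "prioritization"
  )
}

#' @export
print.prioritization <- function(x, ...) {
  cat(sprintf("<prioritization> %d candidates from %d guide genes\n",
              nrow(x$candidates), length(x$guides_used)))
  if (!is.na(x$auc)) {
    cat(sprintf("  leave-one-out AUC = %.3f (%s predictive power)\n",
                x$auc, if (x$auc_good) "good" else "weak"))
  }
  invisible(x)
}

#' @method tidy prioritization
#' @export
tidy.prioritization <- function(x, ...) x$candidates

#' @method glance prioritization
#' @export
glance.prioritization <- function(x, ...) {
  tibble(
    n_guides = length(x$guides_used),
    n_candidates = nrow(x$candidates),
    auc = x$auc,
    auc_good = x$auc_good
  )
}

#' Leave-one-out ROC AUC of a guide-gene set
#'
#' Measures how well the network's neighborhood scoring retrieves known
#' genes: each guide in turn is held out, scored (like every non-guide
#' gene) by its summed edge weight to the remaining guides, and compared
#' with all non-guide gene scores. The AUC is the Mann-Whitney probability
#' that a held-out guide outscores a random non-guide (ties count 0.5),
#' averaged over guides — 0.5 for random expectation, 1 for perfect
#' retrieval.
#'
#' @inheritParams neighborhood_scores
#' @return A single AUC value.
#' @export
loo_auc <- function(net, guides) {
  .check_edges(net)
  genes <- unique(c(net$gene_a, net$gene_b))
  guides_in <- intersect(unique(guides), genes)
  if (length(guides_in) < 2L) {
    abort("need >= 2 guide genes present in the network")
  }
  n_drop <- length(setdiff(unique(guides), guides_in))
  if (n_drop > 0L) {
    inform(sprintf("%d guide gene(s) absent from the network ignored", n_drop))
  }
  long <- .edges_long(net)
  to_guide <- filter(long, .data$to %in% guides_in)
  # S[v]: summed weight from v to the full guide set (no self-edges exist)
  s_all <- to_guide %>%
    group_by(.data$from) %>%
    summarise(s = sum(.data$w), .groups = "drop")
  s_vec <- setNames(s_all$s, s_all$from)
  score_of <- function(g) ifelse(is.na(s_vec[g]), 0, s_vec[g])
  non_guides <- setdiff(genes, guides_in)
  if (length(non_guides) == 0L) abort("network has no non-guide genes")
  s_non_base <- unname(score_of(non_guides))
  aucs <- vapply(guides_in, function(g) {
    # scores under the guide set minus g: subtract each non-guide's edge to g
    adj <- filter(to_guide, .data$to == g, .data$from %in% non_guides)
    s_non <- s_non_base
    if (nrow(adj) > 0L) {
      ix <- match(adj$from, non_guides)
      s_non[ix] <- s_non[ix] - adj$w
    }
    s_g <- unname(score_of(g))
    mean((s_g > s_non) + 0.5 * (s_g == s_non))
  }, numeric(1L))
  mean(aucs)
}

#' Context-based prioritization through network hubs
#'
#' When too few guide genes are known for a phenotype, a set of
#' differentially expressed genes (DEGs) from the relevant biological
#' context can be used instead: central hub genes (degree >=
#' `min_degree`) whose direct neighborhoods are enriched for the DEGs are
#' returned as candidates. Enrichment of each hub's neighborhood among the
#' DEGs is evaluated by the one-tailed Fisher's exact test (hypergeometric
#' tail) over the network's gene universe excluding the hub itself, and
#' hubs with `p <= p_cut` are reported, most significant first. P-values
#' are not adjusted by default, matching the single-cutoff usage; set
#' `adjust = TRUE` for Benjamini-Hochberg.
#'
#' @param net Edge table.
#' @param degs Character vector of DEG ids (an unweighted set).
#' @param min_degree Hub degree threshold (default 50).
#' @param p_cut P-value cutoff (default 0.01).
#' @param adjust Apply Benjamini-Hochberg before the cutoff?
#' @return Tibble `(gene, degree, overlap, p_value)`; empty (with a
#'   warning) when no gene reaches `min_degree`.
#' @export
context_hubs <- function(net, degs, min_degree = 50L, p_cut = 0.01,
                         adjust = FALSE) {
  .check_edges(net)
  net <- canonical_pairs(net)
  genes <- unique(c(net$gene_a, net$gene_b))
  degs <- unique(degs)
  if (length(intersect(degs, genes)) == 0L) {
    abort("no DEG is present in the network")
  }
  deg_tab <- table(c(net$gene_a, net$gene_b))
  hubs <- names(deg_tab)[deg_tab >= min_degree]
  if (length(hubs) == 0L) {
    warn(sprintf("no gene reaches the hub degree threshold %d", min_degree))
    return(tibble(gene = character(), degree = integer(),
                  overlap = integer(), p_value = numeric()))
  }
  long <- .edges_long(net)
  nbr <- split(long$to, long$from)
  n_univ <- length(genes) - 1L  # universe excludes the hub itself
  res <- purrr::map_dfr(hubs, function(h) {
    neighbors <- nbr[[h]]
    k_deg <- length(intersect(degs, setdiff(genes, h)))
    overlap <- length(intersect(neighbors, degs))
    p <- phyper(overlap - 1L, k_deg, n_univ - k_deg, length(neighbors),
                lower.tail = FALSE)
    tibble(gene = h, degree = length(neighbors),
           overlap = overlap, p_value = p)
  })
  if (adjust) res$p_value <- stats::p.adjust(res$p_value, method = "BH")
  res %>%
    filter(.data$p_value <= p_cut) %>%
    arrange(.data$p_value, .data$gene)
}

#' Predict gene function from annotated network neighbors
#'
#' Candidate functional terms for a query gene are the annotation terms of
#' its direct network neighbors, ranked by the summed weight of the edges to
#' the neighbors carrying each term; the top `k` terms are returned.
#'
#' @param net Edge table with a weight column.
#' @param query A single gene id present in the network.
#' @param ann Annotation tibble `(term, gene)`.
#' @param k Number of terms to return (default 10).
#' @return Tibble `(term, score)`, descending score (ties lexicographic);
#'   empty with a message when no neighbor is annotated.
#' @export
predict_function <- function(net, query, ann, k = 10L) {
  .check_edges(net)
  stopifnot(length(query) == 1L)
  genes <- unique(c(net$gene_a, net$gene_b))
  if (!query %in% genes) abort(sprintf("query gene '%s' not in network", query))
  long <- .edges_long(net) %>% filter(.data$from == query)
  scored <- long %>%
    inner_join(distinct(ann, .data$term, gene = .data$gene),
               by = c(to = "gene"), relationship = "many-to-many") %>%
    group_by(.data$term) %>%
    summarise(score = sum(.data$w), .groups = "drop") %>%
    arrange(desc(.data$score), .data$term)
  if (nrow(scored) == 0L) {
    inform(sprintf("no annotated neighbor for '%s'", query))
    return(tibble(term = character(), score = numeric()))
  }
  slice_head(scored, n = k)
}

#' Guilt-by-association benchmark over an annotation set
#'
#' Runs [term_recovery_auc()] over all qualifying terms and summarises the
#' network's overall functional predictive power: the median per-term
#' leave-one-out AUC and a one-sided Wilcoxon signed-rank test of the AUCs
#' against the 0.5 random expectation.
#'
#' @inheritParams term_recovery_auc
#' @return A `gba_benchmark` object: list with `terms` (tibble
#'   `term, n_members, auc`), `median_auc`, `p_value`.
#' @export
gba_benchmark <- function(net, ann, min_term = 5L) {
  terms <- term_recovery_auc(net, ann, min_term = min_term)
  if (nrow(terms) == 0L) abort("no annotation term qualifies for benchmarking")
  p <- tryCatch(
    wilcox.test(terms$auc, mu = 0.5, alternative = "greater",
                exact = FALSE)$p.value,
    error = function(e) NA_real_
  )
  structure(
    list(terms = terms, median_auc = median(terms$auc), p_value = p),
    class = "gba_benchmark"
  )
}

#' @export
print.gba_benchmark <- function(x, ...) {
  cat(sprintf(
    "<gba_benchmark> %d terms; median AUC = %.3f (Wilcoxon vs 0.5: P = %.3g)\n",
    nrow(x$terms), x$median_auc, x$p_value))
  invisible(x)
}

#' @method tidy gba_benchmark
#' @export
tidy.gba_benchmark <- function(x, ...) x$terms

#' @method glance gba_benchmark
#' @export
glance.gba_benchmark <- function(x, ...) {
  tibble(n_terms = nrow(x$terms), median_auc = x$median_auc,
         p_value = x$p_value)
}
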