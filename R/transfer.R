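#' Bidirectional best hits
#'
#' The simplest orthology map: gene `a` (species A, the network source) and
#' gene `b` (species B, the target) are linked iff `b` is `a`'s best
#' `AB`-direction hit and `a` is `b`'s best `BA`-direction hit. Best-hit
#' ties are resolved deterministically (highest score, then lexicographic
#' subject id) and reported with a message. All BBH links carry inparalog
#' score 1.
#'
#' @param sim Similarity tibble `(query, subject, direction, score)` with
#'   both `AB` and `BA` directions present; see [read_similarity_table()].
#' @return Orthology map tibble
#'   `(gene_src, gene_tgt, inparalog_score, cluster_id)`.
#' @export
bbh <- function(sim) {
  ab <- filter(sim, .data$direction == "AB")
  ba <- filter(sim, .data$direction == "BA")
  if (nrow(ab) == 0L || nrow(ba) == 0L) {
    abort("similarity table must contain both AB and BA directions")
  }
  best_ab <- .best_hits(ab)
  best_ba <- .best_hits(ba)
  links <- inner_join(
    select(best_ab, gene_src = "query", gene_tgt = "subject", score_ab = "score"),
    select(best_ba, gene_tgt = "query", gene_src = "subject", score_ba = "score"),
    by = c("gene_src", "gene_tgt")
  ) %>%
    arrange(.data$gene_src, .data$gene_tgt)
  tibble(
    gene_src = links$gene_src,
    gene_tgt = links$gene_tgt,
    inparalog_score = 1,
    cluster_id = paste0("c", seq_len(nrow(links))),
    seed_score = (links$score_ab + links$score_ba) / 2
  )
}

# best hit per query; deterministic tie-break: max score then lexicographic
.best_hits <- function(hits) {
  ties <- hits %>%
    group_by(.data$query) %>%
    filter(.data$score == max(.data$score)) %>%
    summarise(n_tied = n(), .groups = "drop") %>%
    filter(.data$n_tied > 1L)
  if (nrow(ties) > 0L) {
    inform(sprintf(
      "%d query gene(s) had tied best hits; resolved lexicographically",
      nrow(ties)))
  }
  hits %>%
    arrange(.data$query, desc(.data$score), .data$subject) %>%
    group_by(.data$query) %>%
    slice(1L) %>%
    ungroup()
}

#' InParanoid-style orthology clusters
#'
#' Extends [bbh()] seed pairs with same-species inparalogs: genes whose
#' within-species similarity to a seed gene (directions `AA`/`BB` in the
#' similarity table) reaches at least `overlap_cut` of the seed pair's
#' cross-species score join the cluster with confidence
#' `min(1, sim(gene, seed gene) / sim(seed pair))` — 1 for a duplicate
#' exactly as similar as the seed itself, shrinking toward `overlap_cut` for
#' more diverged duplicates. Each emitted link pairs one source-side with
#' one target-side cluster member and carries the product of the two member
#' confidences (seed genes have confidence 1). A gene claimed by several
#' clusters keeps only its links in the cluster with the highest seed score.
#'
#' @inheritParams bbh
#' @param overlap_cut Minimum similarity ratio for cluster membership
#'   (default 0.5).
#' @return Orthology map tibble
#'   `(gene_src, gene_tgt, inparalog_score, cluster_id)`.
#' @export
inparanoid_clusters <- function(sim, overlap_cut = 0.5) {
  stopifnot(overlap_cut > 0, overlap_cut <= 1)
  seeds <- bbh(sim)
  within <- filter(sim, .data$direction %in% c("AA", "BB"))
  members <- purrr::pmap_dfr(
    seeds[c("gene_src", "gene_tgt", "cluster_id", "seed_score")],
    function(gene_src, gene_tgt, cluster_id, seed_score) {
      bind_rows(
        tibble(cluster_id, side = "src", gene = gene_src, conf = 1,
               seed_score),
        tibble(cluster_id, side = "tgt", gene = gene_tgt, conf = 1,
               seed_score),
        .inparalogs(within, "AA", gene_src, cluster_id, seed_score,
                    overlap_cut, side = "src"),
        .inparalogs(within, "BB", gene_tgt, cluster_id, seed_score,
                    overlap_cut, side = "tgt")
      )
    }
  )
  # conflict resolution: a gene belongs to the cluster with the best seed
  members <- members %>%
    arrange(.data$gene, desc(.data$seed_score), .data$cluster_id) %>%
    distinct(.data$gene, .keep_all = TRUE)
  links <- members %>%
    filter(.data$side == "src") %>%
    inner_join(
      members %>%
        filter(.data$side == "tgt") %>%
        select("cluster_id", gene_tgt = "gene", conf_tgt = "conf"),
      by = "cluster_id", relationship = "many-to-many"
    )
  tibble(
    gene_src = links$gene,
    gene_tgt = links$gene_tgt,
    inparalog_score = pmin(1, links$conf * links$conf_tgt),
    cluster_id = links$cluster_id
  ) %>%
    arrange(.data$cluster_id, desc(.data$inparalog_score),
            .data$gene_src, .data$gene_tgt)
}

.inparalogs <- function(within, dir, seed_gene, cluster_id, seed_score,
                        overlap_cut, side) {
  empty <- tibble(cluster_id = character(), side = character(),
                  gene = character(), conf = numeric(), seed_score = numeric())
  raw <- within %>%
    filter(.data$direction == dir,
           .data$query == seed_gene | .data$subject == seed_gene) %>%
    mutate(gene = ifelse(.data$query == seed_gene, .data$subject, .data$query)) %>%
    filter(.data$gene != seed_gene)
  if (nrow(raw) == 0L) return(empty)
  hits <- raw %>%
    group_by(.data$gene) %>%
    summarise(score = max(.data$score), .groups = "drop") %>%
    mutate(ratio = .data$score / seed_score) %>%
    filter(.data$ratio >= overlap_cut)
  if (nrow(hits) == 0L) return(empty)
  tibble(cluster_id, side, gene = hits$gene,
         conf = pmin(1, hits$ratio), seed_score)
}

#' Transfer a network across species through an orthology map
#'
#' Projects every source edge (A', B') onto the target proteome: each target
#' pair (A, B) reachable through orthology links A-A' and B-B' receives the
#' InParanoid-weighted LLS
#' `IWLLS(A, B) = LLS(A', B') * s(A, A') * s(B, B')`, the source weight
#' discounted by the two link confidences. When several source edges map to
#' the same target pair, the maximum candidate is kept (summing would
#' double-count paralog fan-out). Pairs collapsing to a single target gene
#' are discarded. Since confidences are in [0, 1], a transferred edge never
#' outweighs its source.
#'
#' @param net_src Source network tibble with a weight column.
#' @param omap Orthology map from [bbh()] or [inparanoid_clusters()]
#'   (columns `gene_src`, `gene_tgt`, `inparalog_score`).
#' @return Component-network tibble `(gene_a, gene_b, lls)` over target
#'   genes, descending LLS.
#' @export
transfer_network <- function(net_src, omap) {
  .check_edges(net_src)
  wc <- .weight_col(net_src)
  net <- canonical_pairs(net_src)
  map_tbl <- select(omap, "gene_src", "gene_tgt", "inparalog_score")
  cand <- net %>%
    inner_join(rename(map_tbl, gene_a = "gene_src", tgt_a = "gene_tgt",
                      s_a = "inparalog_score"),
               by = "gene_a", relationship = "many-to-many") %>%
    inner_join(rename(map_tbl, gene_b = "gene_src", tgt_b = "gene_tgt",
                      s_b = "inparalog_score"),
               by = "gene_b", relationship = "many-to-many") %>%
    filter(.data$tgt_a != .data$tgt_b) %>%
    mutate(iwlls = .data[[wc]] * .data$s_a * .data$s_b)
  if (nrow(cand) == 0L) {
    abort("orthology map does not cover both endpoints of any source edge")
  }
  canonical_pairs(tibble(
    gene_a = cand$tgt_a, gene_b = cand$tgt_b, lls = cand$iwlls
  )) %>%
    group_by(.data$gene_a, .data$gene_b) %>%
    summarise(lls = max(.data$lls), .groups = "drop") %>%
    arrange(desc(.data$lls), .data$gene_a, .data$gene_b)
}

#' Annotation-term recovery AUC of a network
#'
#' Guilt-by-association quality check, typically applied to a transferred
#' network: for every annotation term with at least `min_term` member genes
#' present in the network, the members are used as guide genes and the
#' leave-one-out ROC AUC ([loo_auc()]) measures how highly the network
#' ranks each held-out member among non-members.
#'
#' @param net Edge table with a weight column.
#' @param ann Annotation tibble `(term, gene)`.
#' @param min_term Minimum members-in-network per term (default 5).
#' @return Tibble `(term, n_members, auc)`; terms whose members are absent
#'   from the network are skipped with a message.
#' @export
term_recovery_auc <- function(net, ann, min_term = 5L) {
  if (nrow(ann) == 0L) abort("annotation set is empty")
  net_genes <- unique(c(net$gene_a, net$gene_b))
  by_term <- ann %>%
    filter(.data$gene %in% net_genes) %>%
    distinct(.data$term, .data$gene)
  sizes <- count(by_term, .data$term, name = "n_members")
  keep <- filter(sizes, .data$n_members >= min_term)
  n_skip <- length(unique(ann$term)) - nrow(keep)
  if (n_skip > 0L) {
    inform(sprintf("skipping %d term(s) with < %d members in the network",
                   n_skip, min_term))
  }
  purrr::map_dfr(keep$term, function(tm) {
    guides <- by_term$gene[by_term$term == tm]
    tibble(term = tm, n_members = length(guides),
           auc = loo_auc(net, guides))
  })
}
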