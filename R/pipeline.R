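#' Run the full construction pipeline on a synthetic world
#'
#' Convenience driver chaining the whole stack on a [generate_world()]
#' fixture: gold standard from the world's annotation terms, evidence
#' scoring per channel, LLS calibration of each scored table, and
#' weighted-sum integration of the resulting component networks. Mirrors
#' exactly what a user would do with real files, and is what the package's
#' end-to-end recovery checks run.
#'
#' @param world A `synthetic_world`.
#' @param evidence Evidence channels to score (default all five).
#' @param bin_size Gold pairs per calibration bin (default 100; worlds are
#'   small).
#' @param B Bootstrap resamples for calibration; 0 (default) fits
#'   in-sample only.
#' @param D,T Weighted-sum integration parameters.
#' @param min_lls Component-network threshold passed to
#'   [apply_lls_model()].
#' @param seed Seed for the bootstrap (only used when `B > 0`).
#' @return List with `gold` (`gold_standard`), `scored` (named list of
#'   scored pair tables), `models` (named list of `lls_model`s),
#'   `components` (named list of component networks) and `network` (the
#'   integrated network tibble).
#' @export
build_world_network <- function(world,
                                evidence = c("coexpression", "phylo",
                                             "domain", "neighbor_prob",
                                             "neighbor_dist"),
                                bin_size = 100L, B = 0L, D = 2, T = 0,
                                min_lls = 0, seed = 1L) {
  stopifnot(inherits(world, "synthetic_world"))
  evidence <- match.arg(evidence, several.ok = TRUE)
  gold <- build_gold_standard(world$annotations, filter = TRUE)
  scorers <- list(
    coexpression = function() coexpression_scores(world$expression),
    phylo = function() profile_scores(world$phylo_profiles),
    domain = function() {
      profile_scores(domain_profiles(world$domain_ann,
                                     length(world$genes)))
    },
    neighbor_prob = function() {
      neighborhood_probability_scores(world$gene_orders)
    },
    neighbor_dist = function() {
      neighborhood_distance_scores(world$gene_orders)
    }
  )
  scored <- lapply(scorers[evidence], function(f) f())
  models <- list()
  components <- list()
  for (id in names(scored)) {
    spt <- scored[[id]][c("gene_a", "gene_b", "score")]
    model <- tryCatch({
      if (B > 0L) {
        bootstrap_lls_model(spt, gold, bin_size = bin_size, B = B,
                            seed = seed, dataset_id = id)
      } else {
        fit_lls_model(spt, gold, bin_size = bin_size, dataset_id = id)
      }
    }, error = function(e) {
      inform(sprintf("skipping evidence '%s': %s", id, conditionMessage(e)))
      NULL
    })
    if (is.null(model)) next
    models[[id]] <- model
    components[[id]] <- apply_lls_model(model, spt, min_lls = min_lls)
  }
  if (length(components) == 0L) {
    abort("no evidence channel could be calibrated against the gold standard")
  }
  network <- integrate_networks(components, D = D, T = T)
  list(gold = gold, scored = scored, models = models,
       components = components, network = network)
}

#' Fraction of truth pairs recovered among the top-ranked edges
#'
#' @param net Integrated (or component) network, ranked by its weight
#'   column.
#' @param truth Pair tibble `(gene_a, gene_b)` of planted co-functional
#'   pairs.
#' @param n_top Number of top edges to inspect; defaults to `nrow(truth)`.
#' @return Fraction of `truth` present in the top `n_top` edges.
#' @export
truth_recovery <- function(net, truth, n_top = nrow(truth)) {
  wc <- .weight_col(net)
  top <- net %>%
    arrange(desc(.data[[wc]]), .data$gene_a, .data$gene_b) %>%
    slice_head(n = n_top)
  truth <- canonical_pairs(truth)
  mean(.pair_key(truth$gene_a, truth$gene_b) %in%
         .pair_key(top$gene_a, top$gene_b))
}

#' Degree-preserving rewired null of a network
#'
#' Double-edge-swap rewiring (10 |E| swaps) that preserves every gene's
#' degree while destroying modular structure; weights are reassigned to the
#' rewired edges in their original order. Used as the null model for
#' clustering and guilt-by-association calibration.
#'
#' @param net Edge table with a weight column.
#' @param seed Integer seed.
#' @return Rewired edge tibble with the same columns.
#' @export
rewire_network <- function(net, seed = 1L) {
  wc <- .weight_col(net)
  g <- .as_igraph(net)
  gr <- withr::with_seed(seed, {
    igraph::rewire(g, igraph::keeping_degseq(niter = 10L * igraph::ecount(g)))
  })
  el <- igraph::as_edgelist(gr)
  out <- canonical_pairs(tibble(gene_a = el[, 1L], gene_b = el[, 2L]))
  net_sorted <- canonical_pairs(net) %>%
    arrange(desc(.data[[wc]]), .data$gene_a, .data$gene_b)
  out[[wc]] <- net_sorted[[wc]]
  arrange(out, desc(.data[[wc]]), .data$gene_a, .data$gene_b)
}
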