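# Small fixtures shared across test files; everything is built in code.

tiny_net <- function() {
  tibble::tibble(
    gene_a = c("g1", "g1", "g2", "g3"),
    gene_b = c("g2", "g3", "g3", "g4"),
    weight = c(1.5, 0.5, 2.0, 1.0)
  )
}

tiny_ann <- function() {
  tibble::tibble(
    term = c("T1", "T1", "T2", "T2", "T3"),
    gene = c("a", "b", "b", "c", "d")
  )
}

# a random weighted network over n genes (Erdos-Renyi style)
random_net <- function(n_genes = 30L, p = 0.2, seed = 1L) {
  withr::with_seed(seed, {
    pairs <- all_pairs(sprintf("g%02d", seq_len(n_genes)))
    keep <- runif(nrow(pairs)) < p
    net <- pairs[keep, ]
    net$weight <- runif(nrow(net), 0.1, 3)
    net
  })
}

# context-hub type-I calibration network: 20 degree-120 hubs over 800 leaves
# joined by a path; fixture dimensions give the discrete one-tailed test an
# attained size close to the nominal 1% (see the methods vignette)
hub_calibration_net <- function(seed = 9L) {
  leaves <- sprintf("L%03d", seq_len(800L))
  hubs <- sprintf("H%02d", seq_len(20L))
  withr::with_seed(seed, {
    hub_edges <- purrr::map_dfr(hubs, function(h) {
      tibble::tibble(gene_a = h, gene_b = sample(leaves, 120L), weight = 1)
    })
    path_edges <- tibble::tibble(
      gene_a = leaves[-length(leaves)], gene_b = leaves[-1L], weight = 1
    )
    net <- canonical_pairs(dplyr::bind_rows(hub_edges, path_edges))
    list(net = net, leaves = leaves, hubs = hubs,
         genes = unique(c(net$gene_a, net$gene_b)))
  })
}

# a labeled scored-pair world over a gold standard. "graded": the positive
# fraction decreases steadily down the score ranking (strong, noise-free
# signal); "perfect": positives strictly outscore negatives; "none": scores
# independent of labels.
make_scored_gold <- function(n_pos, n_neg,
                             separation = c("graded", "perfect", "none"),
                             seed = 1L, n_bins = 10L) {
  separation <- match.arg(separation)
  n <- n_pos + n_neg
  genes <- sprintf("g%04d", seq_len(ceiling(sqrt(4 * n))))
  pairs <- all_pairs(genes)[seq_len(n), ]
  spt <- withr::with_seed(seed, {
    if (separation == "graded") {
      # bin b of n/n_bins ranked pairs holds a linearly decreasing number of
      # positives; scores are the (jittered) reverse rank
      per_bin <- n / n_bins
      pos_per_bin <- round(2 * n_pos / n_bins * (n_bins:1) / (n_bins + 1))
      lab <- unlist(lapply(seq_len(n_bins), function(b) {
        rep(c(TRUE, FALSE), c(pos_per_bin[b], per_bin - pos_per_bin[b]))
      }))
      dplyr::mutate(pairs, score = rev(seq_len(n)) + runif(n, 0, 0.5),
                    is_pos = lab)
    } else if (separation == "perfect") {
      dplyr::mutate(pairs,
                    is_pos = rep(c(TRUE, FALSE), c(n_pos, n_neg)),
                    score = ifelse(is_pos, runif(n, 10, 20), runif(n, 0, 10)))
    } else {
      dplyr::mutate(pairs,
                    is_pos = rep(c(TRUE, FALSE), c(n_pos, n_neg)),
                    score = runif(n, 0, 20))
    }
  })
  gold <- gold_standard(spt[spt$is_pos, c("gene_a", "gene_b")],
                        spt[!spt$is_pos, c("gene_a", "gene_b")])
  list(gold = gold, spt = spt[c("gene_a", "gene_b", "score")])
}
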