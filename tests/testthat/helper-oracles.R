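# Independent brute-force oracles. Each re-implements the quantity it checks
# from its definition, sharing no code with the package internals.

# mutual information by explicit double loop over the joint table (nats);
# equal-width histogramming via findInterval, binary vectors used as-is
mi_oracle <- function(x, y, n_bins = 4L) {
  disc <- function(v) {
    if (length(unique(v)) <= 2L) return(as.integer(factor(v)))
    br <- seq(min(v), max(v), length.out = n_bins + 1L)
    findInterval(v, br, rightmost.closed = TRUE)
  }
  cx <- disc(x); cy <- disc(y)
  n <- length(x)
  mi <- 0
  for (i in unique(cx)) {
    for (j in unique(cy)) {
      pij <- sum(cx == i & cy == j) / n
      if (pij > 0) {
        mi <- mi + pij * log(pij / ((sum(cx == i) / n) * (sum(cy == j) / n)))
      }
    }
  }
  max(0, mi)
}

lls_oracle <- function(np, nn, NP, NN) {
  log(((np + 0.5) / (nn + 0.5)) / (NP / NN))
}

ws_oracle <- function(v, D, T) {
  v <- v[v >= T]
  if (length(v) == 0L) return(NA_real_)
  v <- sort(v, decreasing = TRUE)
  out <- v[1L]
  if (length(v) > 1L) {
    for (i in 2:length(v)) out <- out + v[i] / D^(i - 1L)
  }
  out
}

# leave-one-out AUC by naive full recomputation: for each held-out guide,
# rescore every gene against the reduced guide set by looping over edges
loo_auc_oracle <- function(net, guides) {
  wc <- intersect(c("ws", "lls", "weight", "score"), names(net))[1L]
  genes <- unique(c(net$gene_a, net$gene_b))
  guides <- intersect(guides, genes)
  non_guides <- setdiff(genes, guides)
  score_against <- function(v, gset) {
    sel <- (net$gene_a == v & net$gene_b %in% gset) |
      (net$gene_b == v & net$gene_a %in% gset)
    sum(net[[wc]][sel])
  }
  aucs <- vapply(guides, function(g) {
    gset <- setdiff(guides, g)
    sg <- score_against(g, gset)
    sn <- vapply(non_guides, score_against, numeric(1L), gset = gset)
    mean((sg > sn) + 0.5 * (sg == sn))
  }, numeric(1L))
  mean(aucs)
}

# one-tailed enrichment p via R's exact conditional test on the 2x2 table
fisher_oracle <- function(overlap, n_deg, n_neighbors, n_universe) {
  tab <- matrix(c(
    overlap, n_neighbors - overlap,
    n_deg - overlap, n_universe - n_neighbors - n_deg + overlap
  ), nrow = 2L)
  stats::fisher.test(tab, alternative = "greater")$p.value
}
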