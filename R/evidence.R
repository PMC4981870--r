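#' Mutual information between two profile vectors
#'
#' Measures the similarity of two gene profiles (phylogenetic presence
#' patterns, domain-occurrence vectors) as the mutual information of their
#' joint histogram, in nats:
#' \deqn{MI = \sum_{i,j} p(i,j) \ln \frac{p(i,j)}{p(i)\,p(j)}}
#' Continuous vectors are discretized into `n_bins` equal-width bins over
#' their own range; vectors with at most two distinct values (binary
#' presence/absence profiles) are used as-is. A constant vector carries no
#' information and yields 0.
#'
#' @param x,y Numeric vectors of equal length (>= 2).
#' @param n_bins Number of equal-width bins for continuous vectors
#'   (default 4).
#' @return Non-negative mutual information in nats.
#' @examples
#' mutual_information(c(0, 0, 1, 1), c(0, 0, 1, 1)) # log(2)
#' @export
mutual_information <- function(x, y, n_bins = 4L) {
  stopifnot(length(x) == length(y), length(x) >= 2L, n_bins >= 2L)
  .mi_codes(.discretize(x, n_bins), .discretize(y, n_bins))
}

# equal-width discretization to integer codes 1..n_bins; <=2 distinct values
# are kept as their own codes (binary bypass); constant vectors -> one code
.discretize <- function(x, n_bins) {
  ux <- unique(x)
  if (length(ux) <= 2L) {
    return(match(x, sort(ux)))
  }
  rng <- range(x)
  codes <- floor((x - rng[1L]) / (rng[2L] - rng[1L]) * n_bins) + 1L
  pmin(codes, as.integer(n_bins))
}

# MI in nats from integer code vectors
.mi_codes <- function(cx, cy) {
  kx <- max(cx)
  ky <- max(cy)
  n <- length(cx)
  joint <- tabulate((cx - 1L) * ky + cy, nbins = kx * ky) / n
  px <- tabulate(cx, nbins = kx) / n
  py <- tabulate(cy, nbins = ky) / n
  exp_p <- as.vector(outer(py, px))  # column-major: (cx-1)*ky + cy
  nz <- joint > 0
  max(0, sum(joint[nz] * log(joint[nz] / exp_p[nz])))
}

#' Score gene pairs by profile similarity (mutual information)
#'
#' Computes the pairwise mutual information between the rows of a profile
#' matrix — genes by genomes for phylogenetic profiles, genes by domains for
#' weighted domain-occurrence profiles — and returns one row per unordered
#' gene pair. Pairs with zero MI carry no evidence and are dropped.
#'
#' @param pm Numeric profile matrix with gene row names (>= 2 rows and >= 2
#'   columns).
#' @param n_bins Bins for continuous profiles, see [mutual_information()].
#' @return Tibble `(gene_a, gene_b, score)` sorted by descending score.
#' @export
profile_scores <- function(pm, n_bins = 4L) {
  stopifnot(is.matrix(pm), !is.null(rownames(pm)))
  if (ncol(pm) < 2L) abort("profile matrix needs >= 2 columns (MI is degenerate)")
  if (nrow(pm) < 2L) abort("profile matrix needs >= 2 genes")
  genes <- rownames(pm)
  codes <- t(apply(pm, 1L, .discretize, n_bins = n_bins))
  n <- nrow(pm)
  idx <- combn(n, 2L)
  mi <- vapply(seq_len(ncol(idx)), function(k) {
    .mi_codes(codes[idx[1L, k], ], codes[idx[2L, k], ])
  }, numeric(1L))
  canonical_pairs(tibble(
    gene_a = genes[idx[1L, ]],
    gene_b = genes[idx[2L, ]],
    score = mi
  )) %>%
    filter(.data$score > 0) %>%
    arrange(desc(.data$score), .data$gene_a, .data$gene_b)
}

#' @rdname profile_scores
#' @export
phylo_profile_scores <- profile_scores

#' Build inverse-frequency weighted domain profiles
#'
#' Converts a domain annotation (domain term -> genes carrying it) into a
#' genes-by-domains matrix where presence of domain *d* is encoded as the
#' inverse of its frequency in the proteome, `universe_size / n_d`, and
#' absence as 0. Rare domains are more function-specific than common ones,
#' and this weighting makes sharing a rare domain count for more when the
#' profiles are compared by mutual information.
#'
#' @param domain_ann Tibble `(term, gene)` mapping domain ids to genes.
#' @param universe_size Number of genes in the proteome (>= number of
#'   annotated genes).
#' @return Numeric matrix, genes by domains, with gene row names.
#' @export
domain_profiles <- function(domain_ann, universe_size) {
  domain_ann <- distinct(domain_ann, .data$term, .data$gene)
  genes <- sort(unique(domain_ann$gene))
  doms <- sort(unique(domain_ann$term))
  stopifnot(universe_size >= length(genes), length(doms) >= 1L)
  n_d <- table(domain_ann$term)[doms]
  m <- matrix(0, nrow = length(genes), ncol = length(doms),
              dimnames = list(genes, doms))
  m[cbind(match(domain_ann$gene, genes), match(domain_ann$term, doms))] <-
    universe_size / as.numeric(n_d)[match(domain_ann$term, doms)]
  m
}

#' Gene-neighborhood evidence: physical-distance variant
#'
#' Genes that stay chromosomal neighbors across many genomes tend to be
#' co-functional (operon-like organization). For every gene pair present
#' together in at least `min_genomes` genomes, the score is the mean over
#' those genomes of `1 / (1 + delta)` where `delta` is the absolute
#' difference of their position indices on a shared contig; co-occurrence on
#' different contigs contributes 0 for that genome. Higher scores mean
#' consistently closer genes.
#'
#' @param orders Gene-order tibble `(genome, gene, contig, index)`, see
#'   [read_gene_orders()].
#' @param min_genomes Minimum number of genomes in which both genes must
#'   occur (default 1).
#' @return Tibble `(gene_a, gene_b, score, n_genomes)`, descending score.
#' @export
neighborhood_distance_scores <- function(orders, min_genomes = 1L) {
  if (length(unique(orders$genome)) < 2L) {
    abort("gene-order table must cover >= 2 genomes")
  }
  contrib <- purrr::map_dfr(split(orders, orders$genome), .pair_proximity)
  contrib %>%
    mutate(w = ifelse(.data$same_contig, 1 / (1 + .data$delta), 0)) %>%
    group_by(.data$gene_a, .data$gene_b) %>%
    summarise(score = mean(.data$w), n_genomes = n(), .groups = "drop") %>%
    filter(.data$n_genomes >= min_genomes) %>%
    arrange(desc(.data$score), .data$gene_a, .data$gene_b)
}

# per-genome pair table: same-contig flag and index distance for all pairs
.pair_proximity <- function(gdf) {
  gdf <- distinct(gdf, .data$gene, .keep_all = TRUE)
  n <- nrow(gdf)
  if (n < 2L) {
    return(tibble(gene_a = character(), gene_b = character(),
                  same_contig = logical(), delta = numeric()))
  }
  idx <- combn(n, 2L)
  i <- idx[1L, ]; j <- idx[2L, ]
  canonical_pairs(tibble(
    gene_a = gdf$gene[i],
    gene_b = gdf$gene[j],
    same_contig = gdf$contig[i] == gdf$contig[j],
    delta = abs(gdf$index[i] - gdf$index[j])
  ))
}

#' Gene-neighborhood evidence: probability variant
#'
#' Scores each gene pair by how surprising its observed chromosomal
#' proximity is under random gene placement. For a pair occurring together
#' in `m` genomes and lying within `window` positions on a shared contig in
#' `k` of them, the one-tailed probability of at least `k` proximities is
#' the binomial tail \eqn{P = \sum_{j \ge k} \binom{m}{j} q^j (1-q)^{m-j}},
#' where `q` is the per-genome chance of random proximity. On a single
#' contig of `L` genes `q = min(1, 2 window / (L - 1))`; across contigs the
#' placement probability is summed over contigs, and `q` is averaged over
#' the `m` genomes when contig structure differs. The score is `-ln P`
#' (0 when `k = 0`).
#'
#' @inheritParams neighborhood_distance_scores
#' @param window Maximum index separation counted as "neighboring"
#'   (default 1, i.e. adjacency).
#' @return Tibble `(gene_a, gene_b, score, k, m)`, descending score.
#' @export
neighborhood_probability_scores <- function(orders, window = 1L,
                                            min_genomes = 1L) {
  stopifnot(window >= 1L)
  if (length(unique(orders$genome)) < 2L) {
    abort("gene-order table must cover >= 2 genomes")
  }
  by_genome <- split(orders, orders$genome)
  qs <- vapply(by_genome, .genome_q, numeric(1L), window = window)
  contrib <- purrr::map_dfr(names(by_genome), function(gn) {
    .pair_proximity(by_genome[[gn]]) %>%
      mutate(near = .data$same_contig & .data$delta <= window, q = qs[[gn]])
  })
  contrib %>%
    group_by(.data$gene_a, .data$gene_b) %>%
    summarise(k = sum(.data$near), m = n(), q = mean(.data$q),
              .groups = "drop") %>%
    filter(.data$m >= min_genomes) %>%
    mutate(
      p = ifelse(.data$k == 0L, 1,
                 pbinom(.data$k - 1L, .data$m, .data$q, lower.tail = FALSE)),
      score = -log(.data$p)
    ) %>%
    select("gene_a", "gene_b", "score", "k", "m") %>%
    arrange(desc(.data$score), .data$gene_a, .data$gene_b)
}

# chance that two uniformly placed genes are within `window` positions,
# given the genome's contig length distribution
.genome_q <- function(gdf, window) {
  len <- as.numeric(table(gdf$contig))
  n <- sum(len)
  if (n < 2L) return(0)
  same_contig <- len * (len - 1) / (n * (n - 1))
  within <- ifelse(len > 1, pmin(1, 2 * window / (len - 1)), 0)
  min(1, sum(same_contig * within))
}

#' Co-expression evidence: significance-filtered Pearson correlation
#'
#' Scores gene pairs by the Pearson correlation of their expression profiles
#' and keeps only correlations that are statistically significant at the
#' `conf` confidence level under the exact t test
#' (`t = r sqrt((n-2)/(1-r^2))` on `n - 2` degrees of freedom, two-sided).
#' Correlations estimated from few samples are promiscuous, so a dataset
#' with fewer than `min_samples` samples is rejected outright rather than
#' scored. Genes with constant expression (undefined correlation) are
#' skipped with a message.
#'
#' @param em Numeric genes-by-samples matrix with gene row names, or a data
#'   frame whose first column holds gene ids.
#' @param min_samples Minimum sample count for the dataset to be usable
#'   (default 12).
#' @param conf Confidence level of the significance filter (default 0.99).
#' @return Tibble `(gene_a, gene_b, score, p_value)`, `score` the PCC,
#'   sorted by descending score.
#' @export
coexpression_scores <- function(em, min_samples = 12L, conf = 0.99) {
  if (is.data.frame(em)) {
    genes <- as.character(em[[1L]])
    em <- as.matrix(em[, -1L, drop = FALSE])
    rownames(em) <- genes
  }
  stopifnot(is.matrix(em), !is.null(rownames(em)))
  n <- ncol(em)
  if (n < min_samples) {
    abort(sprintf("dataset rejected: %d samples < required %d", n, min_samples))
  }
  vars <- apply(em, 1L, stats::var)
  if (any(vars == 0)) {
    inform(sprintf("skipping %d constant-expression gene(s)", sum(vars == 0)))
    em <- em[vars > 0, , drop = FALSE]
  }
  if (nrow(em) < 2L) abort("need >= 2 genes with non-constant expression")
  r <- cor(t(em))
  genes <- rownames(em)
  idx <- which(upper.tri(r), arr.ind = TRUE)
  rv <- pmin(pmax(r[idx], -1), 1)
  tt <- rv * sqrt((n - 2) / pmax(1 - rv^2, .Machine$double.eps))
  tt[abs(rv) == 1] <- Inf * sign(rv[abs(rv) == 1])
  pv <- 2 * pt(-abs(tt), df = n - 2)
  canonical_pairs(tibble(
    gene_a = genes[idx[, 1L]],
    gene_b = genes[idx[, 2L]],
    score = rv,
    p_value = pv
  )) %>%
    filter(.data$p_value < 1 - conf) %>%
    arrange(desc(.data$score), .data$gene_a, .data$gene_b)
}
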