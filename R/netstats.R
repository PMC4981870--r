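# igraph view of an edge table (undirected, simple)
.as_igraph <- function(net) {
  .check_edges(net)
  net <- canonical_pairs(net) %>% distinct(.data$gene_a, .data$gene_b)
  igraph::graph_from_data_frame(net, directed = FALSE)
}

#' Power-law fit of the degree distribution
#'
#' Functional gene networks are typically scale-free: few highly connected
#' hubs, many peripheral genes. This descriptive diagnostic fits a line to
#' `log10(count)` versus `log10(degree)` over the observed degrees and
#' reports the implied power-law exponent (the negated slope) and the fit's
#' R-squared. It is a transparency check, not a rigorous scale-free
#' hypothesis test.
#'
#' @param net Edge table.
#' @return Tibble `(exponent, r_squared, n_degrees)`.
#' @export
degree_powerlaw <- function(net) {
  g <- .as_igraph(net)
  deg <- igraph::degree(g)
  tab <- table(deg[deg > 0])
  if (length(tab) < 10L) {
    abort(sprintf("need >= 10 distinct degrees for a power-law fit (have %d)",
                  length(tab)))
  }
  x <- log10(as.numeric(names(tab)))
  y <- log10(as.numeric(tab))
  ft <- lm(y ~ x)
  tibble(
    exponent = -unname(coef(ft)[2L]),
    r_squared = summary(ft)$r.squared,
    n_degrees = length(tab)
  )
}

#' Clustering coefficient against a degree-preserving null
#'
#' Functional modules make real networks far more clustered than random
#' graphs of identical degree sequence. The observed global clustering
#' (mean local clustering coefficient; nodes of degree < 2 contribute 0) is
#' compared with `n_null` degree-preserving rewired replicates (double-edge
#' swaps, 10 |E| swaps per replicate), and the fold enrichment
#' `observed / null mean` is reported (`Inf` when the null mean is 0).
#'
#' @param net Edge table.
#' @param n_null Number of rewired replicates (default 20).
#' @param seed Integer seed (rewiring is stochastic).
#' @return Tibble `(clustering, null_mean, null_sd, fold)`.
#' @export
clustering_vs_null <- function(net, n_null = 20L, seed = 1L) {
  g <- .as_igraph(net)
  obs <- .mean_local_clustering(g)
  deg0 <- igraph::degree(g)
  nulls <- withr::with_seed(seed, {
    vapply(seq_len(n_null), function(i) {
      gr <- igraph::rewire(
        g, igraph::keeping_degseq(niter = 10L * igraph::ecount(g)))
      stopifnot(identical(igraph::degree(gr), deg0))  # rewiring invariant
      .mean_local_clustering(gr)
    }, numeric(1L))
  })
  null_mean <- mean(nulls)
  tibble(
    clustering = obs,
    null_mean = null_mean,
    null_sd = sd(nulls),
    fold = if (null_mean == 0) Inf else obs / null_mean
  )
}

.mean_local_clustering <- function(g) {
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  cc[is.nan(cc)] <- 0  # degree-1 nodes: no possible triangle
  mean(cc)
}

#' Shortest-path-length profile
#'
#' Histogram of breadth-first shortest path lengths over `n_pairs` gene
#' pairs sampled uniformly (with replacement) from the connected pairs of
#' the network. Deterministic for a fixed seed.
#'
#' @param net Edge table.
#' @param n_pairs Number of sampled pairs (default 1000).
#' @param seed Integer seed.
#' @return Tibble `(length, count)`.
#' @export
path_length_profile <- function(net, n_pairs = 1000L, seed = 1L) {
  g <- .as_igraph(net)
  comp <- igraph::components(g)
  sizes <- comp$csize
  eligible <- which(sizes >= 2L)
  if (length(eligible) == 0L) abort("network has no connected pair")
  w_comp <- sizes[eligible] * (sizes[eligible] - 1) / 2
  pairs <- withr::with_seed(seed, {
    ci <- sample(eligible, n_pairs, replace = TRUE, prob = w_comp)
    t(vapply(ci, function(cc) {
      sample(which(comp$membership == cc), 2L, replace = FALSE)
    }, integer(2L)))
  })
  lens <- vapply(seq_len(nrow(pairs)), function(i) {
    as.numeric(igraph::distances(g, v = pairs[i, 1L], to = pairs[i, 2L]))
  }, numeric(1L))
  tibble(length = as.integer(names(table(lens))),
         count = as.integer(table(lens)))
}

#' Full topological diagnostic report
#'
#' Bundles [degree_powerlaw()], [clustering_vs_null()] and
#' [path_length_profile()] into one object.
#'
#' @inheritParams clustering_vs_null
#' @inheritParams path_length_profile
#' @return A `topology_report` list with components `powerlaw`,
#'   `clustering`, `path_lengths`, `degree_hist`.
#' @export
topology_report <- function(net, n_null = 20L, n_pairs = 1000L, seed = 1L) {
  g <- .as_igraph(net)
  deg <- igraph::degree(g)
  pl <- tryCatch(degree_powerlaw(net), error = function(e) NULL)
  structure(
    list(
      powerlaw = pl,
      clustering = clustering_vs_null(net, n_null = n_null, seed = seed),
      path_lengths = path_length_profile(net, n_pairs = n_pairs, seed = seed),
      degree_hist = tibble(degree = as.integer(names(table(deg))),
                           count = as.integer(table(deg)))
    ),
    class = "topology_report"
  )
}

#' @export
print.topology_report <- function(x, ...) {
  cat("<topology_report>\n")
  if (!is.null(x$powerlaw)) {
    cat(sprintf("  power law: exponent %.2f (R^2 = %.2f)\n",
                x$powerlaw$exponent, x$powerlaw$r_squared))
  }
  cat(sprintf("  clustering %.3f vs null %.3f (fold %.1f)\n",
              x$clustering$clustering, x$clustering$null_mean,
              x$clustering$fold))
  invisible(x)
}

#' @method glance topology_report
#' @export
glance.topology_report <- function(x, ...) {
  tibble(
    exponent = if (is.null(x$powerlaw)) NA_real_ else x$powerlaw$exponent,
    powerlaw_r2 = if (is.null(x$powerlaw)) NA_real_ else x$powerlaw$r_squared,
    clustering = x$clustering$clustering,
    null_clustering = x$clustering$null_mean,
    clustering_fold = x$clustering$fold,
    median_path_length = {
      pl <- x$path_lengths
      median(rep(pl$length, pl$count))
    }
  )
}
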