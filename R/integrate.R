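#' Weighted sum of supporting log-likelihood scores
#'
#' Evidence datasets are not independent, so summing their LLS values (the
#' naive-Bayes rule) over-counts correlated support. The weighted sum
#' down-weights every supporter after the strongest one geometrically:
#' \deqn{WS = L_0 + \sum_{i \ge 1} \frac{L_i}{D^i}, \quad L_0 \ge L_1 \ge \dots \ge T}
#' where \eqn{L_0} is the largest supporting LLS, `D >= 1` is the weight
#' factor (`D = 1` recovers the plain sum, `D -> Inf` keeps only the best
#' dataset), and `T` is the minimum LLS a value must reach to count at all.
#' If no value clears `T` there is no edge, encoded as `NA`.
#'
#' @param lls_values Numeric vector of supporting LLS values.
#' @param D Weight factor, >= 1.
#' @param T Minimum LLS threshold.
#' @return The WS value, or `NA_real_` when no supporter reaches `T`.
#' @examples
#' weighted_sum(c(3, 2), D = 2, T = 1) # 3 + 2/2 = 4
#' @export
weighted_sum <- function(lls_values, D = 2, T = 0) {
  stopifnot(D >= 1, is.finite(T))
  v <- sort(lls_values[lls_values >= T], decreasing = TRUE)
  if (length(v) == 0L) return(NA_real_)
  sum(v / D^(seq_along(v) - 1L))
}

#' Integrate component networks into one weighted network
#'
#' Every unordered pair present in at least one component becomes an edge of
#' the integrated network, weighted by the [weighted_sum()] of its
#' supporting LLS values (those at or above `T`; pairs whose supporters all
#' fall below `T` are absent, not zero-weighted). Provenance — which dataset
#' contributed which LLS — is kept in a nested `support` list-column.
#'
#' @param components Named list of component-network tibbles
#'   `(gene_a, gene_b, lls)`; names become dataset ids.
#' @param D,T Weighted-sum parameters, see [weighted_sum()].
#' @return Integrated network tibble
#'   `(gene_a, gene_b, ws, n_support, support)`, descending `ws`; `support`
#'   nests tibbles `(dataset, lls)`.
#' @export
integrate_networks <- function(components, D = 2, T = 0) {
  stopifnot(length(components) >= 1L, D >= 1, is.finite(T))
  if (is.data.frame(components)) components <- list(components)
  if (is.null(names(components)) || any(!nzchar(names(components)))) {
    names(components) <- paste0("dataset_", seq_along(components))
  }
  long <- purrr::imap_dfr(components, function(cn, id) {
    .check_edges(cn)
    canonical_pairs(cn) %>%
      transmute_support(id)
  })
  long <- filter(long, .data$lls >= T)
  if (nrow(long) == 0L) {
    warn("no edge reaches the LLS threshold T; integrated network is empty")
    return(tibble(gene_a = character(), gene_b = character(), ws = numeric(),
                  n_support = integer(), support = list()))
  }
  long %>%
    arrange(.data$gene_a, .data$gene_b, desc(.data$lls), .data$dataset) %>%
    group_by(.data$gene_a, .data$gene_b) %>%
    summarise(
      ws = sum(.data$lls / D^(seq_len(n()) - 1L)),
      n_support = n(),
      support = list(tibble(dataset = dataset, lls = lls)),
      .groups = "drop"
    ) %>%
    arrange(desc(.data$ws), .data$gene_a, .data$gene_b)
}

transmute_support <- function(cn, id) {
  wc <- .weight_col(cn)
  tibble(gene_a = cn$gene_a, gene_b = cn$gene_b,
         lls = cn[[wc]], dataset = id)
}

#' Choose the weighted-sum parameters on a grid
#'
#' For every (D, T) on the grid the components are integrated, the edges are
#' ranked by WS, and overall performance is measured as the area under the
#' curve of cumulative benchmark LLS (computed with [lls()] on the
#' gold-overlapping edges) versus the cumulative number of pairs, evaluated
#' after each successive bin of `bin` overlapping pairs. Larger area rewards
#' both accuracy (high LLS among top edges) and coverage (more pairs). The
#' curve is integrated by the trapezoid rule from zero pairs, holding the
#' first bin's LLS constant down to zero. Grid ties are broken toward
#' smaller D, then larger T.
#'
#' @param components Named list of component networks, as in
#'   [integrate_networks()].
#' @param gold A `gold_standard`.
#' @param D_grid,T_grid Candidate values (defaults `c(1, 1.5, 2, 3, 4)` and
#'   `c(0, 0.5, 1, 1.5, 2)`).
#' @param bin Overlapping pairs per cumulative step (default 1000).
#' @return A `ws_opt` list: chosen `D`, `T`, `area`, and the full `grid`
#'   tibble `(D, T, area)`.
#' @export
optimize_ws_params <- function(components, gold,
                               D_grid = c(1, 1.5, 2, 3, 4),
                               T_grid = c(0, 0.5, 1, 1.5, 2),
                               bin = 1000L) {
  stopifnot(length(D_grid) >= 1L, length(T_grid) >= 1L)
  if (nrow(gold$positives) == 0L) abort("gold standard has no positives")
  grid <- tidyr::expand_grid(D = D_grid, T = T_grid)
  grid$area <- purrr::map2_dbl(grid$D, grid$T, function(D, T) {
    net <- suppressWarnings(integrate_networks(components, D = D, T = T))
    if (nrow(net) == 0L) return(-Inf)
    .lls_pairs_area(net, gold, bin)
  })
  if (all(!is.finite(grid$area))) {
    abort("no (D, T) grid point yields gold-overlapping edges")
  }
  best <- grid %>%
    arrange(desc(.data$area), .data$D, desc(.data$T)) %>%
    slice(1L)
  structure(
    list(D = best$D, T = best$T, area = best$area, grid = grid),
    class = "ws_opt"
  )
}

# area under the cumulative-LLS vs cumulative-pairs curve
.lls_pairs_area <- function(net, gold, bin) {
  lab <- .gold_label(net, gold) %>% filter(!is.na(.data$label))
  if (nrow(lab) == 0L) return(-Inf)
  lab <- arrange(lab, desc(.data$ws), .data$gene_a, .data$gene_b)
  tp <- cumsum(lab$label == "positive")
  fp <- cumsum(lab$label == "negative")
  steps <- unique(c(seq(bin, nrow(lab), by = bin), nrow(lab)))
  y <- lls(pmax(tp[steps], 0), fp[steps],
           max(nrow(gold$positives), 1L), max(nrow(gold$negatives), 1L))
  x <- c(0, steps)
  y <- c(y[1L], y)
  sum(diff(x) * (head(y, -1L) + y[-1L]) / 2)
}

#' @export
print.ws_opt <- function(x, ...) {
  cat(sprintf("<ws_opt> D = %g, T = %g (area = %.4g over %d grid points)\n",
              x$D, x$T, x$area, nrow(x$grid)))
  invisible(x)
}

#' @method tidy ws_opt
#' @export
tidy.ws_opt <- function(x, ...) x$grid

#' @method glance ws_opt
#' @export
glance.ws_opt <- function(x, ...) tibble(D = x$D, T = x$T, area = x$area)
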