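#' Plot a precision-recall curve
#'
#' @param object A `pr_curve` from [precision_recall()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pr_curve
#' @export
autoplot.pr_curve <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$recall, y = .data$precision)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Recall", y = "Precision",
                  title = "Precision-recall against the benchmark") +
    ggplot2::theme_minimal()
}

#' Plot an LLS calibration model
#'
#' Per-bin (mean score, LLS) points with the fitted monotone mapping.
#'
#' @param object An `lls_model`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot lls_model
#' @export
autoplot.lls_model <- function(object, ...) {
  bins <- object$bins
  grid <- tibble(
    mean_score = seq(min(bins$mean_score), max(bins$mean_score),
                     length.out = 200L)
  )
  grid$lls <- object$mapping(grid$mean_score)
  ggplot2::ggplot(bins, ggplot2::aes(x = .data$mean_score, y = .data$lls)) +
    ggplot2::geom_line(data = grid, color = "grey50") +
    ggplot2::geom_point(color = "steelblue") +
    ggplot2::labs(x = "Mean intrinsic score per bin",
                  y = "Log-likelihood score (nats)",
                  title = sprintf("LLS calibration: %s", object$dataset_id)) +
    ggplot2::theme_minimal()
}

#' Plot a guilt-by-association benchmark
#'
#' Distribution of per-term leave-one-out AUCs with the 0.5 random
#' expectation marked.
#'
#' @param object A `gba_benchmark`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot gba_benchmark
#' @export
autoplot.gba_benchmark <- function(object, ...) {
  ggplot2::ggplot(object$terms, ggplot2::aes(x = "", y = .data$auc)) +
    ggplot2::geom_boxplot(fill = "steelblue", alpha = 0.4, width = 0.4) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "Leave-one-out AUC",
                  title = "Per-term guilt-by-association AUC") +
    ggplot2::theme_minimal()
}

#' Log-log degree distribution plot
#'
#' @param net Edge table.
#' @return A ggplot of degree versus count on log10 axes.
#' @export
plot_degree_distribution <- function(net) {
  g <- .as_igraph(net)
  deg <- igraph::degree(g)
  df <- as_tibble(table(degree = deg[deg > 0]), .name_repair = "minimal")
  names(df) <- c("degree", "count")
  df$degree <- as.numeric(df$degree)
  df$count <- as.numeric(df$count)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$degree, y = .data$count)) +
    ggplot2::geom_point(color = "steelblue") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Degree", y = "Gene count",
                  title = "Degree distribution (log-log)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
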