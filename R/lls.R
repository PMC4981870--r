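#' Log-likelihood score of a gold-standard contingency
#'
#' The Bayesian log-likelihood score of observing `n_pos_d` positive and
#' `n_neg_d` negative gold-standard pairs in a dataset (or bin), against a
#' prior of `n_pos_all` positives and `n_neg_all` negatives over the whole
#' gold standard:
#' \deqn{LLS = \ln \frac{P(I|D) / P(\neg I|D)}{P(I) / P(\neg I)}}
#' A Haldane pseudocount of 0.5 is added to the two dataset cells so that a
#' bin with zero positives (or zero negatives) still maps to a finite score;
#' the prior odds are left untouched. Positive LLS means enrichment of true
#' co-functional pairs above the prior.
#'
#' @param n_pos_d,n_neg_d Positive/negative gold pairs observed in the
#'   dataset cell (vectorized).
#' @param n_pos_all,n_neg_all Gold-standard totals (both > 0).
#' @return Numeric LLS in nats.
#' @examples
#' lls(20, 20, 100, 900) # log(9)
#' @export
lls <- function(n_pos_d, n_neg_d, n_pos_all, n_neg_all) {
  stopifnot(n_pos_all > 0, n_neg_all > 0,
            n_pos_d >= 0, n_neg_d >= 0)
  if (any(n_pos_d == 0 & n_neg_d == 0)) {
    abort("empty bin: no gold-standard pairs in the dataset cell")
  }
  log((n_pos_d + 0.5) / (n_neg_d + 0.5)) - log(n_pos_all / n_neg_all)
}

#' Calibrate an evidence score into log-likelihood scores
#'
#' Implements the equal-count binning scheme: the gold-overlapping pairs of a
#' scored evidence table are ranked by score (descending, ties broken by
#' canonical pair order), split into consecutive bins of `bin_size` pairs,
#' and each bin's LLS is computed with [lls()] against the full gold-standard
#' prior. A monotone mapping from raw score to LLS is then fit through the
#' per-bin (mean score, LLS) points — isotonic regression with linear
#' interpolation by default, a linear fit when fewer than 5 bins are
#' available — so that every pair in the dataset, gold-annotated or not, can
#' be assigned a continuous LLS.
#'
#' @param spt Scored pair table `(gene_a, gene_b, score)`.
#' @param gold A `gold_standard` object.
#' @param bin_size Gold pairs per bin (default 1000).
#' @param dataset_id Identifier stored in the model.
#' @param method `"auto"` (isotonic when >= 5 bins), `"isotonic"` or
#'   `"linear"`.
#' @return An `lls_model`: list with `bins` (tibble `bin, mean_score, lls,
#'   lls_insample, n_pos, n_neg`), `mapping` (function score -> LLS),
#'   `prior_odds`, `dataset_id`, `method`, `n_pairs`.
#' @export
fit_lls_model <- function(spt, gold, bin_size = 1000L, dataset_id = "dataset",
                          method = c("auto", "isotonic", "linear")) {
  method <- match.arg(method)
  lab <- .ranked_gold_overlap(spt, gold, bin_size)
  bins <- .bin_lls(lab, bin_size, gold)
  bins$lls_insample <- bins$lls
  .finish_lls_model(bins, gold, dataset_id, method, nrow(lab))
}

# rank gold-overlapping pairs by score desc, canonical pair order on ties
.ranked_gold_overlap <- function(spt, gold, bin_size) {
  lab <- .gold_label(spt, gold) %>% filter(!is.na(.data$label))
  if (nrow(lab) < 2L * bin_size) {
    abort(sprintf(
      "insufficient gold overlap: %d labeled pairs < 2 * bin_size = %d",
      nrow(lab), 2L * bin_size))
  }
  arrange(lab, desc(.data$score), .data$gene_a, .data$gene_b) %>%
    mutate(bin = (row_number() - 1L) %/% bin_size + 1L)
}

.bin_lls <- function(lab, bin_size, gold) {
  lab %>%
    group_by(.data$bin) %>%
    summarise(
      mean_score = mean(.data$score),
      n_pos = sum(.data$label == "positive"),
      n_neg = sum(.data$label == "negative"),
      .groups = "drop"
    ) %>%
    mutate(lls = lls(.data$n_pos, .data$n_neg,
                     nrow(gold$positives), nrow(gold$negatives)))
}

.finish_lls_model <- function(bins, gold, dataset_id, method, n_pairs) {
  if (method == "auto") {
    method <- if (nrow(bins) >= 5L) "isotonic" else "linear"
  }
  mapping <- .fit_mapping(bins$mean_score, bins$lls, method)
  structure(
    list(
      dataset_id = dataset_id,
      bins = bins,
      mapping = mapping,
      prior_odds = nrow(gold$positives) / nrow(gold$negatives),
      method = method,
      n_pairs = n_pairs
    ),
    class = "lls_model"
  )
}

# monotone score -> LLS mapping through per-bin points
.fit_mapping <- function(mean_score, lls_vals, method) {
  if (method == "linear" || length(unique(mean_score)) < 2L) {
    if (length(unique(mean_score)) < 2L) {
      f <- function(s) rep(mean(lls_vals), length(s))
      return(f)
    }
    ft <- lm(y ~ x, data = data.frame(x = mean_score, y = lls_vals))
    a <- coef(ft)[[1L]]; b <- coef(ft)[[2L]]
    return(function(s) a + b * s)
  }
  ord <- order(mean_score)
  iso <- isoreg(mean_score[ord], lls_vals[ord])
  # collapse duplicate x for interpolation; constant extrapolation at ends
  fit <- tibble(x = mean_score[ord], y = iso$yf) %>%
    group_by(.data$x) %>%
    summarise(y = mean(.data$y), .groups = "drop")
  if (nrow(fit) == 1L) {
    yy <- fit$y
    return(function(s) rep(yy, length(s)))
  }
  approxfun(fit$x, fit$y, rule = 2L)
}

#' @export
print.lls_model <- function(x, ...) {
  cat(sprintf("<lls_model '%s'> %d bins over %d gold pairs, %s mapping\n",
              x$dataset_id, nrow(x$bins), x$n_pairs, x$method))
  cat(sprintf("  prior odds P(I)/P(~I) = %.3g; bin LLS range [%.3f, %.3f]\n",
              x$prior_odds, min(x$bins$lls), max(x$bins$lls)))
  invisible(x)
}

#' @method tidy lls_model
#' @export
tidy.lls_model <- function(x, ...) x$bins

#' @method glance lls_model
#' @export
glance.lls_model <- function(x, ...) {
  tibble(
    dataset_id = x$dataset_id,
    n_bins = nrow(x$bins),
    n_pairs = x$n_pairs,
    prior_odds = x$prior_odds,
    method = x$method,
    max_lls = max(x$bins$lls)
  )
}

#' Calibrate with 0.632 bootstrap bias correction
#'
#' Per-bin LLS estimates computed on the same pairs used to define the bins
#' are optimistic. The 0.632 bootstrap combines the in-sample estimate with
#' out-of-bag estimates from `B` bootstrap resamples of the labeled pairs:
#' `lls_bin = 0.368 * lls_insample + 0.632 * mean(lls_oob)`, where each
#' resample's out-of-bag pairs are assigned to the in-sample bins and a bin
#' with no out-of-bag pairs in a resample is skipped for that resample.
#' Deterministic for a fixed `seed`.
#'
#' @inheritParams fit_lls_model
#' @param B Number of bootstrap resamples (>= 10, default 100).
#' @param seed Integer seed.
#' @return An `lls_model` with bootstrap-corrected bin LLS (in-sample values
#'   kept in `bins$lls_insample`), plus fields `B` and `seed`.
#' @export
bootstrap_lls_model <- function(spt, gold, bin_size = 1000L, B = 100L,
                                seed = 1L, dataset_id = "dataset",
                                method = c("auto", "isotonic", "linear")) {
  method <- match.arg(method)
  stopifnot(B >= 10L)
  lab <- .ranked_gold_overlap(spt, gold, bin_size)
  bins <- .bin_lls(lab, bin_size, gold)
  n <- nrow(lab)
  n_pos_all <- nrow(gold$positives)
  n_neg_all <- nrow(gold$negatives)
  is_pos <- lab$label == "positive"
  bin_of <- lab$bin
  k <- nrow(bins)
  oob_sum <- numeric(k)
  oob_n <- integer(k)
  withr::with_seed(seed, {
    for (b in seq_len(B)) {
      drawn <- sample.int(n, n, replace = TRUE)
      oob <- !(seq_len(n) %in% drawn)
      if (!any(oob)) next
      np <- tabulate(bin_of[oob & is_pos], nbins = k)
      nn <- tabulate(bin_of[oob & !is_pos], nbins = k)
      ok <- (np + nn) > 0L
      oob_sum[ok] <- oob_sum[ok] +
        lls(np[ok], nn[ok], n_pos_all, n_neg_all)
      oob_n[ok] <- oob_n[ok] + 1L
    }
  })
  skipped <- sum(oob_n < B)
  if (skipped > 0L) {
    inform(sprintf("%d bin(s) lacked out-of-bag pairs in some resamples", skipped))
  }
  bins$lls_insample <- bins$lls
  have <- oob_n > 0L
  bins$lls[have] <- 0.368 * bins$lls_insample[have] +
    0.632 * (oob_sum[have] / oob_n[have])
  model <- .finish_lls_model(bins, gold, dataset_id, method, n)
  model$B <- B
  model$seed <- seed
  model
}

#' Apply a fitted LLS model to a scored pair table
#'
#' Maps every pair's raw score through the model's monotone mapping and
#' keeps the edges whose LLS clears `min_lls` (and is positive — a
#' component network carries only positive-evidence links).
#'
#' @param model An `lls_model`.
#' @param spt Scored pair table `(gene_a, gene_b, score)` from the same
#'   evidence dataset.
#' @param min_lls Minimum LLS for an edge to be retained (default 0).
#' @return Component network tibble `(gene_a, gene_b, lls)`, descending LLS.
#' @export
apply_lls_model <- function(model, spt, min_lls = 0) {
  stopifnot(inherits(model, "lls_model"))
  spt <- canonical_pairs(spt)
  out <- tibble(
    gene_a = spt$gene_a,
    gene_b = spt$gene_b,
    lls = model$mapping(spt$score)
  )
  out %>%
    filter(is.finite(.data$lls), .data$lls > 0, .data$lls >= min_lls) %>%
    arrange(desc(.data$lls), .data$gene_a, .data$gene_b)
}

#' Precision-recall curve against a gold-standard benchmark
#'
#' Ranks the network's edges by weight, restricts to the
#' benchmark-overlapping pairs, and reports cumulative precision
#' (TP / (TP + FP)) and recall (TP / total benchmark positives) after each
#' successive bin of `bin` overlapping pairs (plus a final point for the
#' remainder).
#'
#' @param net Edge table with a weight column.
#' @param gold A `gold_standard` benchmark.
#' @param bin Pairs per cumulative step (default 1000).
#' @return A `pr_curve`: tibble `(cum_pairs, precision, recall)` with
#'   attributes `n_overlap` and `n_positives`.
#' @export
precision_recall <- function(net, gold, bin = 1000L) {
  wc <- .weight_col(net)
  lab <- .gold_label(net, gold) %>%
    filter(!is.na(.data$label)) %>%
    arrange(desc(.data[[wc]]), .data$gene_a, .data$gene_b)
  if (nrow(lab) == 0L) abort("network has no overlap with the benchmark")
  tp <- cumsum(lab$label == "positive")
  fp <- cumsum(lab$label == "negative")
  steps <- unique(c(seq(bin, nrow(lab), by = bin), nrow(lab)))
  steps <- steps[steps >= 1L]
  out <- tibble(
    cum_pairs = as.integer(steps),
    precision = tp[steps] / (tp[steps] + fp[steps]),
    recall = tp[steps] / nrow(gold$positives)
  )
  structure(out, class = c("pr_curve", class(out)),
            n_overlap = nrow(lab), n_positives = nrow(gold$positives))
}

#' @method tidy pr_curve
#' @export
tidy.pr_curve <- function(x, ...) as_tibble(x)
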