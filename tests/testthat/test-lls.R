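test_that("lls() computes the Bayesian log odds ratio with pseudocount", {
  expect_equal(lls(20, 20, 100, 900), log(9))
  # dataset frequencies at the prior give LLS 0 (up to pseudocount)
  expect_equal(lls(100, 900, 1000, 9000), log((100.5 / 900.5) * 9),
               tolerance = 1e-12)
  # zero positives stay finite through the Haldane pseudocount
  expect_true(is.finite(lls(0, 40, 100, 900)))
  expect_lt(lls(0, 40, 100, 900), 0)
  expect_error(lls(0, 0, 10, 10), "empty bin")
  # pseudocount perturbation is bounded when all cells are >= 5
  for (seed in 1:50) {
    withr::with_seed(seed, {
      np <- sample(5:500, 1); nn <- sample(5:500, 1)
      exact <- log((np / nn) / (100 / 900))
      expect_lt(abs(lls(np, nn, 100, 900) - exact),
                log((min(np, nn) + 0.5) / min(np, nn)) * 2 + 1e-12)
    })
  }
})

test_that("calibration bins separate informative scores and flatten noise", {
  sep <- make_scored_gold(500, 4500, "graded", seed = 2L)
  m <- fit_lls_model(sep$spt, sep$gold, bin_size = 500L)
  # graded positive purity gives strictly decreasing bin LLS down the rank
  expect_true(all(diff(m$bins$lls) < 0))
  expect_gt(m$bins$lls[1], 0)

  # perfect separation: the positive block outscores every negative bin
  per <- make_scored_gold(500, 4500, "perfect", seed = 2L)
  mp <- fit_lls_model(per$spt, per$gold, bin_size = 500L)
  expect_true(all(mp$bins$lls[1] > mp$bins$lls[-1]))
  expect_true(all(diff(mp$bins$lls) <= 0))

  noise <- make_scored_gold(500, 4500, "none", seed = 3L)
  m0 <- fit_lls_model(noise$spt, noise$gold, bin_size = 500L)
  expect_true(all(abs(m0$bins$lls) < 0.5))

  expect_error(fit_lls_model(sep$spt[1:10, ], sep$gold, bin_size = 500L),
               "insufficient gold overlap")
})

test_that("bin means and counts match a brute-force binning oracle", {
  fx <- make_scored_gold(500, 4500, "none", seed = 4L)
  m <- fit_lls_model(fx$spt, fx$gold, bin_size = 1000L)
  # oracle: independent sort and split
  lab <- fx$spt
  key <- paste(lab$gene_a, lab$gene_b)
  pos_key <- paste(fx$gold$positives$gene_a, fx$gold$positives$gene_b)
  lab$is_pos <- key %in% pos_key
  ord <- order(-lab$score, lab$gene_a, lab$gene_b)
  lab <- lab[ord, ]
  for (b in seq_len(nrow(m$bins))) {
    rows <- lab[((b - 1) * 1000 + 1):min(b * 1000, nrow(lab)), ]
    expect_equal(m$bins$mean_score[b], mean(rows$score))
    expect_equal(m$bins$n_pos[b], sum(rows$is_pos))
    expect_equal(m$bins$n_neg[b], sum(!rows$is_pos))
  }
})

test_that("calibration is invariant under monotone score transformation", {
  fx <- make_scored_gold(400, 3600, "perfect", seed = 5L)
  m1 <- fit_lls_model(fx$spt, fx$gold, bin_size = 400L)
  spt2 <- dplyr::mutate(fx$spt, score = exp(score / 5))
  m2 <- fit_lls_model(spt2, fx$gold, bin_size = 400L)
  expect_equal(m1$bins$lls, m2$bins$lls)
  expect_equal(m1$bins$n_pos, m2$bins$n_pos)
})

test_that("0.632 bootstrap is seed-deterministic and tracks in-sample LLS", {
  fx <- make_scored_gold(800, 7200, "perfect", seed = 6L)
  b1 <- bootstrap_lls_model(fx$spt, fx$gold, bin_size = 800L, B = 30L,
                            seed = 11L)
  b2 <- bootstrap_lls_model(fx$spt, fx$gold, bin_size = 800L, B = 30L,
                            seed = 11L)
  expect_equal(b1$bins, b2$bins)
  # strong-signal fixture: bootstrap LLS within 10% of the in-sample value
  top <- b1$bins[1, ]
  expect_lt(abs(top$lls - top$lls_insample) / abs(top$lls_insample), 0.1)

  # label-free scores stay near zero whatever B
  nz <- make_scored_gold(500, 4500, "none", seed = 7L)
  for (B in c(10L, 50L)) {
    m <- bootstrap_lls_model(nz$spt, nz$gold, bin_size = 1000L, B = B,
                             seed = 3L)
    expect_true(all(abs(m$bins$lls) < 0.5))
  }
})

test_that("applying a model maps scores monotonically and thresholds edges", {
  fx <- make_scored_gold(400, 3600, "graded", seed = 8L)
  m <- fit_lls_model(fx$spt, fx$gold, bin_size = 400L)
  net <- apply_lls_model(m, fx$spt, min_lls = 0)
  # monotone scores in => monotone lls out (never inverted, flats allowed)
  joined <- dplyr::inner_join(net, fx$spt, by = c("gene_a", "gene_b"))
  expect_true(all(diff(joined$lls[order(joined$score)]) >= -1e-12))
  expect_gt(cor(joined$lls, joined$score, method = "spearman"), 0.5)
  # a score equal to a bin mean maps to (at least) that bin's fitted LLS level
  probe <- tibble::tibble(gene_a = "zz1", gene_b = "zz2",
                          score = m$bins$mean_score[1])
  expect_equal(apply_lls_model(m, probe)$lls, m$mapping(m$bins$mean_score[1]))
  # threshold above the maximum mapped value empties the network
  expect_equal(nrow(apply_lls_model(m, fx$spt,
                                    min_lls = max(net$lls) + 1)), 0L)
})

test_that("precision-recall bins accumulate benchmark overlap correctly", {
  pos <- tibble::tibble(gene_a = sprintf("p%02da", 1:20),
                        gene_b = sprintf("p%02db", 1:20))
  neg <- tibble::tibble(gene_a = sprintf("n%02da", 1:30),
                        gene_b = sprintf("n%02db", 1:30))
  gold <- gold_standard(pos, neg)
  # all top edges positive: first-point precision 1
  net <- dplyr::bind_rows(
    dplyr::mutate(pos, lls = 20 - dplyr::row_number()),
    dplyr::mutate(neg[1:10, ], lls = -(1:10))
  )
  pr <- precision_recall(net, gold, bin = 5L)
  expect_equal(pr$precision[1], 1)
  expect_equal(pr$cum_pairs, c(5L, 10L, 15L, 20L, 25L, 30L))
  # final recall is the fraction of benchmark positives present in the net
  expect_equal(pr$recall[nrow(pr)], 20 / 20)
  net2 <- dplyr::mutate(pos[1:8, ], lls = 1)
  pr2 <- precision_recall(net2, gold, bin = 4L)
  expect_equal(pr2$recall[nrow(pr2)], 8 / 20)
  expect_error(precision_recall(tibble::tibble(gene_a = "x", gene_b = "y",
                                               lls = 1), gold),
               "no overlap")

  # random ranking keeps precision near the benchmark positive fraction
  withr::with_seed(9, {
    big_pos <- all_pairs(sprintf("a%02d", 1:30))[1:200, ]
    big_neg <- all_pairs(sprintf("b%02d", 1:50))[1:800, ]
    g2 <- gold_standard(big_pos, big_neg)
    net3 <- dplyr::mutate(dplyr::bind_rows(big_pos, big_neg), lls = runif(1000))
    pr3 <- precision_recall(net3, g2, bin = 500L)
    expect_lt(abs(pr3$precision[nrow(pr3)] - 0.2), 0.05)
  })
})
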