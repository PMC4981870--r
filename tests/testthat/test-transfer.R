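make_sim <- function(ab, ba = NULL, within = NULL) {
  dplyr::bind_rows(
    dplyr::mutate(ab, direction = "AB"),
    if (!is.null(ba)) dplyr::mutate(ba, direction = "BA"),
    within
  )
}

test_that("bidirectional best hits require mutual best in both directions", {
  ab <- tibble::tibble(query = c("a1", "a2"), subject = c("b1", "b2"),
                       score = c(90, 80))
  ba <- tibble::tibble(query = c("b1", "b2"), subject = c("a1", "a2"),
                       score = c(85, 75))
  omap <- bbh(make_sim(ab, ba))
  expect_equal(omap$gene_src, c("a1", "a2"))
  expect_equal(omap$gene_tgt, c("b1", "b2"))
  expect_true(all(omap$inparalog_score == 1))

  # a -> b best but b's best is c != a: no link for a
  ab2 <- tibble::tibble(query = "a1", subject = "b1", score = 90)
  ba2 <- tibble::tibble(query = "b1", subject = c("a1", "a9"),
                        score = c(50, 95))
  expect_equal(nrow(bbh(make_sim(ab2, ba2))), 0L)
  expect_error(bbh(make_sim(ab2)), "both AB and BA")
})

test_that("bbh equals a brute-force double loop on random tables", {
  for (seed in 1:5) {
    sim <- withr::with_seed(seed, {
      a <- sprintf("a%02d", 1:12); b <- sprintf("b%02d", 1:12)
      ab <- expand.grid(query = a, subject = b, stringsAsFactors = FALSE) |>
        dplyr::slice_sample(n = 100) |>
        dplyr::mutate(score = round(runif(100, 1, 100), 3))
      ba <- expand.grid(query = b, subject = a, stringsAsFactors = FALSE) |>
        dplyr::slice_sample(n = 100) |>
        dplyr::mutate(score = round(runif(100, 1, 100), 3))
      make_sim(ab, ba)
    })
    got <- bbh(sim)
    # oracle: explicit best-hit scan with the same deterministic tie rule
    best <- function(df, q) {
      h <- df[df$query == q, ]
      h <- h[order(-h$score, h$subject), ]
      if (nrow(h) == 0L) NA_character_ else h$subject[1]
    }
    ab <- sim[sim$direction == "AB", ]; ba <- sim[sim$direction == "BA", ]
    expected <- list()
    for (q in unique(ab$query)) {
      b <- best(ab, q)
      if (!is.na(b) && identical(best(ba, b), q)) {
        expected[[length(expected) + 1]] <- c(q, b)
      }
    }
    expected <- do.call(rbind, expected)
    expect_equal(nrow(got), NROW(expected))
    if (NROW(expected) > 0) {
      expect_setequal(paste(got$gene_src, got$gene_tgt),
                      paste(expected[, 1], expected[, 2]))
    }
  }
})

test_that("inparanoid clustering grades inparalogs by similarity ratio", {
  ab <- tibble::tibble(query = "a1", subject = "b1", score = 100)
  ba <- tibble::tibble(query = "b1", subject = "a1", score = 100)
  # no within-species hits: reduces to bbh
  expect_equal(nrow(inparanoid_clusters(make_sim(ab, ba))), 1L)

  # a duplicate at 80% of the seed similarity joins with confidence 0.8
  within <- tibble::tibble(query = "a2", subject = "a1", direction = "AA",
                           score = 80)
  omap <- inparanoid_clusters(make_sim(ab, ba, within))
  dup <- omap[omap$gene_src == "a2", ]
  expect_equal(dup$inparalog_score, 0.8)
  expect_equal(dup$gene_tgt, "b1")

  # a duplicate exactly as similar as the seed scores 1
  within$score <- 100
  omap2 <- inparanoid_clusters(make_sim(ab, ba, within))
  expect_equal(omap2$inparalog_score[omap2$gene_src == "a2"], 1)

  # below the membership cutoff the duplicate is excluded
  within$score <- 30
  omap3 <- inparanoid_clusters(make_sim(ab, ba, within), overlap_cut = 0.5)
  expect_false("a2" %in% omap3$gene_src)
})

test_that("transfer multiplies source weight by both link confidences", {
  net <- tibble::tibble(gene_a = "a1", gene_b = "a2", lls = 2)
  omap <- tibble::tibble(
    gene_src = c("a1", "a2"), gene_tgt = c("b1", "b2"),
    inparalog_score = c(0.5, 0.5), cluster_id = c("c1", "c2")
  )
  out <- transfer_network(net, omap)
  expect_equal(nrow(out), 1L)
  expect_equal(out$lls, 2 * 0.25)

  # seed orthologs (confidence 1) preserve the source weight
  omap$inparalog_score <- 1
  expect_equal(transfer_network(net, omap)$lls, 2)

  # identity orthology is a no-op on edges and weights
  src <- random_net(15L, seed = 3L)
  names(src)[3] <- "lls"
  genes <- unique(c(src$gene_a, src$gene_b))
  id_map <- tibble::tibble(gene_src = genes, gene_tgt = genes,
                           inparalog_score = 1, cluster_id = genes)
  rt <- transfer_network(src, id_map)
  orig <- dplyr::arrange(canonical_pairs(src), dplyr::desc(lls), gene_a, gene_b)
  expect_equal(rt$gene_a, orig$gene_a)
  expect_equal(rt$gene_b, orig$gene_b)
  expect_equal(rt$lls, orig$lls)

  # fan-out keeps the maximum route, never a sum
  omap_fan <- tibble::tibble(
    gene_src = c("a1", "a1", "a2"), gene_tgt = c("b1", "b1x", "b2"),
    inparalog_score = c(1, 0.7, 1), cluster_id = "c1"
  )
  # force both routes onto one target pair via a second source edge
  net2 <- tibble::tibble(gene_a = c("a1", "a1x"), gene_b = c("a2", "a2"),
                         lls = c(2, 3))
  omap2 <- tibble::tibble(
    gene_src = c("a1", "a1x", "a2"), gene_tgt = c("b1", "b1", "b2"),
    inparalog_score = c(1, 0.6, 1), cluster_id = c("c1", "c1", "c2")
  )
  out2 <- transfer_network(net2, omap2)
  expect_equal(out2$lls, max(2 * 1, 3 * 0.6))

  # transfer never increases a weight (confidences are <= 1)
  w <- generate_world(seed = 3L, n_genes = 80L, n_modules = 3L,
                      module_size = 10L)
  omap_w <- inparanoid_clusters(w$sim_table)
  src_w <- dplyr::mutate(w$truth, lls = withr::with_seed(4, runif(nrow(w$truth), 1, 3)))
  out_w <- transfer_network(src_w, omap_w)
  src_max <- max(src_w$lls)
  expect_true(all(out_w$lls <= src_max + 1e-12))

  expect_error(
    transfer_network(net, tibble::tibble(gene_src = "zz", gene_tgt = "y",
                                         inparalog_score = 1, cluster_id = "c")),
    "does not cover")
})

test_that("term recovery AUC is high for planted cliques, ~0.5 when scattered", {
  p <- planted_module_network(seed = 5L, n_genes = 120L, n_modules = 3L,
                              module_size = 12L)
  res <- term_recovery_auc(p$net, p$annotations, min_term = 5L)
  expect_equal(nrow(res), 3L)
  expect_true(all(res$auc > 0.9))

  # terms scattered at random over a rewired net recover at chance level
  nn <- rewire_network(p$net, seed = 6L)
  res0 <- term_recovery_auc(nn, p$annotations, min_term = 5L)
  expect_lt(abs(mean(res0$auc) - 0.5), 0.12)

  # terms below the membership floor are skipped
  small_ann <- tibble::tibble(term = "tiny", gene = p$modules$gene[1:3])
  expect_message(out <- term_recovery_auc(p$net, small_ann, min_term = 5L),
                 "skipping")
  expect_equal(nrow(out), 0L)
})
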