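test_that("neighborhood scores sum guide-edge weights and exclude guides", {
  net <- tiny_net()
  # single guide: ranking is the guide's adjacency sorted by weight
  pr <- neighborhood_scores(net, "g3")
  expect_equal(pr$candidates$gene, c("g2", "g4", "g1"))
  expect_equal(pr$candidates$score, c(2.0, 1.0, 0.5))

  # candidate adjacent to two guides sums both edges
  net2 <- tibble::tibble(gene_a = c("u1", "u2"), gene_b = c("x", "x"),
                         weight = c(1.2, 0.8))
  pr2 <- suppressMessages(neighborhood_scores(net2, c("u1", "u2")))
  expect_equal(pr2$candidates$score[pr2$candidates$gene == "x"], 2.0)

  # guides never appear as candidates
  pr3 <- neighborhood_scores(net, c("g1", "g2"))
  expect_false(any(c("g1", "g2") %in% pr3$candidates$gene))
  expect_error(neighborhood_scores(net, "absent"), "no guide gene")

  # additivity over disjoint guide sets, per candidate
  big <- random_net(25L, p = 0.3, seed = 2L)
  g1 <- c("g01", "g02"); g2 <- c("g10", "g11")
  s <- function(guides) {
    cc <- neighborhood_scores(big, guides)$candidates
    setNames(cc$score, cc$gene)
  }
  s1 <- s(g1); s2 <- s(g2); s12 <- s(c(g1, g2))
  shared <- setdiff(names(s12), c(g1, g2))
  for (g in shared) {
    v1 <- if (g %in% names(s1)) s1[[g]] else 0
    v2 <- if (g %in% names(s2)) s2[[g]] else 0
    expect_equal(s12[[g]], v1 + v2)
  }
})

test_that("leave-one-out AUC separates cliques and matches the oracle", {
  # guides form a clique disconnected from the rest: perfect AUC
  clique <- all_pairs(c("c1", "c2", "c3", "c4"))
  clique$weight <- 1
  rest <- tibble::tibble(gene_a = c("r1", "r2"), gene_b = c("r2", "r3"),
                         weight = 1)
  net <- dplyr::bind_rows(clique, rest)
  expect_equal(loo_auc(net, c("c1", "c2", "c3", "c4")), 1.0)
  expect_error(loo_auc(net, "c1"), ">= 2 guide genes")

  # oracle equivalence on random nets and random guide sets
  for (seed in 1:6) {
    withr::with_seed(seed, {
      net_r <- random_net(sample(15:40, 1), p = 0.25, seed = seed + 100)
      genes <- unique(c(net_r$gene_a, net_r$gene_b))
      guides <- sample(genes, sample(3:6, 1))
      expect_equal(loo_auc(net_r, guides), loo_auc_oracle(net_r, guides),
                   tolerance = 1e-12)
    })
  }

  # random guides in an Erdos-Renyi net: chance-level AUC on average
  aucs <- vapply(1:20, function(seed) {
    withr::with_seed(seed, {
      net_r <- random_net(40L, p = 0.2, seed = seed + 500)
      genes <- unique(c(net_r$gene_a, net_r$gene_b))
      loo_auc(net_r, sample(genes, 6))
    })
  }, numeric(1L))
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("context hubs use the exact one-tailed hypergeometric enrichment", {
  # hub whose neighborhood equals the DEG set exactly: minimal tail term
  hub_edges <- tibble::tibble(gene_a = "h", gene_b = sprintf("n%02d", 1:10),
                              weight = 1)
  filler <- tibble::tibble(gene_a = sprintf("f%02d", 1:89),
                           gene_b = c(sprintf("f%02d", 2:89), "n01"),
                           weight = 1)
  net <- dplyr::bind_rows(hub_edges, filler)  # universe: 100 genes

  res <- context_hubs(net, degs = sprintf("n%02d", 1:10), min_degree = 10L)
  expect_equal(res$gene, "h")
  expect_equal(res$overlap, 10L)
  expect_equal(res$p_value, 1 / choose(99, 10), tolerance = 1e-12)

  # p-values match fisher.test on random configurations with small margins
  for (seed in 1:10) {
    withr::with_seed(seed, {
      genes <- unique(c(net$gene_a, net$gene_b))
      degs <- sample(setdiff(genes, "h"), sample(5:40, 1))
      got <- context_hubs(net, degs, min_degree = 10L, p_cut = 1)
      row <- got[got$gene == "h", ]
      expect_equal(row$p_value,
                   fisher_oracle(row$overlap, length(degs), row$degree,
                                 length(genes) - 1L),
                   tolerance = 1e-9)
    })
  }

  # degree threshold above the maximum degree: empty result with a warning
  expect_warning(out <- context_hubs(net, "n01", min_degree = 1000L),
                 "hub degree")
  expect_equal(nrow(out), 0L)
  expect_error(context_hubs(net, "zzz"), "no DEG")
})

test_that("function prediction ranks terms by summed neighbor edge weight", {
  net <- tibble::tibble(
    gene_a = c("q", "q", "q"),
    gene_b = c("n1", "n2", "n3"),
    weight = c(1, 2, 2.9)
  )
  ann <- tibble::tibble(
    term = c("shared", "shared", "other"),
    gene = c("n1", "n2", "n3")
  )
  out <- predict_function(net, "q", ann)
  expect_equal(out$term, c("shared", "other"))
  expect_equal(out$score, c(3.0, 2.9))

  # single neighbor, single term
  out1 <- predict_function(net[1, ], "q", ann)
  expect_equal(out1, tibble::tibble(term = "shared", score = 1))

  # k larger than the distinct terms returns everything
  expect_equal(nrow(predict_function(net, "q", ann, k = 50L)), 2L)
  expect_error(predict_function(net, "zz", ann), "not in network")
  expect_message(empty <- predict_function(net, "n1", ann[0, ]), "no annotated")
  expect_equal(nrow(empty), 0L)
})

test_that("gba benchmark summarises per-term AUCs against 0.5", {
  p <- planted_module_network(seed = 8L, n_genes = 150L, n_modules = 4L,
                              module_size = 12L)
  gb <- gba_benchmark(p$net, p$annotations, min_term = 5L)
  expect_equal(nrow(gb$terms), 4L)  # one AUC per term
  expect_gt(gb$median_auc, 0.9)
  expect_lt(gb$p_value, 0.05)
  g <- glance(gb)
  expect_equal(g$n_terms, 4L)
  suppressMessages(
    expect_error(gba_benchmark(p$net, p$annotations, min_term = 100L)))
})
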