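test_that("the one-sided Fisher tail is exact", {
  expect_equal(fisher_greater(0, 10, 5, 40), 1)  # P(X >= 0) = 1
  # k = n = K: single possible table in the tail
  expect_equal(fisher_greater(3, 3, 3, 30), bf_hyper_tail(3, 3, 3, 30))
  for (i in 1:200) {
    tb <- rand_table(i)
    expect_equal(fisher_greater(tb$k, tb$K, tb$n, tb$N),
                 bf_hyper_tail(tb$k, tb$K, tb$n, tb$N), tolerance = 1e-10)
  }
  expect_error(fisher_greater(5, 3, 4, 10), class = "ppiclust_value_error")
})

test_that("the EASE score jackknifes the overlap and dominates the Fisher p", {
  expect_equal(ease_p(1, 10, 5, 100), 1)  # single-gene overlaps never significant
  expect_equal(ease_p(0, 10, 5, 100), 1)
  for (i in 1:200) {
    tb <- rand_table(100 + i)
    e <- ease_p(tb$k, tb$K, tb$n, tb$N)
    f <- fisher_greater(tb$k, tb$K, tb$n, tb$N)
    expect_gte(e, f)
    expect_equal(e, bf_hyper_tail(max(tb$k - 1, 0), tb$K, tb$n, tb$N),
                 tolerance = 1e-12)
  }
})

test_that("multiple-testing corrections follow their definitions", {
  expect_equal(bonferroni(0.01), 0.01)
  expect_equal(bonferroni(c(0.4, 0.4, 0.4)), c(1, 1, 1))
  expect_equal(bonferroni(c(0.01, 0.2)), c(0.02, 0.4))
  expect_error(bonferroni(c(0.5, 1.2)), class = "ppiclust_value_error")

  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  for (i in 1:500) {
    p <- withr::with_seed(i, stats::runif(sample(1:40, 1))^2)
    expect_equal(bh_fdr(p), bf_bh(p), tolerance = 1e-12)
    # permutation equivariance
    perm <- withr::with_seed(i + 1, sample(length(p)))
    expect_equal(bh_fdr(p[perm]), bh_fdr(p)[perm], tolerance = 1e-12)
  }
})

test_that("cluster scoring handles degenerate disease sets and flags significance by FDR", {
  g <- dplyr::bind_rows(k_clique(c("A", "B", "C")),
                        k_clique(c("P", "Q", "R", "S")))
  run <- dpcluso(edge_net(g), cluster_params(0.5))
  bg <- c("A", "B", "C", "P", "Q", "R", "S", "T", "U")

  # cluster disjoint from the disease set -> p = 1
  sc <- score_clusters(run, disease_set = c("T", "U"), background = bg)
  expect_true(all(sc$p == 1))
  expect_false(any(sc$significant))
  # disease set = background -> k = n, no enrichment possible
  sc2 <- score_clusters(run, disease_set = bg, background = bg)
  expect_true(all(sc2$p == 1))
  # ordering invariants within a corrected family
  expect_true(all(sc$p <= sc$p_bonferroni + 1e-15))
  expect_true(all(sc$p <= sc$fdr + 1e-15))
  expect_error(score_clusters(run, disease_set = "ZZ", background = bg),
               class = "ppiclust_value_error")
})

test_that("planted disease modules reach lower FDR than background clusters", {
  med_fdr <- function(s) {
    cfg <- small_config(seed = s, n_proteins = 150)
    ppi <- generate_ppi(cfg)
    dg <- generate_disease_reference(ppi$truth, cfg)
    net <- edge_net(ppi$interactions)
    run <- dpcluso(net, cluster_params(0.7))
    sc <- score_clusters(run, intersect(dg$protein, net$nodes$protein),
                         net$nodes$protein)
    dmn <- unique(unlist(ppi$truth$modules[ppi$truth$disease_modules]))
    memb <- tidy(run)
    planted_frac <- tapply(memb$node %in% dmn, memb$cluster_id, mean)
    sc$planted <- planted_frac[as.character(sc$cluster_id)] > 0.5
    c(planted = median(sc$fdr[sc$planted]),
      background = median(sc$fdr[!sc$planted]))
  }
  res <- vapply(1:20, med_fdr, numeric(2))
  expect_lt(median(res["planted", ]), median(res["background", ]))
})

test_that("pathway enrichment applies count, EASE and FDR thresholds", {
  cluster <- sprintf("P%02d", 1:8)
  bg <- sprintf("P%02d", 1:60)
  pw <- list(
    exact = cluster,                         # identical to the cluster
    single = c("P01", "Q1", "Q2"),           # overlap of 1: always excluded
    random = c("Q3", "Q4", "Q5", "Q6"))
  res <- enrich_pathways(cluster, pw, bg)
  expect_true("exact" %in% res$pathway)
  expect_false("single" %in% res$pathway)
  expect_equal(res$pathway[1], "exact")  # minimal EASE among competitors

  none <- enrich_pathways(cluster, list(miss = c("Q7", "Q8")), bg)
  expect_equal(nrow(none), 0)
  expect_error(enrich_pathways(cluster, list(), bg),
               class = "ppiclust_value_error")
})

test_that("raw cluster p-values are calibrated under a null disease set", {
  cfg <- small_config(seed = 31, n_proteins = 120)
  net <- edge_net(generate_ppi(cfg)$interactions)
  run <- dpcluso(net, cluster_params(0.6))
  nodes <- net$nodes$protein
  K <- 25
  set.seed(99)
  hits <- replicate(400, {
    dg <- sample(nodes, K)
    sc <- score_clusters(run, dg, nodes)
    mean(sc$p < 0.05)
  })
  # one-sided discrete test is conservative: rejection rate at most ~5%
  expect_lt(mean(hits), 0.05 + 3 * stats::sd(hits) / sqrt(length(hits)))
})
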