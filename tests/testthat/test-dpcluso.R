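test_that("edge weights count common neighbors", {
  tri <- k_clique(c("A", "B", "C"))
  expect_true(all(edge_weights(tri)$weight == 1))

  star <- tibble::tibble(a = "H", b = c("X", "Y", "Z"), score = 1)
  expect_true(all(edge_weights(star)$weight == 0))

  g <- rand_graph(20, 0.25, seed = 21)
  ew <- edge_weights(g)
  for (r in seq_len(nrow(ew))) {
    na <- unique(c(g$b[g$a == ew$a[r]], g$a[g$b == ew$a[r]]))
    nb <- unique(c(g$b[g$a == ew$b[r]], g$a[g$b == ew$b[r]]))
    expect_equal(ew$weight[r], length(intersect(na, nb)))
  }
})

test_that("cluster property matches its definition", {
  tri_plus <- dplyr::bind_rows(
    k_clique(c("A", "B", "C")),
    tibble::tibble(a = c("A", "B"), b = c("N", "N"), score = 1))
  # N has 2 edges into the triangle (density 1, size 3) -> 2/3
  expect_equal(cluster_property("N", c("A", "B", "C"), tri_plus), 2 / 3)
  expect_equal(cluster_property("Z", c("A", "B", "C"),
                                dplyr::bind_rows(tri_plus,
                                                 tibble::tibble(a = "Y", b = "Z", score = 1))),
               0)
  expect_error(cluster_property("A", c("A", "B"), tri_plus),
               class = "ppiclust_contract_error")
  # randomized instances: recompute from definitions
  for (i in 1:20) {
    g <- rand_graph(15, 0.3, seed = 500 + i)
    nodes <- sort(unique(c(g$a, g$b)))
    if (length(nodes) < 5) next
    cl <- sort(sample(nodes, 4))
    outside <- setdiff(nodes, cl)[1]
    if (is.na(outside)) next
    e_in <- sum(g$a %in% cl & g$b %in% cl)
    d_k <- 2 * e_in / (4 * 3)
    e_nk <- sum((g$a == outside & g$b %in% cl) |
                  (g$b == outside & g$a %in% cl))
    want <- if (d_k == 0) 0 else e_nk / (d_k * 4)
    expect_equal(cluster_property(outside, cl, g), want)
  }
})

test_that("cluster growth follows the density and periphery rules", {
  single <- tibble::tibble(a = "A", b = "B", score = 1)
  cl <- grow_cluster("A", single, cluster_params(1.0))
  expect_setequal(cl$nodes, c("A", "B"))
  expect_equal(cl$density, 1)

  k4 <- k_clique(c("A", "B", "C", "D"))
  expect_setequal(grow_cluster("A", k4, cluster_params(0.5))$nodes,
                  c("A", "B", "C", "D"))

  two_k4 <- dplyr::bind_rows(k_clique(c("V", "A", "B", "C")),
                             k_clique(c("V", "X", "Y", "Z")))
  grown <- grow_cluster("V", two_k4, cluster_params(0.9))
  expect_equal(length(grown$nodes), 4)  # one K4 only
  expect_true(setequal(grown$nodes, c("V", "A", "B", "C")) ||
                setequal(grown$nodes, c("V", "X", "Y", "Z")))
  expect_error(grow_cluster("missing", k4, cluster_params(0.5)),
               class = "ppiclust_lookup_error")
})

test_that("the clustering covers every node and respects its guarantees on canonical graphs", {
  # edgeless graph: one singleton per node
  lonely <- edge_net(tibble::tibble(a = character(0), b = character(0),
                                    score = numeric(0)),
                     nodes = c("A", "B", "C"))
  run <- dpcluso(lonely, cluster_params(0.5))
  expect_equal(nrow(run$clusters), 3)
  expect_true(all(run$clusters$size == 1))

  # disjoint K3 and K4 are returned exactly
  g <- dplyr::bind_rows(k_clique(c("A", "B", "C")),
                        k_clique(c("P", "Q", "R", "S")))
  run2 <- dpcluso(g, cluster_params(0.5))
  multi <- run2$clusters[run2$clusters$size >= 2, ]
  expect_equal(nrow(multi), 2)
  expect_setequal(multi$nodes[[which(multi$size == 3)]], c("A", "B", "C"))
  expect_setequal(multi$nodes[[which(multi$size == 4)]],
                  c("P", "Q", "R", "S"))

  # two K4 sharing a node: two overlapping K4 clusters
  two_k4 <- dplyr::bind_rows(k_clique(c("V", "A", "B", "C")),
                             k_clique(c("V", "X", "Y", "Z")))
  run3 <- dpcluso(two_k4, cluster_params(0.9))
  sizes4 <- run3$clusters[run3$clusters$size == 4, ]
  expect_equal(nrow(sizes4), 2)
  expect_true(all(vapply(sizes4$nodes, function(nd) "V" %in% nd, logical(1))))
})

test_that("coverage, density guarantee, connectivity and determinism hold on random graphs", {
  for (i in 1:60) {
    withr::with_seed(7000 + i, {
      n <- sample(4:40, 1)
      p_edge <- stats::runif(1, 0.05, 0.5)
      d_in <- sample(seq(0.1, 0.9, 0.1), 1)
    })
    g <- rand_graph(n, p_edge, seed = 7100 + i)
    net <- edge_net(g, nodes = sprintf("N%03d", 1:n))
    run <- dpcluso(net, cluster_params(d_in))
    # coverage
    expect_setequal(unique(unlist(run$clusters$nodes)), net$nodes$protein)
    # density >= d_in and connectivity for every multi-node cluster
    for (j in seq_len(nrow(run$clusters))) {
      nd <- run$clusters$nodes[[j]]
      if (length(nd) >= 2) {
        e_in <- sum(g$a %in% nd & g$b %in% nd)
        expect_gte(2 * e_in / (length(nd) * (length(nd) - 1)), d_in - 1e-12)
        expect_true(bf_connected(g, nd))
      }
    }
    # determinism under row permutation
    perm <- withr::with_seed(i, sample(nrow(g)))
    net_p <- edge_net(g[perm, ], nodes = sprintf("N%03d", 1:n))
    run_p <- dpcluso(net_p, cluster_params(d_in))
    expect_identical(run$clusters, run_p$clusters)
  }
})

test_that("at density 1 every reported cluster is a maximal-by-growth clique", {
  # Uncovered-only seeding means a maximal clique whose members are all
  # claimed by earlier clusters is not regenerated, so containment of every
  # maximal clique is not guaranteed; what is guaranteed at d_in = 1 is
  # that every multi-node cluster is itself a clique (verified against
  # brute-force clique enumeration) and that growth cannot be extended.
  for (i in 1:40) {
    withr::with_seed(9000 + i, {
      n <- sample(5:9, 1)
      p_edge <- stats::runif(1, 0.3, 0.8)
    })
    g <- rand_graph(n, p_edge, seed = 9100 + i)
    if (nrow(g) == 0) next
    net <- edge_net(g, nodes = sprintf("N%03d", 1:n))
    run <- dpcluso(net, cluster_params(1.0))
    ig <- igraph::graph_from_data_frame(g[, 1:2], directed = FALSE)
    mc_all <- lapply(igraph::max_cliques(ig), function(cl) sort(names(cl)))
    for (nd in run$clusters$nodes) {
      if (length(nd) >= 2) {
        e_in <- sum(g$a %in% nd & g$b %in% nd)
        expect_equal(e_in, choose(length(nd), 2))  # induced clique
        # grown clique is maximal: it equals some brute-force maximal clique
        expect_true(any(vapply(mc_all, function(m) identical(sort(nd), m),
                               logical(1))))
      }
    }
  }
})

test_that("the density sweep summarises runs consistently", {
  g <- generate_ppi(small_config(seed = 2))$interactions
  net <- edge_net(g)
  sweep <- density_sweep(net, densities = c(0.3, 0.9))
  expect_named(sweep, c("d0.3", "d0.9"))
  tab <- tidy(sweep)
  expect_equal(tab$density_threshold, c(0.3, 0.9))
  # bookkeeping identity: summary recomputable from the cluster lists
  for (nm in names(sweep)) {
    cl <- sweep[[nm]]$clusters
    row <- tab[tab$density_threshold == sweep[[nm]]$params$d_in, ]
    expect_equal(row$total_clusters, nrow(cl))
    expect_equal(row$max_size, max(cl$size))
    expect_equal(row$average_size, mean(cl$size))
  }
  # single density behaves as dpcluso
  single <- density_sweep(net, densities = 0.5)
  expect_identical(single[[1]]$clusters,
                   dpcluso(net, cluster_params(0.5))$clusters)
  expect_error(density_sweep(net, densities = numeric(0)),
               class = "ppiclust_value_error")
})

test_that("average cluster size decreases from low to high density on planted graphs", {
  ratios <- vapply(1:10, function(s) {
    g <- generate_ppi(small_config(seed = s, n_proteins = 120))$interactions
    net <- edge_net(g)
    lo <- glance(dpcluso(net, cluster_params(0.1)))$average_size
    hi <- glance(dpcluso(net, cluster_params(0.9)))$average_size
    hi <= lo
  }, logical(1))
  expect_true(median(ratios) == 1)
})
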