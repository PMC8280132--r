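#' Clustering parameters for the density-periphery algorithm
#'
#' @param d_in Density threshold in (0, 1]: every reported multi-node
#'   cluster has induced density >= `d_in`.
#' @param cp_in Cluster-property threshold (periphery-tracking admission
#'   criterion), conventionally 0.5.
#' @param min_report_size Minimum cluster size used by downstream
#'   enrichment (singletons are still emitted to guarantee coverage).
#' @return A `cluster_params` list.
#' @export
cluster_params <- function(d_in, cp_in = 0.5, min_report_size = 2) {
  if (!is.numeric(d_in) || length(d_in) != 1 || is.na(d_in) ||
      d_in <= 0 || d_in > 1) {
    abort("`d_in` must be a density in (0, 1]", class = "ppiclust_value_error")
  }
  if (cp_in < 0) abort("`cp_in` must be >= 0", class = "ppiclust_value_error")
  structure(list(d_in = d_in, cp_in = cp_in,
                 min_report_size = as.integer(min_report_size)),
            class = "cluster_params")
}

# internal graph representation: nodes sorted lexicographically, adjacency
# as integer index lists -- node indices double as the deterministic id
# tie-break, and the representation is invariant to edge-file row order
dpc_graph <- function(x) {
  edges <- if (inherits(x, "disease_network")) x$edges else as_tibble(x)
  stopifnot(all(c("a", "b") %in% names(edges)))
  extra_nodes <- if (inherits(x, "disease_network")) x$nodes$protein else character(0)
  nodes <- sort(unique(c(edges$a, edges$b, extra_nodes)))
  n <- length(nodes)
  ai <- match(edges$a, nodes)
  bi <- match(edges$b, nodes)
  keep <- ai != bi
  ai <- ai[keep]; bi <- bi[keep]
  key <- paste0(pmin(ai, bi), "_", pmax(ai, bi))
  dup <- duplicated(key)
  ai <- ai[!dup]; bi <- bi[!dup]
  adj <- vector("list", n)
  ord <- split(c(bi, ai), c(ai, bi))
  for (nm in names(ord)) adj[[as.integer(nm)]] <- sort(ord[[nm]])
  for (i in seq_len(n)) if (is.null(adj[[i]])) adj[[i]] <- integer(0)
  list(nodes = nodes, adj = adj, n = n,
       edge_i = pmin(ai, bi), edge_j = pmax(ai, bi))
}

#' Common-neighbor edge weights
#'
#' The weight of edge \{u, v\} is the number of common neighbors of u and v
#' (the number of triangles through the edge), the edge weight used to rank
#' cluster seeds.
#'
#' @param net A `disease_network` or an edge table with columns `a`, `b`.
#' @return Tibble (`a`, `b`, `weight`), `a < b`, sorted.
#' @export
edge_weights <- function(net) {
  g <- dpc_graph(net)
  w <- vapply(seq_along(g$edge_i), function(k) {
    length(intersect_sorted(g$adj[[g$edge_i[k]]], g$adj[[g$edge_j[k]]]))
  }, integer(1))
  tibble(a = g$nodes[g$edge_i], b = g$nodes[g$edge_j], weight = w) |>
    arrange(.data$a, .data$b)
}

intersect_sorted <- function(x, y) x[x %in% y]

node_weights_int <- function(g) {
  w <- numeric(g$n)
  if (length(g$edge_i) == 0) return(w)
  ew <- vapply(seq_along(g$edge_i), function(k) {
    length(intersect_sorted(g$adj[[g$edge_i[k]]], g$adj[[g$edge_j[k]]]))
  }, integer(1))
  for (k in seq_along(ew)) {
    w[g$edge_i[k]] <- w[g$edge_i[k]] + ew[k]
    w[g$edge_j[k]] <- w[g$edge_j[k]] + ew[k]
  }
  w
}

#' Cluster property of an outside node with respect to a cluster
#'
#' `cp = E_nk / (d_k * |N_k|)` where `E_nk` is the number of edges between
#' the node and cluster members, `d_k` the cluster's density and `|N_k|` its
#' size; defined as 0 when `d_k = 0`.  The density of a single-node cluster
#' is taken as 1.
#'
#' @param node Protein id outside the cluster.
#' @param cluster Character vector of cluster member ids.
#' @param net A `disease_network` or edge table.
#' @return The cluster property value.
#' @export
cluster_property <- function(node, cluster, net) {
  if (node %in% cluster) {
    abort("`node` must lie outside the cluster", class = "ppiclust_contract_error")
  }
  g <- dpc_graph(net)
  ni <- match(node, g$nodes)
  if (is.na(ni)) {
    abort(paste0("node not in network: ", node), class = "ppiclust_lookup_error")
  }
  ci <- match(cluster, g$nodes)
  e_nk <- sum(g$adj[[ni]] %in% ci)
  d_k <- induced_density(g, ci)
  if (d_k == 0) return(0)
  e_nk / (d_k * length(ci))
}

induced_density <- function(g, members) {
  s <- length(members)
  if (s <= 1) return(1)
  e <- sum(vapply(members, function(i) sum(g$adj[[i]] %in% members), numeric(1))) / 2
  2 * e / (s * (s - 1))
}

# core greedy growth on integer indices; returns member indices
grow_indices <- function(g, seed_i, d_in, cp_in, node_w) {
  eps <- 1e-12
  in_cl <- logical(g$n)
  in_cl[seed_i] <- TRUE
  members <- seed_i
  e_k <- 0
  e_to <- numeric(g$n)
  nb <- g$adj[[seed_i]]
  e_to[nb] <- e_to[nb] + 1
  repeat {
    s <- length(members)
    cand <- which(e_to > 0 & !in_cl)
    if (length(cand) == 0) break
    e_c <- e_to[cand]
    d_k <- if (s == 1) 1 else 2 * e_k / (s * (s - 1))
    new_density <- 2 * (e_k + e_c) / ((s + 1) * s)
    cp <- if (d_k > 0) e_c / (d_k * s) else rep(0, length(cand))
    ok <- new_density >= d_in - eps & cp >= cp_in - eps
    if (!any(ok)) break
    cand <- cand[ok]; e_c <- e_c[ok]
    pick <- cand[order(-e_c, -node_w[cand], cand)[1]]
    in_cl[pick] <- TRUE
    members <- c(members, pick)
    e_k <- e_k + e_to[pick]
    nb <- g$adj[[pick]]
    e_to[nb] <- e_to[nb] + 1
  }
  sort(members)
}

#' Grow one cluster from a seed node
#'
#' Starting from the seed, neighbor candidates are examined in priority
#' order (edges into the cluster descending, node weight descending, id
#' ascending) and the best candidate whose admission keeps the cluster
#' density >= `d_in` and whose cluster property is >= `cp_in` is added;
#' growth stops when no candidate qualifies.
#'
#' @param seed Seed protein id.
#' @param net A `disease_network` or edge table.
#' @param params A [cluster_params()].
#' @return A list (`nodes`, `density`, `seed_node`).
#' @export
grow_cluster <- function(seed, net, params) {
  g <- dpc_graph(net)
  si <- match(seed, g$nodes)
  if (is.na(si)) {
    abort(paste0("seed not in network: ", seed), class = "ppiclust_lookup_error")
  }
  nw <- node_weights_int(g)
  members <- grow_indices(g, si, params$d_in, params$cp_in, nw)
  list(nodes = g$nodes[members],
       density = induced_density(g, members),
       seed_node = seed)
}

#' Overlapping, coverage-guaranteeing density clustering
#'
#' Repeatedly seeds a cluster at the uncovered node with the highest node
#' weight (sum of incident common-neighbor edge weights; ties broken by
#' degree, then id), grows it greedily on the *full* graph under the density
#' and cluster-property thresholds, and marks its members covered, until
#' every node is covered.  Because growth ignores coverage, clusters may
#' overlap; because every iteration covers at least the seed, every node
#' ends up in at least one cluster.  Output is deterministic for a given
#' network, regardless of edge-file row order.
#'
#' @param net A `disease_network` or edge table with columns `a`, `b`.
#' @param params A [cluster_params()].
#' @return An object of class `clustering_run`: list with `params`,
#'   `clusters` (tibble `cluster_id`, `seed_node`, `size`, `density`,
#'   `nodes` list-column) and `n_nodes`.
#' @export
dpcluso <- function(net, params) {
  g <- dpc_graph(net)
  if (g$n == 0) {
    abort("cannot cluster an empty network", class = "ppiclust_value_error")
  }
  nw <- node_weights_int(g)
  deg <- lengths(g$adj)
  seed_order <- order(-nw, -deg, seq_len(g$n))
  covered <- logical(g$n)
  rows <- list()
  k <- 0L
  for (si in seed_order) {
    if (covered[si]) next
    members <- grow_indices(g, si, params$d_in, params$cp_in, nw)
    covered[members] <- TRUE
    k <- k + 1L
    rows[[k]] <- tibble(
      cluster_id = k, seed_node = g$nodes[si],
      size = length(members),
      density = induced_density(g, members),
      nodes = list(g$nodes[members]))
  }
  structure(list(params = params, clusters = bind_rows(rows), n_nodes = g$n),
            class = "clustering_run")
}

#' @export
print.clustering_run <- function(x, ...) {
  s <- glance(x)
  cat(sprintf(
    "<clustering_run> d_in=%g: %d clusters (%d of size >= 2), max size %d, mean size %.3f\n",
    x$params$d_in, s$total_clusters, s$clusters_ge2, s$max_size, s$average_size))
  invisible(x)
}

#' Cluster membership as a long table
#'
#' @param x A `clustering_run`.
#' @param ... Unused.
#' @return Tibble (`cluster_id`, `node`, `size`, `density`).
#' @method tidy clustering_run
#' @export
tidy.clustering_run <- function(x, ...) {
  x$clusters |>
    select("cluster_id", "nodes", "size", "density") |>
    tidyr::unnest_longer("nodes", values_to = "node") |>
    select("cluster_id", "node", "size", "density")
}

#' One-row summary of a clustering run
#'
#' Reports both all-cluster and size->=2 summaries (singleton clusters are
#' emitted to guarantee coverage but usually excluded from analysis).
#'
#' @param x A `clustering_run`.
#' @param ... Unused.
#' @return Tibble with `density_threshold`, `total_clusters`, `max_size`,
#'   `average_size`, `clusters_ge2`, `average_size_ge2`.
#' @method glance clustering_run
#' @export
glance.clustering_run <- function(x, ...) {
  cl <- x$clusters
  ge2 <- cl |> filter(.data$size >= 2)
  tibble(
    density_threshold = x$params$d_in,
    total_clusters = nrow(cl),
    max_size = if (nrow(cl)) max(cl$size) else 0L,
    average_size = if (nrow(cl)) mean(cl$size) else NA_real_,
    clusters_ge2 = nrow(ge2),
    average_size_ge2 = if (nrow(ge2)) mean(ge2$size) else NA_real_
  )
}

#' Run the clustering over a sweep of density thresholds
#'
#' @param net A `disease_network` or edge table.
#' @param densities Density thresholds (each in (0, 1]).
#' @param cp_in Cluster-property threshold shared by all runs.
#' @param min_report_size Passed to [cluster_params()].
#' @return An object of class `density_sweep`: a named list of
#'   `clustering_run`s (names `d0.1`, ...).
#' @export
density_sweep <- function(net, densities = seq(0.1, 0.9, by = 0.1),
                          cp_in = 0.5, min_report_size = 2) {
  if (length(densities) == 0) {
    abort("`densities` must be non-empty", class = "ppiclust_value_error")
  }
  runs <- lapply(densities, function(d) {
    dpcluso(net, cluster_params(d, cp_in, min_report_size))
  })
  names(runs) <- paste0("d", format(densities, trim = TRUE))
  structure(runs, class = "density_sweep")
}

#' Sweep summary in the shape of a per-density results table
#'
#' @param x A `density_sweep`.
#' @param ... Unused.
#' @return Tibble with one row per density threshold.
#' @method tidy density_sweep
#' @export
tidy.density_sweep <- function(x, ...) {
  bind_rows(lapply(unclass(x), glance))
}
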