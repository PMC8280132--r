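# Independent brute-force oracles used to cross-check the implementation.
# These are deliberately written from first principles (enumeration, BFS,
# rank statistics) and never call the code paths they verify.

# random undirected simple graph as an edge tibble
rand_graph <- function(n, p, seed, prefix = "N") {
  withr::with_seed(seed, {
    ids <- sprintf(paste0(prefix, "%03d"), seq_len(n))
    pairs <- t(utils::combn(n, 2))
    keep <- stats::runif(nrow(pairs)) < p
    tibble::tibble(a = ids[pairs[keep, 1]], b = ids[pairs[keep, 2]],
                   score = 1)
  })
}

# hypergeometric upper tail by direct enumeration of the mass function
bf_hyper_tail <- function(k, K, n, N) {
  i <- seq(max(k, 0), min(K, n))
  if (length(i) == 0) return(0)
  sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
}

# Benjamini-Hochberg step-up, coded independently of stats::p.adjust
bf_bh <- function(p) {
  m <- length(p)
  ord <- order(p, decreasing = TRUE)
  adj <- numeric(m)
  running <- Inf
  for (r in seq_along(ord)) {
    i <- ord[r]
    rank_i <- m - r + 1
    running <- min(running, p[i] * m / rank_i)
    adj[i] <- min(running, 1)
  }
  adj
}

# tie-corrected Mann-Whitney AUC via mid-ranks
bf_auc <- function(scores, labels) {
  r <- rank(scores)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# all-pairs BFS on an edge tibble; returns list(dist matrix, nodes)
bf_distances <- function(edges, nodes) {
  adj <- lapply(stats::setNames(nodes, nodes), function(v) {
    c(edges$b[edges$a == v], edges$a[edges$b == v])
  })
  d <- matrix(Inf, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  for (s in nodes) {
    d[s, s] <- 0
    frontier <- s
    k <- 0
    while (length(frontier) > 0) {
      k <- k + 1
      nxt <- unique(unlist(adj[frontier], use.names = FALSE))
      nxt <- nxt[is.infinite(d[s, nxt])]
      d[s, nxt] <- k
      frontier <- nxt
    }
  }
  d
}

# local clustering coefficient of one node from first principles
bf_local_cc <- function(edges, v) {
  nb <- unique(c(edges$b[edges$a == v], edges$a[edges$b == v]))
  k <- length(nb)
  if (k < 2) return(0)
  links <- sum((edges$a %in% nb) & (edges$b %in% nb))
  2 * links / (k * (k - 1))
}

# enzymes on simple paths of length <= max_len from a metabolite
bf_enzymes <- function(gedges, start, max_len) {
  hit <- character(0)
  walk <- function(node, visited, depth) {
    if (depth == max_len) return()
    inc <- which(gedges$compound_a == node | gedges$compound_b == node)
    for (e in inc) {
      other <- ifelse(gedges$compound_a[e] == node,
                      gedges$compound_b[e], gedges$compound_a[e])
      if (other %in% visited) next
      hit <<- c(hit, gedges$enzyme_label[e])
      walk(other, c(visited, other), depth + 1)
    }
  }
  walk(start, start, 0)
  sort(unique(hit))
}

# convenience: edge tibble -> disease_network including isolated nodes
edge_net <- function(edges, nodes = NULL) {
  as_disease_network(edges, nodes = nodes)
}

# induced subgraph connectivity check from first principles
bf_connected <- function(edges, members) {
  if (length(members) <= 1) return(TRUE)
  sub <- edges[edges$a %in% members & edges$b %in% members, ]
  seen <- members[1]
  repeat {
    nxt <- unique(c(sub$b[sub$a %in% seen], sub$a[sub$b %in% seen]))
    nxt <- setdiff(nxt, seen)
    if (length(nxt) == 0) break
    seen <- c(seen, nxt)
  }
  setequal(seen, members)
}

# small synthetic configuration for fast unit tests
small_config <- function(seed = 1, ...) {
  args <- utils::modifyList(list(
    n_proteins = 90, n_modules = 3, module_size_range = c(10, 10),
    overlap_nodes = 3, module_layout = "chain", p_in = 0.9, p_out = 0.02,
    disease_odds = 10, disease_baseline = 0.15, n_disease_modules = 2,
    n_pathways = 6, pathway_module_alignment = 2 / 6,
    pathway_noise_genes = 2, n_metabolites = 4,
    seed_background_fraction = 0.5, seed = seed), list(...))
  do.call(synth_config, args)
}

# complete graph on the given ids, as an edge tibble
k_clique <- function(ids) {
  p <- t(utils::combn(ids, 2))
  tibble::tibble(a = pmin(p[, 1], p[, 2]), b = pmax(p[, 1], p[, 2]), score = 1)
}

# random valid 2x2 contingency margins with overlap
rand_table <- function(seed) {
  withr::with_seed(seed, {
    N <- sample(10:60, 1)
    K <- sample(0:N, 1)
    n <- sample(1:N, 1)
    k <- sample(max(0, K + n - N):min(K, n), 1)
    list(k = k, K = K, n = n, N = N)
  })
}
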