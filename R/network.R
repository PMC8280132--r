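#' Load a scored interaction table
#'
#' Three columns: protein `a`, protein `b`, `score` in \[0, 1\].  Pairs are
#' canonicalized (`a < b`); self-interactions are dropped; duplicate
#' unordered pairs keep the maximum score.
#'
#' @param path Path to a tab-separated interaction file.
#' @return Tibble (`a`, `b`, `score`).
#' @export
load_interactions <- function(path) {
  raw <- read_flat_tsv(path, readr::cols(
    .default = readr::col_character()))
  names(raw)[1:3] <- c("a", "b", "score")
  score <- suppressWarnings(as.numeric(raw$score))
  bad <- which(is.na(score) | score < 0 | score > 1)
  if (length(bad) > 0) {
    abort(sprintf("malformed interaction score at data line %d: '%s'",
                  bad[1], raw$score[bad[1]]), class = "ppiclust_parse_error")
  }
  canonicalize_interactions(tibble(a = raw$a, b = raw$b, score = score))
}

canonicalize_interactions <- function(interactions) {
  if (nrow(interactions) == 0) {
    return(tibble(a = character(0), b = character(0), score = numeric(0)))
  }
  interactions |>
    filter(.data$a != .data$b) |>
    mutate(lo = pmin(.data$a, .data$b), hi = pmax(.data$a, .data$b)) |>
    group_by(.data$lo, .data$hi) |>
    summarise(score = max(.data$score), .groups = "drop") |>
    select(a = "lo", b = "hi", score = "score") |>
    arrange(.data$a, .data$b)
}

#' Build the disease-relevant PPI network
#'
#' Edge retention rule: an interaction between proteins a and b is kept when
#' both endpoints are in the seed set S (regardless of score), or when
#' exactly one endpoint is in S and the score is strictly greater than
#' `threshold`.  Interactions with both endpoints outside S are always
#' dropped.  The network's node set is the union of endpoints of retained
#' edges, so seed proteins without any retained interaction are absent.
#'
#' @param interactions Tibble (`a`, `b`, `score`) of scored interactions.
#' @param seeds A `seed_sets` object (or list with `scz`, `bd`, `all`).
#' @param threshold Score threshold for edges leaving the seed set.
#' @return An object of class `disease_network`: list with `edges` (tibble
#'   `a`, `b`, `score`), `nodes` (tibble `protein`, `in_scz`, `in_bd`,
#'   `in_seed`) and `threshold`.
#' @export
build_network <- function(interactions, seeds, threshold = 0.7) {
  stopifnot(threshold >= 0, threshold <= 1)
  if (length(seeds$all) == 0) {
    abort("seed set is empty; cannot build a disease network",
          class = "ppiclust_value_error")
  }
  interactions <- canonicalize_interactions(as_tibble(interactions))
  a_in <- interactions$a %in% seeds$all
  b_in <- interactions$b %in% seeds$all
  keep <- (a_in & b_in) |
    (xor(a_in, b_in) & interactions$score > threshold)
  edges <- interactions[keep, ]
  nodes <- sort(unique(c(edges$a, edges$b)))
  structure(list(
    edges = edges,
    nodes = tibble(
      protein = nodes,
      in_scz = as.integer(nodes %in% seeds$scz),
      in_bd = as.integer(nodes %in% seeds$bd),
      in_seed = as.integer(nodes %in% seeds$all)
    ),
    threshold = threshold
  ), class = "disease_network")
}

#' @export
print.disease_network <- function(x, ...) {
  cat(sprintf("<disease_network> %d nodes, %d edges (seed-leaving score > %g)\n",
              nrow(x$nodes), nrow(x$edges), x$threshold))
  invisible(x)
}

network_igraph <- function(net) {
  igraph::graph_from_data_frame(net$edges[, c("a", "b")], directed = FALSE,
                                vertices = net$nodes$protein)
}

#' Global topology statistics of a disease network
#'
#' Clustering coefficient is the mean local clustering over all nodes, with
#' degree-0/1 nodes contributing 0.  Characteristic path length and diameter
#' are computed on the largest connected component.  The power-law slope is
#' the descriptive least-squares slope of log10(count) on log10(degree) over
#' degrees with nonzero count.
#'
#' @param net A `disease_network`.
#' @return A list of class `topology_stats`: `n_nodes`, `n_edges`,
#'   `clustering_coefficient`, `characteristic_path_length`, `diameter`,
#'   `degree_histogram` (tibble `degree`, `count`), `powerlaw_slope`.
#' @export
topology_stats <- function(net) {
  if (nrow(net$nodes) == 0) {
    abort("cannot compute topology statistics of an empty network",
          class = "ppiclust_value_error")
  }
  g <- network_igraph(net)
  local_cc <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  local_cc[is.na(local_cc)] <- 0  # degree-1 nodes
  comp <- igraph::components(g)
  giant <- which(comp$membership == which.max(comp$csize))
  if (length(giant) >= 2) {
    d <- igraph::distances(g, v = giant, to = giant)
    finite <- d[upper.tri(d)]
    cpl <- mean(finite)
    diam <- max(finite)
  } else {
    cpl <- 0
    diam <- 0
  }
  deg <- igraph::degree(g)
  hist <- as_tibble(as.data.frame(table(degree = deg), stringsAsFactors = FALSE)) |>
    mutate(degree = as.integer(as.character(.data$degree))) |>
    rename(count = "Freq")
  pos <- hist |> filter(.data$degree > 0)
  slope <- if (nrow(pos) >= 2) {
    unname(stats::coef(stats::lm(log10(pos$count) ~ log10(pos$degree)))[2])
  } else {
    NA_real_
  }
  structure(list(
    n_nodes = nrow(net$nodes),
    n_edges = nrow(net$edges),
    clustering_coefficient = mean(local_cc),
    characteristic_path_length = cpl,
    diameter = as.integer(diam),
    degree_histogram = hist,
    powerlaw_slope = slope
  ), class = "topology_stats")
}

#' @export
print.topology_stats <- function(x, ...) {
  cat(sprintf(paste0(
    "<topology_stats> %d nodes, %d edges\n",
    "  clustering coefficient: %.4f\n",
    "  characteristic path length: %.4f\n",
    "  diameter: %d\n",
    "  log-log degree slope: %.3f\n"),
    x$n_nodes, x$n_edges, x$clustering_coefficient,
    x$characteristic_path_length, x$diameter, x$powerlaw_slope))
  invisible(x)
}

#' @rdname topology_stats
#' @param x A `topology_stats` object.
#' @param ... Unused.
#' @method glance topology_stats
#' @export
glance.topology_stats <- function(x, ...) {
  tibble(n_nodes = x$n_nodes, n_edges = x$n_edges,
         clustering_coefficient = x$clustering_coefficient,
         characteristic_path_length = x$characteristic_path_length,
         diameter = x$diameter, powerlaw_slope = x$powerlaw_slope)
}

#' Per-disease edge counts of a disease network
#'
#' An edge is attributed to a disease when both endpoints are in that
#' disease's seed set, or when it is a score-admitted edge whose seed-side
#' endpoint is in that disease's seed set.  Edges attributed to both
#' diseases are the "common" count.  This is one reasonable reading of
#' per-disease interaction counts; it is reported descriptively.
#'
#' @param net A `disease_network`.
#' @return Tibble with `n_scz`, `n_bd`, `n_common`, `n_total`.
#' @export
edge_disease_counts <- function(net) {
  flags <- net$nodes
  a <- match(net$edges$a, flags$protein)
  b <- match(net$edges$b, flags$protein)
  in_d <- function(col) {
    fa <- flags[[col]][a] == 1; fb <- flags[[col]][b] == 1
    sa <- flags$in_seed[a] == 1; sb <- flags$in_seed[b] == 1
    (fa & fb) | (fa & !sb) | (fb & !sa)
  }
  scz <- in_d("in_scz"); bd <- in_d("in_bd")
  tibble(n_scz = sum(scz), n_bd = sum(bd),
         n_common = sum(scz & bd), n_total = nrow(net$edges))
}

#' Degree-distribution plot of a disease network
#'
#' @param object A `disease_network`.
#' @param ... Unused.
#' @return A ggplot: log-log degree distribution.
#' @method autoplot disease_network
#' @export
autoplot.disease_network <- function(object, ...) {
  hist <- topology_stats(object)$degree_histogram |>
    filter(.data$degree > 0)
  ggplot2::ggplot(hist, ggplot2::aes(x = .data$degree, y = .data$count)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "degree", y = "number of nodes",
                  title = "Degree distribution") +
    ggplot2::theme_minimal()
}

#' Build a `disease_network` directly from an edge table
#'
#' Convenience constructor for analyses that start from an already-filtered
#' edge list (all nodes flagged as seed members).
#'
#' @param edges Data frame with columns `a`, `b` and optionally `score`.
#' @param nodes Optional character vector of node ids (to include isolated
#'   nodes); defaults to the endpoints of `edges`.
#' @return A `disease_network`.
#' @export
as_disease_network <- function(edges, nodes = NULL) {
  edges <- as_tibble(edges)
  if (!"score" %in% names(edges)) edges$score <- 1
  edges <- canonicalize_interactions(edges)
  nodes <- sort(unique(c(edges$a, edges$b, nodes)))
  structure(list(
    edges = edges,
    nodes = tibble(protein = nodes, in_scz = 1L, in_bd = 1L, in_seed = 1L),
    threshold = NA_real_
  ), class = "disease_network")
}
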