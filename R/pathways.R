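#' Top-k enriched pathways of one cluster
#'
#' Orders retained enrichments by EASE score ascending, overlap count
#' descending, then pathway id, and keeps the first `k` (all of them when
#' fewer pass).
#'
#' @param enrichments Tibble from [enrich_pathways()] for one cluster.
#' @param k Number of pathways to keep (>= 1).
#' @return The top-k rows.
#' @export
top_k_pathways <- function(enrichments, k = 3) {
  if (k < 1) abort("`k` must be >= 1", class = "ppiclust_value_error")
  enrichments |>
    arrange(.data$ease_p, desc(.data$count), .data$pathway) |>
    head(k)
}

#' Bipartite graph of significant clusters and their top pathways
#'
#' One edge per (cluster, pathway) membership in that cluster's top-k list;
#' pathway degree is the number of distinct significant clusters whose
#' top-k lists contain the pathway.
#'
#' @param per_cluster_topk Tibble with columns `cluster_id`, `pathway` (one
#'   row per top-k membership; other columns ignored).
#' @return An object of class `bipartite_pathways`: list with `edges`
#'   (tibble `cluster_id`, `pathway`) and `degrees` (tibble `pathway`,
#'   `degree`).
#' @export
build_bipartite <- function(per_cluster_topk) {
  edges <- as_tibble(per_cluster_topk) |>
    distinct(.data$cluster_id, .data$pathway) |>
    arrange(.data$cluster_id, .data$pathway)
  degrees <- edges |>
    dplyr::count(.data$pathway, name = "degree") |>
    arrange(desc(.data$degree), .data$pathway)
  structure(list(edges = edges, degrees = degrees),
            class = "bipartite_pathways")
}

#' @export
print.bipartite_pathways <- function(x, ...) {
  cat(sprintf(
    "<bipartite_pathways> %d clusters, %d pathways, %d edges\n",
    dplyr::n_distinct(x$edges$cluster_id),
    dplyr::n_distinct(x$edges$pathway), nrow(x$edges)))
  invisible(x)
}

#' @rdname build_bipartite
#' @param x A `bipartite_pathways` object.
#' @param ... Unused.
#' @method tidy bipartite_pathways
#' @export
tidy.bipartite_pathways <- function(x, ...) x$edges

#' Select high-degree pathways from the bipartite graph
#'
#' Pathways linked to at least `min_degree` significant clusters, ranked by
#' degree descending then pathway id.
#'
#' @param bg A `bipartite_pathways` object.
#' @param min_degree Minimum bipartite degree.
#' @return Tibble (`pathway`, `degree`, `selected`) over all pathways in
#'   the graph, ranked; `selected` is 1 for pathways meeting `min_degree`.
#' @export
select_pathways <- function(bg, min_degree = 3) {
  stopifnot(inherits(bg, "bipartite_pathways"))
  bg$degrees |>
    mutate(selected = as.integer(.data$degree >= min_degree)) |>
    arrange(desc(.data$degree), .data$pathway)
}

#' Pathway-degree bar plot
#'
#' @param object A `bipartite_pathways` object.
#' @param min_degree Selection cutoff drawn as a reference line.
#' @param ... Unused.
#' @return A ggplot of pathway bipartite degrees.
#' @method autoplot bipartite_pathways
#' @export
autoplot.bipartite_pathways <- function(object, min_degree = 3, ...) {
  d <- object$degrees |>
    mutate(pathway = factor(.data$pathway, levels = rev(.data$pathway)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$degree, y = .data$pathway)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = min_degree - 0.5, linetype = "dashed") +
    ggplot2::labs(x = "bipartite degree (number of significant clusters)",
                  y = NULL, title = "Cluster support per pathway") +
    ggplot2::theme_minimal()
}
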