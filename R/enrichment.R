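#' One-sided Fisher's exact (hypergeometric tail) enrichment p-value
#'
#' Probability of drawing at least `k` annotated items when `n` items are
#' drawn without replacement from a background of `N` items of which `K`
#' are annotated: `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`.  This is
#' the one-sided enrichment version of Fisher's exact test on the 2x2
#' table, computed exactly.
#'
#' @param k Overlap count.
#' @param K Annotated-set size in the background.
#' @param n Query-set size.
#' @param N Background size.
#' @return The exact tail probability.
#' @export
#' @examples
#' fisher_greater(k = 5, K = 40, n = 10, N = 200)
fisher_greater <- function(k, K, n, N) {
  check_counts(k, K, n, N)
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

check_counts <- function(k, K, n, N) {
  ok <- is.finite(k) & is.finite(K) & is.finite(n) & is.finite(N) &
    k >= 0 & K >= 0 & n >= 0 & K <= N & n <= N & k <= pmin(K, n)
  if (!all(ok)) {
    abort(sprintf(
      "inconsistent contingency counts: k=%s K=%s n=%s N=%s",
      toString(k[!ok][1]), toString(K[!ok][1]), toString(n[!ok][1]),
      toString(N[!ok][1])), class = "ppiclust_value_error")
  }
  invisible(TRUE)
}

#' EASE score: jackknifed one-sided Fisher p-value
#'
#' The conservative enrichment score used by annotation tools: one gene is
#' removed from the overlap before the Fisher tail is computed, i.e.
#' `fisher_greater(max(k - 1, 0), K, n, N)`.  A single-gene overlap can
#' therefore never be significant (its EASE score is 1).
#'
#' @inheritParams fisher_greater
#' @return The EASE p-value (always >= the plain Fisher p-value).
#' @export
ease_p <- function(k, K, n, N) {
  check_counts(k, K, n, N)
  fisher_greater(pmax(k - 1, 0), K, n, N)
}

check_pvalues <- function(p) {
  if (length(p) == 0) return(invisible(TRUE))
  if (any(!is.finite(p) | p < 0 | p > 1)) {
    abort("p-values must lie in [0, 1]", class = "ppiclust_value_error")
  }
  invisible(TRUE)
}

#' Bonferroni correction
#'
#' `min(1, p * m)` with `m` the family size.
#'
#' @param p Vector of p-values in \[0, 1\].
#' @return Adjusted p-values in input order.
#' @export
bonferroni <- function(p) {
  check_pvalues(p)
  p.adjust(p, method = "bonferroni")
}

#' Benjamini-Hochberg step-up false discovery rate
#'
#' Step-up adjusted values: with p-values sorted ascending,
#' `q_(i) = min over j >= i of min(1, p_(j) * m / j)`, returned in input
#' order.
#'
#' @param p Vector of p-values in \[0, 1\].
#' @return BH-adjusted values (FDR) in input order.
#' @export
bh_fdr <- function(p) {
  check_pvalues(p)
  p.adjust(p, method = "BH")
}

#' Disease-gene enrichment of every cluster in a run
#'
#' For each cluster of size >= `min_report_size`, the 2x2 overlap of the
#' cluster with the disease protein set against the network background is
#' scored with the one-sided Fisher test; Bonferroni and Benjamini-Hochberg
#' corrections are applied across that run's clusters as one family.  A
#' cluster is significant when its FDR is below `fdr_cutoff`.
#'
#' @param run A `clustering_run`.
#' @param disease_set Character vector of disease protein ids (subset of
#'   `background`).
#' @param background Character vector: the enrichment universe (must contain
#'   every cluster's nodes; normally the network's node set).
#' @param fdr_cutoff Significance cutoff on the BH FDR.
#' @return Tibble (`cluster_id`, `size`, `k`, `p`, `p_bonferroni`, `fdr`,
#'   `significant`), one row per size->=`min_report_size` cluster.
#' @export
score_clusters <- function(run, disease_set, background, fdr_cutoff = 0.05) {
  stopifnot(inherits(run, "clustering_run"))
  background <- unique(background)
  disease_set <- unique(disease_set)
  all_nodes <- unique(unlist(run$clusters$nodes))
  if (!all(all_nodes %in% background)) {
    abort("background must contain every cluster node",
          class = "ppiclust_value_error")
  }
  if (!all(disease_set %in% background)) {
    abort("disease_set must be a subset of background",
          class = "ppiclust_value_error")
  }
  cl <- run$clusters |> filter(.data$size >= run$params$min_report_size)
  N <- length(background)
  K <- length(disease_set)
  k <- vapply(cl$nodes, function(nd) sum(nd %in% disease_set), numeric(1))
  p <- fisher_greater(k, K, cl$size, N)
  tibble(
    cluster_id = cl$cluster_id,
    size = cl$size,
    k = as.integer(k),
    p = p,
    p_bonferroni = bonferroni(p),
    fdr = bh_fdr(p),
    significant = bh_fdr(p) < fdr_cutoff
  )
}

#' Pathway enrichment of one cluster against GMT gene sets
#'
#' For every pathway: `count` is the overlap with the cluster, the EASE
#' score is the jackknifed Fisher tail, and BH FDR is computed across the
#' pathways tested for this cluster.  A pathway is retained when
#' `count >= count_min`, `ease_p <= ease_max` and `fdr <= fdr_max`
#' (annotation-tool default thresholds).  The background defaults to the
#' union of all pathway genes and the supplied universe.
#'
#' @param cluster Character vector of cluster member ids.
#' @param pathways Named list of gene sets (see [read_gmt()]).
#' @param background Character vector: enrichment universe (must contain the
#'   cluster's nodes; pathway genes are added to it).
#' @param count_min,ease_max,fdr_max Retention thresholds.
#' @return Tibble (`pathway`, `count`, `ease_p`, `fdr`) of retained
#'   pathways, sorted by EASE score ascending (empty when none pass).
#' @export
enrich_pathways <- function(cluster, pathways, background,
                            count_min = 2, ease_max = 0.1, fdr_max = 0.05) {
  if (length(pathways) == 0) {
    abort("`pathways` must be a non-empty gene-set list",
          class = "ppiclust_value_error")
  }
  if (!all(cluster %in% background)) {
    abort("background must contain every cluster node",
          class = "ppiclust_value_error")
  }
  universe <- unique(c(background, unlist(pathways)))
  N <- length(universe)
  n <- length(unique(cluster))
  res <- tibble(
    pathway = names(pathways),
    count = vapply(pathways, function(g) length(intersect(cluster, g)), numeric(1)),
    K = lengths(lapply(pathways, unique))
  ) |>
    mutate(ease_p = ease_p(.data$count, .data$K, n, N),
           fdr = bh_fdr(.data$ease_p)) |>
    filter(.data$count >= count_min, .data$ease_p <= ease_max,
           .data$fdr <= fdr_max) |>
    arrange(.data$ease_p, desc(.data$count), .data$pathway) |>
    mutate(count = as.integer(.data$count)) |>
    select("pathway", "count", "ease_p", "fdr")
  res
}
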