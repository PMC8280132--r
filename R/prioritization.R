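#' Assign significance scores to proteins from cluster FDRs
#'
#' Each protein's SScore is `-log10(FDR)` of the most significant cluster
#' containing it (overlapping clustering can place a protein in several
#' clusters; only the highest score is kept).  FDR values are floored at
#' `fdr_floor` before the log to avoid infinities; proteins found only in
#' singleton clusters (which are not tested) receive SScore 0.
#'
#' @param run A `clustering_run`.
#' @param significance Output of [score_clusters()] for `run`.
#' @param fdr_floor Lower bound applied to FDR values before `-log10`.
#' @return Tibble (`protein`, `sscore`, `best_cluster`), all network
#'   proteins, sorted by protein id.
#' @export
assign_sscores <- function(run, significance, fdr_floor = 1e-16) {
  stopifnot(inherits(run, "clustering_run"))
  membership <- tidy(run)
  scored <- membership |>
    left_join(significance |> select("cluster_id", "fdr"), by = "cluster_id") |>
    mutate(sscore = ifelse(is.na(.data$fdr), 0,
                           -log10(pmax(.data$fdr, fdr_floor))))
  out <- scored |>
    rename(protein = "node") |>
    group_by(.data$protein) |>
    arrange(desc(.data$sscore), .data$cluster_id, .by_group = TRUE) |>
    summarise(sscore = .data$sscore[1],
              best_cluster = .data$cluster_id[1], .groups = "drop") |>
    arrange(.data$protein)
  if (nrow(out) != run$n_nodes) {
    abort("internal consistency error: some network node is in no cluster",
          class = "ppiclust_internal_error")
  }
  out
}

#' True-positive labels for ROC evaluation
#'
#' A network protein is labelled positive when it belongs to the reference
#' disease-gene set or to the biomarker-derived seed set; evaluation is
#' restricted to network nodes (reference genes outside the network are not
#' counted as missed positives; their number is reported as an attribute).
#'
#' @param network_nodes Character vector of network protein ids.
#' @param reference_genes Character vector: reference disease genes.
#' @param seed_set Character vector: biomarker-derived seed proteins.
#' @return Tibble (`protein`, `label`), with attribute
#'   `n_reference_outside_network`.
#' @export
truth_labels <- function(network_nodes, reference_genes, seed_set = character(0)) {
  network_nodes <- sort(unique(network_nodes))
  positive <- union(reference_genes, seed_set)
  out <- tibble(protein = network_nodes,
                label = as.integer(network_nodes %in% positive))
  attr(out, "n_reference_outside_network") <-
    length(setdiff(reference_genes, network_nodes))
  out
}

#' ROC curve and AUC of a protein score table
#'
#' Thresholds are the distinct scores in descending order plus a sentinel
#' above the maximum; at each threshold every protein with score >= the
#' threshold is called positive, so tied scores enter together.  AUC is the
#' area under the (FPR, TPR) polyline by trapezoidal integration, which
#' equals the tie-corrected Mann-Whitney probability.
#'
#' @param scores Tibble (`protein`, `sscore`) as from [assign_sscores()].
#' @param labels Tibble (`protein`, `label`) as from [truth_labels()].
#' @return An object of class `roc_result`: list with `curve` (tibble
#'   `threshold`, `tpr`, `fpr`), `auc`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels) {
  d <- dplyr::inner_join(as_tibble(scores), as_tibble(labels), by = "protein")
  n_pos <- sum(d$label == 1)
  n_neg <- sum(d$label == 0)
  if (n_pos == 0 || n_neg == 0) {
    abort("ROC undefined: need at least one positive and one negative label",
          class = "ppiclust_value_error")
  }
  thr <- sort(unique(d$sscore), decreasing = TRUE)
  sentinel <- if (thr[1] <= 0) 1 else thr[1] * 2
  thr <- c(sentinel, thr)
  ord <- order(-d$sscore)
  s_sorted <- d$sscore[ord]
  l_sorted <- d$label[ord]
  cum_tp <- cumsum(l_sorted == 1)
  cum_fp <- cumsum(l_sorted == 0)
  # index of the last protein admitted at each threshold
  n_at <- c(0, vapply(thr[-1], function(t) sum(s_sorted >= t), numeric(1)))
  tpr <- c(0, cum_tp[n_at[-1]])[seq_along(n_at)] / n_pos
  fpr <- c(0, cum_fp[n_at[-1]])[seq_along(n_at)] / n_neg
  tpr[1] <- 0; fpr[1] <- 0
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(
    curve = tibble(threshold = thr, tpr = tpr, fpr = fpr),
    auc = auc, n_pos = n_pos, n_neg = n_neg
  ), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.4f (%d positives, %d negatives)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' @rdname roc_auc
#' @param x A `roc_result`.
#' @param ... Unused.
#' @method tidy roc_result
#' @export
tidy.roc_result <- function(x, ...) x$curve

#' @rdname roc_auc
#' @method glance roc_result
#' @export
glance.roc_result <- function(x, ...) {
  tibble(auc = x$auc, n_pos = x$n_pos, n_neg = x$n_neg)
}

#' ROC curve plot
#'
#' @param object A `roc_result`.
#' @param ... Unused.
#' @return A ggplot of the ROC curve.
#' @method autoplot roc_result
#' @export
autoplot.roc_result <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("ROC (AUC = %.3f)", object$auc)) +
    ggplot2::theme_minimal()
}

#' Select the clustering density with the best AUC
#'
#' @param auc_table Tibble (`density`, `auc`), one row per density.
#' @return The density with maximal AUC; ties go to the smaller density.
#' @export
select_density <- function(auc_table) {
  stopifnot(nrow(auc_table) > 0)
  best <- auc_table |>
    arrange(desc(.data$auc), .data$density) |>
    slice(1)
  best$density
}
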