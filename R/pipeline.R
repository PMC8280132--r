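#' Load a disease-gene reference list
#'
#' One protein/gene id per line; lines starting with `#` are comments.
#'
#' @param path File path.
#' @return Character vector of unique ids.
#' @export
load_disease_genes <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "ppiclust_io_error")
  }
  x <- trimws(readLines(path))
  sort(unique(x[x != "" & !startsWith(x, "#")]))
}

#' Pipeline configuration
#'
#' Assembles and validates every tunable of the end-to-end run.  Inputs are
#' either the six flat files (`paths`) or a [synth_config()] (`synth`), in
#' which case the inputs are generated on the fly with known ground truth.
#'
#' @param paths Named list of input paths (`biomarkers`, `associations`,
#'   `metabolic_graph`, `interactions`, `disease_genes`, `pathways`).
#'   `metabolic_graph` may be NULL for association-only mapping.
#' @param synth A `synth_config`, as an alternative to `paths`.
#' @param score_threshold Score cutoff for interactions leaving the seed set.
#' @param densities Density thresholds for the clustering sweep.
#' @param cp_in Cluster-property threshold.
#' @param min_report_size Minimum cluster size entering enrichment.
#' @param fdr_cutoff Cluster-significance FDR cutoff.
#' @param count_min,ease_max,fdr_max Pathway-enrichment retention thresholds.
#' @param top_k Pathways kept per significant cluster.
#' @param min_degree Bipartite-degree cutoff for final pathway selection.
#' @param max_len Path-length bound of the enzyme extraction.
#' @param fdr_floor FDR floor before `-log10` in the SScore.
#' @param roc_truth `"reference"` (default) labels ROC positives by the
#'   reference disease-gene set alone; `"reference_and_seeds"` adds the
#'   biomarker-derived seed proteins.  The default excludes seeds because
#'   the seed set also defines the network: when most network nodes are
#'   seeds, seed-based labels leave no negative class.
#' @param seed Integer seed (used only to generate synthetic inputs).
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(paths = NULL, synth = NULL,
                            score_threshold = 0.7,
                            densities = seq(0.1, 0.9, by = 0.1),
                            cp_in = 0.5, min_report_size = 2,
                            fdr_cutoff = 0.05,
                            count_min = 2, ease_max = 0.1, fdr_max = 0.05,
                            top_k = 3, min_degree = 3,
                            max_len = 2, fdr_floor = 1e-16,
                            roc_truth = c("reference", "reference_and_seeds"),
                            seed = 1L) {
  roc_truth <- match.arg(roc_truth)
  if (is.null(paths) == is.null(synth)) {
    abort("provide exactly one of `paths` or `synth`",
          class = "ppiclust_config_error")
  }
  if (!is.null(synth)) stopifnot(inherits(synth, "synth_config"))
  if (is.null(densities) || length(densities) == 0 ||
      any(densities <= 0 | densities > 1)) {
    abort("`densities` must be in (0, 1]", class = "ppiclust_config_error")
  }
  densities <- sort(unique(densities))
  for (f in c("score_threshold", "fdr_cutoff", "ease_max", "fdr_max")) {
    v <- get(f)
    if (!is.numeric(v) || v < 0 || v > 1) {
      abort(paste0("`", f, "` must be in [0, 1]"), class = "ppiclust_config_error")
    }
  }
  stopifnot(top_k >= 1, min_degree >= 1, count_min >= 0, max_len >= 1)
  structure(list(
    paths = paths, synth = synth, score_threshold = score_threshold,
    densities = densities, cp_in = cp_in, min_report_size = min_report_size,
    fdr_cutoff = fdr_cutoff, count_min = count_min, ease_max = ease_max,
    fdr_max = fdr_max, top_k = top_k, min_degree = min_degree,
    max_len = max_len, fdr_floor = fdr_floor, roc_truth = roc_truth,
    seed = as.integer(seed)
  ), class = "pipeline_config")
}

stage <- function(name, quiet, code) {
  if (!quiet) message(sprintf("[%s] ...", name))
  tryCatch(force(code), error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
          class = "ppiclust_stage_error", parent = e)
  })
}

#' Run the full biomarker-to-pathway pipeline
#'
#' Executes the five stages in order: (1) map biomarkers to protein seed
#' sets; (2) build the score-filtered disease PPI network and its topology
#' statistics; (3) cluster the network over the density sweep; (4) score
#' every clustering by disease-gene enrichment, assign protein SScores and
#' select the density with the best ROC AUC against the reference; (5) rank
#' pathways by bipartite degree over the significant clusters of the chosen
#' density.  All intermediate tables are written to `outdir` (if given)
#' with deterministic formatting, plus a machine-readable `report.json`.
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory (optional; created if missing).
#' @param quiet Suppress per-stage progress messages.
#' @return An object of class `pipeline_report` (list of stage results and
#'   summary counts).
#' @export
run_pipeline <- function(config, outdir = NULL, quiet = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(outdir) && !dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  emit <- function(x, file) {
    if (!is.null(outdir)) write_flat_tsv(x, file.path(outdir, file))
  }

  inputs <- stage("inputs", quiet, {
    if (!is.null(config$synth)) {
      syn <- synthesize_inputs(config$synth)
      list(
        biomarkers = syn$biomarkers |>
          mutate(metabolite = normalize_name(.data$metabolite)) |>
          mutate(scz = .data$disease_label %in% c("SCZ", "BOTH"),
                 bd = .data$disease_label %in% c("BD", "BOTH")),
        associations = syn$associations |>
          mutate(metabolite = normalize_name(.data$metabolite)),
        graph = if (nrow(syn$metabolic_graph) > 0)
          as_metabolic_graph(syn$metabolic_graph) else NULL,
        interactions = canonicalize_interactions(syn$interactions),
        disease_genes = sort(unique(syn$disease_genes$protein)),
        pathways = syn$pathways,
        truth = syn$truth
      )
    } else {
      p <- config$paths
      list(
        biomarkers = load_biomarkers(p$biomarkers),
        associations = load_associations(p$associations),
        graph = if (!is.null(p$metabolic_graph))
          load_metabolic_graph(p$metabolic_graph) else NULL,
        interactions = load_interactions(p$interactions),
        disease_genes = load_disease_genes(p$disease_genes),
        pathways = read_gmt(p$pathways),
        truth = NULL
      )
    }
  })

  seeds <- stage("mapping", quiet, {
    if (nrow(inputs$biomarkers) == 0) {
      abort("no biomarkers to map", class = "ppiclust_value_error")
    }
    build_seed_sets(inputs$biomarkers, inputs$associations, inputs$graph,
                    config$max_len)
  })
  emit(tidy(seeds), "seeds.tsv")

  net <- stage("network", quiet, {
    build_network(inputs$interactions, seeds, config$score_threshold)
  })
  topo <- stage("network", quiet, topology_stats(net))
  emit(net$edges, "network.tsv")
  if (!is.null(outdir)) {
    jsonlite::write_json(
      c(glance(topo), list(degree_histogram = topo$degree_histogram)),
      file.path(outdir, "topology.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "columns")
  }

  sweep <- stage("clustering", quiet, {
    density_sweep(net, config$densities, config$cp_in, config$min_report_size)
  })
  if (!is.null(outdir)) {
    for (nm in names(sweep)) {
      emit(tidy(sweep[[nm]])[, c("cluster_id", "node")],
           sprintf("clusters_%s.tsv", nm))
    }
  }

  network_nodes <- net$nodes$protein
  disease_in_net <- intersect(inputs$disease_genes, network_nodes)
  significances <- stage("significance", quiet, {
    lapply(sweep, score_clusters, disease_set = disease_in_net,
           background = network_nodes, fdr_cutoff = config$fdr_cutoff)
  })
  if (!is.null(outdir)) {
    sig_all <- bind_rows(significances, .id = "density_run")
    emit(sig_all, "cluster_significance.tsv")
  }

  roc_stage <- stage("roc", quiet, {
    seed_for_truth <- if (config$roc_truth == "reference_and_seeds") {
      seeds$all
    } else {
      character(0)
    }
    labels <- truth_labels(network_nodes, inputs$disease_genes, seed_for_truth)
    rocs <- list(); sscores <- list()
    for (nm in names(sweep)) {
      ss <- assign_sscores(sweep[[nm]], significances[[nm]], config$fdr_floor)
      sscores[[nm]] <- ss
      rocs[[nm]] <- roc_auc(ss, labels)
    }
    auc_table <- tibble(
      density = config$densities,
      auc = vapply(rocs, function(r) r$auc, numeric(1)),
      n_pos = vapply(rocs, function(r) r$n_pos, numeric(1)),
      n_neg = vapply(rocs, function(r) r$n_neg, numeric(1)))
    list(labels = labels, sscores = sscores, rocs = rocs,
         auc_table = auc_table, chosen = select_density(auc_table))
  })
  if (!is.null(outdir)) {
    for (nm in names(sweep)) {
      emit(roc_stage$sscores[[nm]], sprintf("sscores_%s.tsv", nm))
      emit(tidy(roc_stage$rocs[[nm]]), sprintf("roc_%s.tsv", nm))
    }
    emit(roc_stage$auc_table, "auc_summary.tsv")
  }

  pathways_stage <- stage("pathways", quiet, {
    chosen_nm <- names(sweep)[match(roc_stage$chosen, config$densities)]
    run <- sweep[[chosen_nm]]
    sig <- significances[[chosen_nm]] |> filter(.data$significant)
    bg_univ <- union(network_nodes, unlist(inputs$pathways))
    topk <- lapply(sig$cluster_id, function(cid) {
      nodes <- run$clusters$nodes[[match(cid, run$clusters$cluster_id)]]
      enr <- enrich_pathways(nodes, inputs$pathways, bg_univ,
                             config$count_min, config$ease_max, config$fdr_max)
      if (nrow(enr) > 0) {
        top_k_pathways(enr, config$top_k) |> mutate(cluster_id = cid)
      } else {
        NULL
      }
    })
    topk <- bind_rows(topk)
    bp <- build_bipartite(if (nrow(topk) > 0) topk else
      tibble(cluster_id = integer(0), pathway = character(0)))
    list(chosen_run = run, significant = sig, topk = topk, bipartite = bp,
         ranking = select_pathways(bp, config$min_degree))
  })
  if (!is.null(outdir)) {
    emit(pathways_stage$topk %||% tibble(), "pathway_enrichment.tsv")
    emit(tidy(pathways_stage$bipartite), "bipartite_edges.tsv")
    emit(pathways_stage$ranking, "pathway_ranking.tsv")
  }

  sweep_summary <- summarize_sweep(sweep, significances)
  if (!is.null(outdir)) emit(sweep_summary, "summary.tsv")

  report <- structure(list(
    config = config,
    n_biomarkers = nrow(inputs$biomarkers),
    seeds = seeds,
    n_seed_scz = length(seeds$scz), n_seed_bd = length(seeds$bd),
    n_seed_common = length(seeds$common), n_seed_total = length(seeds$all),
    network = net, topology = topo,
    edge_counts = edge_disease_counts(net),
    sweep = sweep, sweep_summary = sweep_summary,
    significances = significances,
    auc_table = roc_stage$auc_table,
    chosen_density = roc_stage$chosen,
    sscores = roc_stage$sscores,
    rocs = roc_stage$rocs,
    n_significant = sum(vapply(significances, function(s) sum(s$significant),
                               numeric(1))[
      match(roc_stage$chosen, config$densities)]),
    pathway_topk = pathways_stage$topk,
    bipartite = pathways_stage$bipartite,
    pathway_ranking = pathways_stage$ranking,
    truth = inputs$truth,
    version = as.character(utils::packageVersion("ppiclust"))
  ), class = "pipeline_report")

  if (!is.null(outdir)) {
    jsonlite::write_json(report_json(report), file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "columns")
  }
  report
}

report_json <- function(report) {
  list(
    version = report$version,
    n_biomarkers = report$n_biomarkers,
    seed_counts = list(scz = report$n_seed_scz, bd = report$n_seed_bd,
                       common = report$n_seed_common,
                       total = report$n_seed_total),
    network = list(n_nodes = report$topology$n_nodes,
                   n_edges = report$topology$n_edges,
                   clustering_coefficient = report$topology$clustering_coefficient,
                   characteristic_path_length = report$topology$characteristic_path_length,
                   diameter = report$topology$diameter),
    edge_counts = report$edge_counts,
    sweep_summary = report$sweep_summary,
    auc = report$auc_table[, c("density", "auc")],
    chosen_density = report$chosen_density,
    n_significant_clusters = report$n_significant,
    selected_pathways = report$pathway_ranking |> filter(.data$selected == 1)
  )
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat(sprintf("  biomarkers: %d; seeds: %d SCZ / %d BD / %d common / %d total\n",
              x$n_biomarkers, x$n_seed_scz, x$n_seed_bd, x$n_seed_common,
              x$n_seed_total))
  cat(sprintf("  network: %d nodes, %d edges\n",
              x$topology$n_nodes, x$topology$n_edges))
  cat(sprintf("  chosen density: %g (AUC %.4f); significant clusters: %d\n",
              x$chosen_density,
              x$auc_table$auc[match(x$chosen_density, x$auc_table$density)],
              x$n_significant))
  cat(sprintf("  selected pathways (degree >= %d): %d\n",
              x$config$min_degree, sum(x$pathway_ranking$selected)))
  invisible(x)
}

#' Per-density sweep summary with significant-cluster counts
#'
#' One row per density threshold: total clusters, maximum and average
#' cluster size (over all clusters and over size->=2 clusters), and the
#' number of significant clusters.
#'
#' @param sweep A `density_sweep`.
#' @param significances List of [score_clusters()] outputs parallel to
#'   `sweep`.
#' @return A tibble shaped like a per-density clustering results table.
#' @export
summarize_sweep <- function(sweep, significances) {
  out <- tidy(sweep)
  out$significant_clusters <- unname(vapply(
    significances, function(s) sum(s$significant), numeric(1)))
  out
}

#' AUC-versus-density plot
#'
#' @param report A `pipeline_report`.
#' @return A ggplot of AUC against clustering density threshold.
#' @export
plot_auc_by_density <- function(report) {
  ggplot2::ggplot(report$auc_table,
                  ggplot2::aes(x = .data$density, y = .data$auc)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_point(data = report$auc_table |>
                          filter(.data$density == report$chosen_density),
                        colour = "red", size = 3) +
    ggplot2::labs(x = "clustering density threshold", y = "AUC",
                  title = "Density selection by ROC AUC") +
    ggplot2::theme_minimal()
}
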