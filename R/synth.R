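#' Configuration for the synthetic input generator
#'
#' Builds and validates the configuration of the planted-structure generator
#' that emulates the six flat-file inputs of the pipeline: a scored
#' interaction list, a disease-gene reference, pathway gene sets (GMT), a
#' biomarker list, a metabolite-protein association table and a small
#' metabolic graph.
#'
#' The defaults are the package's canonical demo conditions: five planted
#' dense modules of 40 proteins arranged in a ring, consecutive modules
#' sharing 10 nodes, on a universe of 300 proteins, with the first two
#' modules planted as disease modules.  Module size, edge probabilities and
#' the background disease-gene rate were fixed by a prospective power
#' analysis so that a disease-module cluster clears Benjamini-Hochberg
#' FDR < 0.05 with comfortable margin at a planted odds ratio of 10, and so
#' that the clustering density sweep has a well-defined optimum (see the
#' methods vignette).
#'
#' @param n_proteins Number of proteins in the universe.
#' @param n_modules Number of planted modules.
#' @param module_size_range Integer pair; module sizes are drawn uniformly
#'   from this range (minimum 3).
#' @param overlap_nodes Number of nodes shared between consecutive modules.
#' @param module_layout `"ring"` (last module also overlaps the first) or
#'   `"chain"`.
#' @param p_in Within-module edge probability.
#' @param p_out Background edge probability.
#' @param score_in_params,score_out_params Beta shape pairs for interaction
#'   scores on within-module and background edges.
#' @param disease_odds Odds ratio (> 0, may be `Inf`) for disease-gene
#'   membership inside disease modules relative to background.
#' @param disease_baseline Background disease-gene membership probability.
#' @param n_disease_modules Number of modules planted as disease modules
#'   (the first `n_disease_modules` modules).
#' @param n_pathways Number of pathway gene sets.
#' @param pathway_module_alignment Fraction of pathways that are
#'   supersets-with-noise of planted disease modules.
#' @param pathway_noise_genes Number of random extra genes added to each
#'   aligned pathway.
#' @param n_metabolites Number of biomarker metabolites.
#' @param seed_background_fraction Fraction of background (non-module)
#'   proteins included in the metabolite-derived seed set.
#' @param seed Integer random seed; every generator is a pure function of
#'   (config, seed).
#' @return An object of class `synth_config` (a validated named list).
#' @export
#' @examples
#' cfg <- synth_config(n_proteins = 60, n_modules = 2,
#'                     module_size_range = c(8, 8), overlap_nodes = 0,
#'                     seed = 1)
#' ppi <- generate_ppi(cfg)
#' head(ppi$interactions)
synth_config <- function(n_proteins = 300,
                         n_modules = 5,
                         module_size_range = c(40, 40),
                         overlap_nodes = 10,
                         module_layout = c("ring", "chain"),
                         p_in = 0.86,
                         p_out = 0.04,
                         score_in_params = c(8, 2),
                         score_out_params = c(2, 8),
                         disease_odds = 10,
                         disease_baseline = 0.15,
                         n_disease_modules = 2,
                         n_pathways = 12,
                         pathway_module_alignment = 2 / 12,
                         pathway_noise_genes = 5,
                         n_metabolites = 10,
                         seed_background_fraction = 0.6,
                         seed = 1L) {
  module_layout <- match.arg(module_layout)
  cfg <- list(
    n_proteins = n_proteins, n_modules = n_modules,
    module_size_range = module_size_range, overlap_nodes = overlap_nodes,
    module_layout = module_layout, p_in = p_in, p_out = p_out,
    score_in_params = score_in_params, score_out_params = score_out_params,
    disease_odds = disease_odds, disease_baseline = disease_baseline,
    n_disease_modules = n_disease_modules, n_pathways = n_pathways,
    pathway_module_alignment = pathway_module_alignment,
    pathway_noise_genes = pathway_noise_genes,
    n_metabolites = n_metabolites,
    seed_background_fraction = seed_background_fraction,
    seed = as.integer(seed)
  )
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

config_error <- function(field, msg) {
  abort(paste0("invalid synthetic configuration: `", field, "` ", msg),
        class = "ppiclust_config_error")
}

validate_synth_config <- function(cfg) {
  chk_count <- function(field, min = 1) {
    x <- cfg[[field]]
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != floor(x))
      config_error(field, paste0("must be an integer >= ", min))
  }
  chk_prob <- function(field) {
    x <- cfg[[field]]
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1)
      config_error(field, "must be a probability in [0, 1]")
  }
  chk_count("n_proteins", 3)
  chk_count("n_modules", 1)
  chk_count("n_metabolites", 1)
  chk_count("n_pathways", 1)
  chk_count("overlap_nodes", 0)
  chk_count("pathway_noise_genes", 0)
  chk_prob("p_in"); chk_prob("p_out")
  chk_prob("disease_baseline")
  chk_prob("pathway_module_alignment")
  chk_prob("seed_background_fraction")
  msr <- cfg$module_size_range
  if (!is.numeric(msr) || length(msr) != 2 || any(msr != floor(msr)) ||
      msr[1] < 3 || msr[2] < msr[1]) {
    config_error("module_size_range", "must be an increasing integer pair with minimum >= 3")
  }
  if (cfg$overlap_nodes >= msr[1]) {
    config_error("overlap_nodes", "must be smaller than the smallest module size")
  }
  if (!is.numeric(cfg$disease_odds) || length(cfg$disease_odds) != 1 ||
      is.na(cfg$disease_odds) || cfg$disease_odds <= 0) {
    config_error("disease_odds", "must be > 0 (Inf allowed)")
  }
  if (cfg$n_disease_modules < 0 || cfg$n_disease_modules > cfg$n_modules) {
    config_error("n_disease_modules", "must be between 0 and n_modules")
  }
  for (field in c("score_in_params", "score_out_params")) {
    x <- cfg[[field]]
    if (!is.numeric(x) || length(x) != 2 || any(is.na(x)) || any(x <= 0))
      config_error(field, "must be a pair of positive Beta shape parameters")
  }
  invisible(cfg)
}

#' The frozen demonstration configuration
#'
#' The configuration used by the packaged end-to-end demonstration, the test
#' suite's planted-structure recovery checks and `scripts/acceptance.R`.
#' Identical to the [synth_config()] defaults apart from the seed.
#'
#' @param seed Integer random seed.
#' @return A `synth_config` object.
#' @export
demo_config <- function(seed = 1L) synth_config(seed = seed)

protein_ids <- function(n) {
  sprintf(paste0("P%0", max(4L, nchar(as.character(n))), "d"), seq_len(n))
}

# module index blocks: consecutive integer blocks sharing `overlap` indices;
# in a ring the tail of the last module is replaced by the head of the first
module_index_sets <- function(sizes, overlap, layout, n_proteins) {
  k <- length(sizes)
  sets <- vector("list", k)
  start <- 1L
  for (i in seq_len(k)) {
    sets[[i]] <- seq.int(start, start + sizes[i] - 1L)
    start <- start + sizes[i] - if (i < k) overlap else 0L
  }
  if (layout == "ring" && k >= 3 && overlap > 0) {
    last <- sets[[k]]
    keep <- head(last, length(last) - overlap)
    sets[[k]] <- c(keep, sets[[1]][seq_len(overlap)])
  }
  span <- max(unlist(sets))
  if (span > n_proteins) {
    config_error("n_proteins", sprintf(
      "= %d is too small for the planted modules (need >= %d)", n_proteins, span))
  }
  sets
}

#' Generate a scored protein-protein interaction list with planted modules
#'
#' Plants `n_modules` dense modules (within-module edge probability `p_in`)
#' on a background of `p_out` edges, with consecutive modules sharing
#' `overlap_nodes` proteins.  Interaction scores are drawn from a Beta
#' distribution whose shape depends on whether the edge lies inside a planted
#' module, so that a high-confidence score filter retains module edges and
#' discards most background edges.
#'
#' @param config A [synth_config()].
#' @return A list with elements `interactions` (tibble `a`, `b`, `score`;
#'   undirected, self-loop-free, duplicate-free, `a < b`) and `truth`, a
#'   `ground_truth` list recording module membership, disease modules and the
#'   protein universe.
#' @export
generate_ppi <- function(config) {
  validate_synth_config(config)
  with_seed(config$seed, {
    n <- config$n_proteins
    ids <- protein_ids(n)
    size_choices <- seq.int(config$module_size_range[1], config$module_size_range[2])
    sizes <- size_choices[sample.int(length(size_choices), config$n_modules,
                                     replace = TRUE)]
    idx_sets <- module_index_sets(sizes, config$overlap_nodes,
                                  config$module_layout, n)
    modules <- lapply(idx_sets, function(ix) ids[sort(ix)])
    names(modules) <- sprintf("M%02d", seq_along(modules))

    # upper-triangle pair enumeration
    pair_i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
    pair_j <- sequence((n - 1L):1L) + pair_i
    within <- rep(FALSE, length(pair_i))
    for (ix in idx_sets) {
      inmod_i <- pair_i %in% ix
      inmod_j <- pair_j %in% ix
      within <- within | (inmod_i & inmod_j)
    }
    u <- runif(length(pair_i))
    keep <- u < ifelse(within, config$p_in, config$p_out)
    ei <- pair_i[keep]; ej <- pair_j[keep]; ew <- within[keep]
    score <- numeric(length(ei))
    score[ew] <- rbeta(sum(ew), config$score_in_params[1], config$score_in_params[2])
    score[!ew] <- rbeta(sum(!ew), config$score_out_params[1], config$score_out_params[2])

    interactions <- tibble(a = ids[ei], b = ids[ej], score = score) |>
      arrange(.data$a, .data$b)

    assignments <- bind_rows(lapply(names(modules), function(m) {
      tibble(protein = modules[[m]], module = m)
    }))
    truth <- structure(list(
      proteins = ids,
      modules = modules,
      module_assignments = assignments,
      disease_modules = names(modules)[seq_len(config$n_disease_modules)],
      background = setdiff(ids, unique(assignments$protein))
    ), class = "ground_truth")
    list(interactions = interactions, truth = truth)
  })
}

#' Generate a reference disease-gene table over planted modules
#'
#' Each protein is an independent Bernoulli draw: probability
#' `disease_baseline` outside the planted disease modules and the probability
#' whose odds are `disease_odds` times the baseline odds inside them.
#' `disease_odds = Inf` saturates to membership probability 1 inside and 0
#' outside.
#'
#' @param truth `ground_truth` from [generate_ppi()].
#' @param config The same [synth_config()].
#' @return A tibble with column `protein`: the disease-gene reference set.
#' @export
generate_disease_reference <- function(truth, config) {
  validate_synth_config(config)
  stopifnot(inherits(truth, "ground_truth"))
  dm_nodes <- unique(unlist(truth$modules[truth$disease_modules]))
  with_seed(config$seed + 1L, {
    p0 <- config$disease_baseline
    if (is.infinite(config$disease_odds)) {
      p_in_mod <- 1; p_bg <- 0
    } else {
      odds <- config$disease_odds * p0 / (1 - p0)
      p_in_mod <- odds / (1 + odds)
      p_bg <- p0
    }
    prob <- ifelse(truth$proteins %in% dm_nodes, p_in_mod, p_bg)
    hit <- runif(length(prob)) < prob
    tibble(protein = truth$proteins[hit])
  })
}

#' Generate pathway gene sets aligned with planted modules
#'
#' A fraction `pathway_module_alignment` of the pathways are
#' supersets-with-noise of planted disease modules (the module's nodes plus
#' `pathway_noise_genes` random genes), cycling through the disease modules
#' in order; the remaining pathways are random gene sets of module-like size.
#'
#' @inheritParams generate_disease_reference
#' @return A list with `pathways` (named list of gene-id vectors, GMT-ready)
#'   and `planted` (named list: the aligned pathways and the module each one
#'   covers).
#' @export
generate_pathways <- function(truth, config) {
  validate_synth_config(config)
  stopifnot(inherits(truth, "ground_truth"))
  with_seed(config$seed + 2L, {
    np <- config$n_pathways
    target_modules <- if (length(truth$disease_modules) > 0) {
      truth$disease_modules
    } else {
      names(truth$modules)
    }
    n_aligned <- min(round(config$pathway_module_alignment * np), np)
    typical_size <- max(3L, round(mean(lengths(truth$modules))))
    pathways <- vector("list", np)
    planted <- character(0)
    for (j in seq_len(np)) {
      if (j <= n_aligned) {
        mod <- target_modules[(j - 1L) %% length(target_modules) + 1L]
        extra <- sample(setdiff(truth$proteins, truth$modules[[mod]]),
                        config$pathway_noise_genes)
        pathways[[j]] <- sort(c(truth$modules[[mod]], extra))
        planted[sprintf("PW%02d", j)] <- mod
      } else {
        pathways[[j]] <- sort(sample(truth$proteins, typical_size))
      }
    }
    names(pathways) <- sprintf("PW%02d", seq_len(np))
    list(pathways = pathways,
         planted = lapply(setNames(names(planted), names(planted)),
                          function(pw) list(module = planted[[pw]],
                                            genes = pathways[[pw]])))
  })
}

#' Generate biomarker, association and metabolic-graph inputs
#'
#' Builds the three upstream inputs of the mapping stage so that the mapped
#' seed set is known exactly: the planted module nodes plus a
#' `seed_background_fraction` sample of background proteins are distributed
#' over `n_metabolites` biomarkers.  Most proteins are delivered through the
#' pairwise association table; per metabolite, up to two proteins are instead
#' delivered as enzyme labels on a 3-compound chain in the metabolic graph
#' within path length 2, and one decoy protein is placed beyond path length 2
#' (it must not be picked up).
#'
#' @inheritParams generate_disease_reference
#' @return A list with `biomarkers` (tibble `metabolite`, `disease_label`),
#'   `associations` (tibble `metabolite`, `protein`), `metabolic_graph`
#'   (tibble `compound_a`, `compound_b`, `enzyme_label`; one row per
#'   edge-label pair) and `truth_map` (named list: per-metabolite expected
#'   protein set, per-disease seed sets and the union seed set).
#' @export
generate_metabolic_inputs <- function(truth, config) {
  validate_synth_config(config)
  stopifnot(inherits(truth, "ground_truth"))
  with_seed(config$seed + 3L, {
    planted <- sort(unique(truth$module_assignments$protein))
    n_bg_seed <- round(config$seed_background_fraction * length(truth$background))
    bg_seed <- sort(sample(truth$background, n_bg_seed))
    seed_all <- c(planted, bg_seed)
    nm <- config$n_metabolites
    mets <- sprintf("MB%02d", seq_len(nm))
    share <- split(seed_all, rep_len(seq_len(nm), length(seed_all)))
    labels <- rep_len(c("SCZ", "BD", "BOTH"), nm)

    non_seed <- setdiff(truth$proteins, seed_all)
    assoc <- list(); graph_rows <- list(); met_truth <- list()
    for (i in seq_len(nm)) {
      prot <- share[[i]]
      via_graph <- if (length(prot) >= 4) utils::tail(prot, 2) else character(0)
      via_assoc <- setdiff(prot, via_graph)
      assoc[[i]] <- tibble(metabolite = mets[i], protein = via_assoc)
      rows <- NULL
      if (length(via_graph) == 2) {
        c1 <- sprintf("C%02d_1", i); c2 <- sprintf("C%02d_2", i)
        rows <- tibble(
          compound_a = c(mets[i], c1),
          compound_b = c(c1, c2),
          enzyme_label = via_graph
        )
        if (length(non_seed) > 0) {
          decoy <- sample(non_seed, 1)
          rows <- bind_rows(rows, tibble(
            compound_a = c2, compound_b = sprintf("C%02d_3", i),
            enzyme_label = decoy))
        }
      }
      graph_rows[[i]] <- rows
      met_truth[[mets[i]]] <- sort(prot)
    }
    biomarkers <- tibble(metabolite = mets, disease_label = labels)
    seed_for <- function(d) {
      sort(unique(unlist(met_truth[labels %in% c(d, "BOTH")])))
    }
    list(
      biomarkers = biomarkers,
      associations = bind_rows(assoc),
      metabolic_graph = bind_rows(graph_rows),
      truth_map = list(
        metabolite_protein_truth = met_truth,
        seed_scz = seed_for("SCZ"),
        seed_bd = seed_for("BD"),
        seed_all = sort(seed_all)
      )
    )
  })
}

#' Generate the full set of pipeline inputs with known ground truth
#'
#' Convenience wrapper running the four generators and assembling the
#' complete ground-truth record; optionally writes the six flat files to a
#' directory (`interactions.tsv`, `disease_genes.tsv`, `pathways.gmt`,
#' `biomarkers.tsv`, `associations.tsv`, `metabolic_graph.tsv`).
#'
#' @param config A [synth_config()].
#' @param dir Optional output directory (created if missing).
#' @return A list with the six inputs and `truth` (class `ground_truth`,
#'   including `disease_genes`, `planted_pathways` and the seed sets).
#' @export
synthesize_inputs <- function(config, dir = NULL) {
  ppi <- generate_ppi(config)
  truth <- ppi$truth
  disease <- generate_disease_reference(truth, config)
  pw <- generate_pathways(truth, config)
  met <- generate_metabolic_inputs(truth, config)
  truth$disease_genes <- disease$protein
  truth$planted_pathways <- pw$planted
  truth$metabolite_protein_truth <- met$truth_map$metabolite_protein_truth
  truth$seed_scz <- met$truth_map$seed_scz
  truth$seed_bd <- met$truth_map$seed_bd
  truth$seed_all <- met$truth_map$seed_all
  out <- list(
    interactions = ppi$interactions,
    disease_genes = disease,
    pathways = pw$pathways,
    biomarkers = met$biomarkers,
    associations = met$associations,
    metabolic_graph = met$metabolic_graph,
    truth = truth
  )
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_flat_tsv(out$interactions, file.path(dir, "interactions.tsv"))
    writeLines(out$disease_genes$protein, file.path(dir, "disease_genes.tsv"))
    write_gmt(out$pathways, file.path(dir, "pathways.gmt"))
    write_flat_tsv(out$biomarkers, file.path(dir, "biomarkers.tsv"))
    write_flat_tsv(out$associations, file.path(dir, "associations.tsv"))
    write_flat_tsv(out$metabolic_graph, file.path(dir, "metabolic_graph.tsv"))
  }
  out
}
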