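#' Load a biomarker metabolite list
#'
#' Reads a two-column table (`metabolite`, `disease_label`) with labels
#' `SCZ`, `BD` or `BOTH`.  Metabolite names are case-folded and trimmed;
#' duplicate names are merged by unioning their disease labels, so a
#' metabolite reported once per disease collapses to a single record.
#'
#' @param path Path to a tab-separated biomarker file.
#' @return A tibble (`metabolite`, `scz`, `bd`), sorted by metabolite name,
#'   one row per unique metabolite.
#' @export
#' @examples
#' bm <- load_biomarkers(ppiclust_example("biomarkers_scz_bd.tsv"))
#' nrow(bm)  # 46 unique biomarker metabolites
load_biomarkers <- function(path) {
  raw <- read_flat_tsv(path, readr::cols(.default = readr::col_character()))
  if (ncol(raw) < 2) {
    abort("biomarker file must have two columns: metabolite, disease_label",
          class = "ppiclust_parse_error")
  }
  names(raw)[1:2] <- c("metabolite", "disease_label")
  raw <- raw |>
    mutate(metabolite = normalize_name(.data$metabolite),
           disease_label = toupper(trimws(.data$disease_label)),
           line = row_number())
  bad <- raw |> filter(!.data$disease_label %in% c("SCZ", "BD", "BOTH") |
                         .data$metabolite == "")
  if (nrow(bad) > 0) {
    abort(sprintf(
      "unrecognized disease label or empty metabolite at data line %d: '%s'",
      bad$line[1], bad$disease_label[1]), class = "ppiclust_parse_error")
  }
  raw |>
    group_by(.data$metabolite) |>
    summarise(
      scz = any(.data$disease_label %in% c("SCZ", "BOTH")),
      bd = any(.data$disease_label %in% c("BD", "BOTH")),
      .groups = "drop") |>
    arrange(.data$metabolite)
}

normalize_name <- function(x) tolower(trimws(x))

#' Load a metabolite-protein association table
#'
#' @param path Path to a tab-separated table with columns `metabolite`,
#'   `protein`.
#' @return A deduplicated tibble with normalized metabolite names.
#' @export
load_associations <- function(path) {
  raw <- read_flat_tsv(path, readr::cols(.default = readr::col_character()))
  names(raw)[1:2] <- c("metabolite", "protein")
  raw |>
    mutate(metabolite = normalize_name(.data$metabolite)) |>
    distinct(.data$metabolite, .data$protein)
}

#' Load a metabolic graph of compounds and enzyme-labelled edges
#'
#' One row per (compound pair, enzyme label); an edge may carry several
#' labels across rows.  Compound names are normalized like metabolite names.
#'
#' @param path Path to a tab-separated table with columns `compound_a`,
#'   `compound_b`, `enzyme_label`.
#' @return An object of class `metabolic_graph`: a list with `edges`
#'   (tibble `compound_a`, `compound_b`, `enzyme_label`) and `compounds`.
#' @export
load_metabolic_graph <- function(path) {
  raw <- read_flat_tsv(path, readr::cols(.default = readr::col_character()))
  names(raw)[1:3] <- c("compound_a", "compound_b", "enzyme_label")
  as_metabolic_graph(raw)
}

#' Build a metabolic graph from an edge-label table
#'
#' @param edges Data frame with columns `compound_a`, `compound_b`,
#'   `enzyme_label`.
#' @return A `metabolic_graph` object.
#' @export
as_metabolic_graph <- function(edges) {
  edges <- as_tibble(edges) |>
    mutate(compound_a = normalize_name(.data$compound_a),
           compound_b = normalize_name(.data$compound_b)) |>
    distinct()
  if (nrow(edges) > 0 && any(edges$compound_a == edges$compound_b)) {
    abort("metabolic graph contains a self-loop compound edge",
          class = "ppiclust_value_error")
  }
  structure(list(
    edges = edges,
    compounds = sort(unique(c(edges$compound_a, edges$compound_b)))
  ), class = "metabolic_graph")
}

#' Proteins associated with one biomarker metabolite
#'
#' Exact name-match lookup (after normalization) in the pairwise association
#' table; a metabolite absent from the table yields an empty set.
#'
#' @param metabolite Metabolite name.
#' @param associations Table from [load_associations()].
#' @return Sorted character vector of protein ids.
#' @export
associated_proteins <- function(metabolite, associations) {
  m <- normalize_name(metabolite)
  sort(unique(associations$protein[associations$metabolite == m]))
}

#' Enzymes within a path length of a biomarker on the metabolic graph
#'
#' Path length counts compound-to-compound hops.  An enzyme label on edge
#' \{u, v\} is selected when `min(dist(m, u), dist(m, v)) <= max_len - 1`,
#' where `dist` is the unweighted shortest-path distance from the metabolite
#' `m` over compound nodes: an enzyme "at path length k" labels an edge whose
#' nearer endpoint is k - 1 hops away.  With the default `max_len = 2` this
#' selects every enzyme on the first two shells of edges around the
#' biomarker.
#'
#' @param graph A `metabolic_graph`.
#' @param metabolite Compound id of the biomarker (must be in the graph).
#' @param max_len Maximum path length (>= 1).
#' @return Sorted character vector of enzyme labels.
#' @export
#' @examples
#' g <- load_metabolic_graph(ppiclust_example("glutamate_map.tsv"))
#' enzymes_within_path_length(g, "l-glutamate", max_len = 2)
enzymes_within_path_length <- function(graph, metabolite, max_len = 2) {
  stopifnot(inherits(graph, "metabolic_graph"), max_len >= 1)
  m <- normalize_name(metabolite)
  if (!m %in% graph$compounds) {
    abort(paste0("compound not present in metabolic graph: ", metabolite),
          class = "ppiclust_lookup_error")
  }
  dist <- compound_distances(graph, m)
  near <- pmin(dist[graph$edges$compound_a], dist[graph$edges$compound_b])
  sort(unique(graph$edges$enzyme_label[near <= max_len - 1]))
}

# BFS distances from one compound; unreachable compounds get Inf
compound_distances <- function(graph, from) {
  adj <- split(c(graph$edges$compound_b, graph$edges$compound_a),
               c(graph$edges$compound_a, graph$edges$compound_b))
  dist <- setNames(rep(Inf, length(graph$compounds)), graph$compounds)
  dist[from] <- 0
  frontier <- from
  d <- 0
  while (length(frontier) > 0) {
    d <- d + 1
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    nxt <- nxt[is.infinite(dist[nxt])]
    dist[nxt] <- d
    frontier <- nxt
  }
  dist
}

#' Build per-disease seed protein sets from biomarkers
#'
#' For each disease, the seed set is the union over that disease's
#' biomarkers of their associated proteins and of the enzymes within
#' `max_len` path lengths on the metabolic graph (contributions from both
#' sources are unioned).  A biomarker labelled for both diseases contributes
#' to both sets.  Biomarker metabolites absent from the metabolic graph
#' simply contribute no enzymes.
#'
#' @param biomarkers Tibble from [load_biomarkers()].
#' @param associations Tibble from [load_associations()].
#' @param graph Optional `metabolic_graph` (NULL for association-only
#'   mapping).
#' @param max_len Path-length bound for enzyme extraction.
#' @return An object of class `seed_sets`: list with sorted character
#'   vectors `scz`, `bd`, `all` (= union) and `common` (= intersection).
#' @export
build_seed_sets <- function(biomarkers, associations, graph = NULL,
                            max_len = 2) {
  per_marker <- lapply(biomarkers$metabolite, function(m) {
    prot <- associated_proteins(m, associations)
    if (!is.null(graph) && normalize_name(m) %in% graph$compounds) {
      prot <- union(prot, enzymes_within_path_length(graph, m, max_len))
    }
    prot
  })
  s_scz <- sort(unique(unlist(per_marker[biomarkers$scz])))
  s_bd <- sort(unique(unlist(per_marker[biomarkers$bd])))
  structure(list(
    scz = s_scz,
    bd = s_bd,
    all = sort(union(s_scz, s_bd)),
    common = sort(intersect(s_scz, s_bd))
  ), class = "seed_sets")
}

#' @export
print.seed_sets <- function(x, ...) {
  cat(sprintf(
    "<seed_sets> SCZ: %d proteins, BD: %d, union: %d, common: %d\n",
    length(x$scz), length(x$bd), length(x$all), length(x$common)))
  invisible(x)
}

#' Seed sets as a tidy table
#'
#' @param x A `seed_sets` object.
#' @param ... Unused.
#' @return Tibble (`protein`, `in_scz`, `in_bd`).
#' @method tidy seed_sets
#' @export
tidy.seed_sets <- function(x, ...) {
  tibble(protein = x$all,
         in_scz = as.integer(x$all %in% x$scz),
         in_bd = as.integer(x$all %in% x$bd))
}
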