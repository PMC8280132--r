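test_that("generated interaction lists are clean and reproducible", {
  cfg <- small_config(seed = 3)
  ppi1 <- generate_ppi(cfg)
  ppi2 <- generate_ppi(cfg)
  expect_identical(ppi1$interactions, ppi2$interactions)

  e <- ppi1$interactions
  expect_true(all(e$a < e$b))
  expect_false(any(duplicated(paste(e$a, e$b))))
  expect_true(all(e$score >= 0 & e$score <= 1))
  expect_true(all(unique(ppi1$truth$module_assignments$protein) %in%
                    ppi1$truth$proteins))
})

test_that("with no background edges and no overlap, components are the planted modules", {
  cfg <- small_config(seed = 11, p_out = 0, overlap_nodes = 0, p_in = 1)
  ppi <- generate_ppi(cfg)
  g <- igraph::graph_from_data_frame(ppi$interactions[, 1:2], directed = FALSE)
  comp <- igraph::components(g)
  comps <- split(names(comp$membership), comp$membership)
  mods <- lapply(ppi$truth$modules, sort)
  expect_setequal(
    unname(vapply(comps, function(x) paste(sort(x), collapse = ","),
                  character(1))),
    unname(vapply(mods, paste, collapse = ",", FUN.VALUE = character(1))))
})

test_that("realized within-module edge density tracks p_in", {
  dens <- vapply(1:20, function(s) {
    cfg <- synth_config(n_proteins = 80, n_modules = 5,
                        module_size_range = c(10, 10), overlap_nodes = 0,
                        module_layout = "chain", p_in = 0.9, p_out = 0.01,
                        seed = s)
    ppi <- generate_ppi(cfg)
    e <- ppi$interactions
    mean(vapply(ppi$truth$modules, function(m) {
      inside <- sum(e$a %in% m & e$b %in% m)
      inside / choose(length(m), 2)
    }, numeric(1)))
  }, numeric(1))
  expect_lt(abs(mean(dens) - 0.9), 0.1)
})

test_that("disease reference respects the planted odds ratio", {
  cfg <- small_config(seed = 5)
  ppi <- generate_ppi(cfg)

  # saturated odds: disease set equals the union of disease-module nodes
  cfg_inf <- small_config(seed = 5, disease_odds = Inf)
  dg_inf <- generate_disease_reference(ppi$truth, cfg_inf)
  dm_nodes <- sort(unique(unlist(
    ppi$truth$modules[ppi$truth$disease_modules])))
  expect_identical(sort(dg_inf$protein), dm_nodes)

  # determinism
  dg1 <- generate_disease_reference(ppi$truth, cfg)
  dg2 <- generate_disease_reference(ppi$truth, cfg)
  expect_identical(dg1, dg2)

  # odds 1: inside/outside membership rates agree over repeated draws
  rates <- vapply(1:50, function(s) {
    cfg1 <- small_config(seed = s, disease_odds = 1, disease_baseline = 0.3)
    p <- generate_ppi(cfg1)
    dg <- generate_disease_reference(p$truth, cfg1)
    dmn <- unique(unlist(p$truth$modules[p$truth$disease_modules]))
    outn <- setdiff(p$truth$proteins, dmn)
    c(mean(dmn %in% dg$protein), mean(outn %in% dg$protein))
  }, numeric(2))
  expect_lt(abs(mean(rates[1, ]) - mean(rates[2, ])), 0.05)

  expect_error(small_config(disease_odds = 0), class = "ppiclust_config_error")
})

test_that("raising disease_odds raises hypergeometric enrichment of planted modules", {
  enr <- function(odds) {
    vapply(1:20, function(s) {
      cfg <- small_config(seed = s, disease_odds = odds)
      p <- generate_ppi(cfg)
      dg <- generate_disease_reference(p$truth, cfg)
      dmn <- unique(unlist(p$truth$modules[p$truth$disease_modules]))
      fisher_greater(length(intersect(dmn, dg$protein)),
                     length(dg$protein), length(dmn),
                     length(p$truth$proteins))
    }, numeric(1))
  }
  expect_lt(median(enr(10)), median(enr(1)))
})

test_that("pathway gene sets align with planted modules as configured", {
  cfg <- small_config(seed = 7, pathway_module_alignment = 1,
                      pathway_noise_genes = 0, n_pathways = 3)
  ppi <- generate_ppi(cfg)
  pw <- generate_pathways(ppi$truth, cfg)
  for (nm in names(pw$planted)) {
    mod <- ppi$truth$modules[[pw$planted[[nm]]$module]]
    expect_true(all(mod %in% pw$pathways[[nm]]))
  }

  # alignment 0: no pathway identical to any module, across seeds
  for (s in 1:20) {
    cfg0 <- small_config(seed = s, pathway_module_alignment = 0)
    p <- generate_ppi(cfg0)
    pw0 <- generate_pathways(p$truth, cfg0)
    expect_length(pw0$planted, 0)
    for (set in pw0$pathways) {
      for (m in p$truth$modules) expect_false(setequal(set, m))
    }
  }
})

test_that("GMT files round-trip", {
  sets <- list(A = c("P1", "P2", "P3"), B = c("P2", "P9"))
  f <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, f)
  expect_identical(lapply(read_gmt(f), sort), lapply(sets, sort))
})

test_that("metabolic inputs close the loop with the mapping module", {
  cfg <- small_config(seed = 9)
  ppi <- generate_ppi(cfg)
  met <- generate_metabolic_inputs(ppi$truth, cfg)
  assoc <- met$associations
  assoc$metabolite <- tolower(assoc$metabolite)
  graph <- as_metabolic_graph(met$metabolic_graph)
  for (m in met$biomarkers$metabolite) {
    got <- union(
      associated_proteins(m, assoc),
      if (tolower(m) %in% graph$compounds)
        enzymes_within_path_length(graph, m, 2) else character(0))
    expect_identical(sort(got),
                     met$truth_map$metabolite_protein_truth[[m]])
  }
  # determinism
  expect_identical(met, generate_metabolic_inputs(ppi$truth, cfg))
})

test_that("configuration errors name the offending field", {
  expect_error(small_config(p_in = 1.2), "p_in",
               class = "ppiclust_config_error")
  expect_error(small_config(module_size_range = c(2, 5)),
               "module_size_range", class = "ppiclust_config_error")
  expect_error(small_config(n_pathways = 0), "n_pathways",
               class = "ppiclust_config_error")
  expect_error(small_config(n_metabolites = 0), "n_metabolites",
               class = "ppiclust_config_error")
  expect_error(small_config(overlap_nodes = 10), "overlap_nodes",
               class = "ppiclust_config_error")
})
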