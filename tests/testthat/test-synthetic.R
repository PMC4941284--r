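test_that("configuration invariants are enforced", {
  expect_error(synthetic_config(n_genes = 0), "n_genes")
  expect_error(synthetic_config(pathway_size_range = c(10, 5)), "min <= max")
  expect_error(synthetic_config(n_genes = 20, pathway_size_range = c(5, 30)),
               "n_genes")
  expect_error(synthetic_config(planted_target_fraction = 0), "fraction")
  expect_error(synthetic_config(planted_target_fraction = 1.2), "fraction")
  expect_error(synthetic_config(signal_strength = 1.5), "signal_strength")
  expect_error(synthetic_config(n_genes = 10, ppi_mean_degree = 9.5,
                                pathway_size_range = c(3, 5),
                                n_disease_genes = 5),
               "degenerate")
  expect_error(synthetic_config(n_pathways = 3, planted_pathway_index = 4),
               "planted_pathway_index")
  # boundary from the generator contract: mean degree = n - 1 is a complete
  # graph, which is dense but not degenerate
  expect_s3_class(synthetic_config(n_genes = 4, ppi_model = "erdos_renyi",
                                   ppi_mean_degree = 3,
                                   pathway_size_range = c(2, 3),
                                   n_disease_genes = 2),
                  "synthetic_config")
})

test_that("generated PPI graphs are simple and reproducible", {
  cfg4 <- synthetic_config(n_genes = 4, ppi_model = "erdos_renyi",
                           ppi_mean_degree = 3, pathway_size_range = c(2, 3),
                           n_disease_genes = 2, seed = 5)
  ppi <- generate_ppi(cfg4)
  expect_lte(nrow(ppi$edges), 6L)                     # complete graph bound
  expect_true(all(ppi$edges$from != ppi$edges$to))    # no self loops
  expect_false(any(duplicated(paste(ppi$edges$from, ppi$edges$to))))

  # determinism: same seed twice, identical edge lists; different seed differs
  cfg <- small_config(seed = 3)
  expect_identical(generate_ppi(cfg)$edges, generate_ppi(cfg)$edges)
  expect_false(identical(generate_ppi(small_config(seed = 4))$edges,
                         generate_ppi(cfg)$edges))
})

test_that("scale-free graphs are hub-dominated and mostly connected", {
  cfg <- synthetic_config(n_genes = 200, ppi_model = "scale_free",
                          ppi_mean_degree = 6, seed = 7,
                          pathway_size_range = c(5, 10), n_disease_genes = 5)
  ppi <- generate_ppi(cfg)
  g <- igraph::graph_from_data_frame(ppi$edges, directed = FALSE,
                                     vertices = data.frame(name = ppi$genes))
  deg <- igraph::degree(g)
  expect_gt(max(deg), 3 * mean(deg))
  comp <- igraph::components(g)
  expect_gte(max(comp$csize) / length(ppi$genes), 0.8)

  # default parameters also give a dominant giant component
  ppi_def <- generate_ppi(synthetic_config())
  comp_def <- igraph::components(
    igraph::graph_from_data_frame(ppi_def$edges, directed = FALSE,
                                  vertices = data.frame(name = ppi_def$genes)))
  expect_gte(max(comp_def$csize) / length(ppi_def$genes), 0.8)
})

test_that("gene sets respect sizes, universe closure and determinism", {
  cfg <- small_config(seed = 11)
  ppi <- generate_ppi(cfg)
  gs <- generate_gene_sets(cfg, ppi)
  expect_length(gs$sets, cfg$n_pathways)
  sizes <- lengths(gs$sets)
  expect_true(all(sizes >= cfg$pathway_size_range[1] &
                    sizes <= cfg$pathway_size_range[2]))
  expect_true(all(unlist(gs$sets) %in% ppi$genes))
  expect_true(all(!vapply(gs$sets, anyDuplicated, 1L)))
  expect_true(attr(gs, "planted") %in% names(gs$sets))

  one <- small_config(seed = 2, n_pathways = 1, pathway_size_range = c(5, 5))
  gs1 <- generate_gene_sets(one, generate_ppi(one))
  expect_length(gs1$sets, 1L)
  expect_length(gs1$sets[[1]], 5L)

  expect_identical(generate_gene_sets(cfg, ppi)$sets, gs$sets)
  expect_false(identical(generate_gene_sets(small_config(seed = 12),
                                            ppi)$sets, gs$sets))
})

test_that("pharmacopeia respects ranges and records the planted truth", {
  cfg <- small_config(seed = 21)
  b <- generate_synthetic_bundle(cfg)
  expect_true(all(lengths(b$drug_targets) >= 1 & lengths(b$drug_targets) <= 5))
  expect_equal(nrow(b$similarity), cfg$n_herbs * cfg$compounds_per_herb)
  expect_equal(ncol(b$similarity), cfg$n_reference_drugs)
  expect_true(all(b$similarity >= 0 & b$similarity <= 1))
  expect_true(all(table(b$herb_compounds$herb) == cfg$compounds_per_herb))
  expect_true(all(b$true_pairs$gene %in%
                    c(b$planted$core, b$planted$extras)))
  expect_setequal(unique(b$true_pairs$compound), rownames(b$similarity))
  # core is the configured fraction of the planted pathway
  expect_equal(length(b$planted$core),
               max(1L, round(cfg$planted_target_fraction *
                               length(b$planted$members))))
})

test_that("disease genes overlap the planted pathway at the configured fraction", {
  for (seed in 1:5) {
    cfg <- small_config(seed = seed)
    b <- generate_synthetic_bundle(cfg)
    got <- length(intersect(b$disease_genes, b$planted$members))
    want <- round(cfg$disease_overlap_fraction * cfg$n_disease_genes)
    expect_lte(abs(got - want), 1)
    expect_length(b$disease_genes, cfg$n_disease_genes)
  }
})

test_that("the full bundle is a pure function of the configuration", {
  cfg <- small_config(seed = 31)
  b1 <- generate_synthetic_bundle(cfg)
  b2 <- generate_synthetic_bundle(cfg)
  expect_identical(b1$ppi$edges, b2$ppi$edges)
  expect_identical(b1$similarity, b2$similarity)
  expect_identical(b1$gene_sets$sets, b2$gene_sets$sets)
  expect_identical(b1$disease_genes, b2$disease_genes)
  expect_identical(b1$true_pairs, b2$true_pairs)
})

test_that("perfect signal with one anchor target gives concordance exactly 1", {
  cfg <- small_config(seed = 41, signal_strength = 1, noise_sd = 0,
                      targets_per_compound = 1)
  b <- generate_synthetic_bundle(cfg)
  prof <- score_compounds(b$similarity, b$ppi, b$drug_targets)
  scores <- mapply(function(co, g) prof$scores[co, g],
                   b$true_pairs$compound, b$true_pairs$gene)
  expect_true(all(abs(scores - 1) < 1e-8))
})

test_that("zero signal carries no information about true pairs", {
  # Monte-Carlo: mean concordance of true pairs vs random pairs over seeds
  deltas <- vapply(1:50, function(s) {
    cfg <- small_config(seed = 200 + s, signal_strength = 0)
    b <- generate_synthetic_bundle(cfg)
    prof <- score_compounds(b$similarity, b$ppi, b$drug_targets)
    true_scores <- mapply(function(co, g) prof$scores[co, g],
                          b$true_pairs$compound, b$true_pairs$gene)
    mean(true_scores) - mean(prof$scores)
  }, 1.0)
  se <- stats::sd(deltas) / sqrt(length(deltas))
  expect_lt(abs(mean(deltas)), 2 * se + 1e-8)
})

test_that("mean true-pair concordance is non-decreasing in signal strength", {
  levels <- c(0, 0.3, 0.6, 0.9)
  mean_by_level <- vapply(levels, function(ss) {
    mean(vapply(1:20, function(s) {
      cfg <- small_config(seed = 300 + s, signal_strength = ss)
      b <- generate_synthetic_bundle(cfg)
      prof <- score_compounds(b$similarity, b$ppi, b$drug_targets)
      mean(mapply(function(co, g) prof$scores[co, g],
                  b$true_pairs$compound, b$true_pairs$gene))
    }, 1.0))
  }, 1.0)
  expect_true(all(diff(mean_by_level) >= 0))
})

test_that("bundle serialization round-trips through the declared formats", {
  dir <- withr::local_tempdir()
  cfg <- small_config(seed = 51)
  b <- generate_synthetic_bundle(cfg)
  paths <- write_synthetic_bundle(b, dir)
  expect_true(all(file.exists(unlist(paths))))

  inputs <- read_pipeline_inputs(list(
    ppi = paths$ppi, genes = paths$genes, similarity = paths$similarity,
    drug_targets = paths$drug_targets, herb_compounds = paths$herb_compounds,
    disease_genes = paths$disease_genes, gene_sets = paths$gene_sets
  ))
  expect_identical(inputs$ppi$edges, b$ppi$edges)
  expect_identical(inputs$ppi$genes, b$ppi$genes)
  expect_equal(inputs$similarity, b$similarity, tolerance = 1e-12)
  expect_identical(lapply(inputs$drug_targets[names(b$drug_targets)], sort),
                   lapply(b$drug_targets, sort))
  expect_identical(inputs$herb_compounds, b$herb_compounds)
  expect_setequal(inputs$disease_genes, b$disease_genes)
  expect_identical(inputs$gene_sets$sets, b$gene_sets$sets)
  truth <- jsonlite::read_json(paths$truth)
  expect_identical(truth$planted_pathway, b$planted$pathway)
})
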