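test_that("gene-drug closeness follows the kernel over shortest paths", {
  ppi <- path_ppi()
  # the gene is the drug's sole target: d = 0, kernel gives 1
  expect_equal(gene_drug_closeness("A", "d1", ppi, list(d1 = "A")), 1.0)
  # two hops away: exp(-2^2)
  expect_equal(gene_drug_closeness("A", "d1", ppi, list(d1 = "C")), exp(-4))
  # several targets accumulate
  expect_equal(gene_drug_closeness("B", "d1", ppi, list(d1 = c("A", "C"))),
               2 * exp(-1))
  # disconnected component contributes zero
  ppi2 <- ppi_network(data.frame(from = c("A", "X"), to = c("B", "Y")))
  expect_equal(gene_drug_closeness("X", "d1", ppi2, list(d1 = c("A", "B"))), 0)
  # a drug with no mapped target is an error naming the drug
  expect_error(gene_drug_closeness("A", "bad", ppi, list(bad = character(0))),
               "bad")
  expect_error(gene_drug_closeness("A", "bad", ppi, list(bad = "ZZZ")), "bad")
})

test_that("closeness matrix agrees with per-pair computation", {
  cfg <- small_config(seed = 61)
  b <- generate_synthetic_bundle(cfg)
  genes <- sample(b$ppi$genes, 5)
  drugs <- names(b$drug_targets)[1:4]
  cm <- closeness_matrix(b$ppi, b$drug_targets[drugs], genes = genes)
  for (g in genes) {
    for (d in drugs) {
      expect_equal(cm[g, d],
                   gene_drug_closeness(g, d, b$ppi, b$drug_targets),
                   tolerance = 1e-12)
    }
  }
})

test_that("concordance equals the textbook Pearson formula", {
  cfg <- small_config(seed = 71)
  b <- generate_synthetic_bundle(cfg)
  clo <- closeness_matrix(b$ppi, b$drug_targets)
  compounds <- rownames(b$similarity)[1:3]
  genes <- sample(b$ppi$genes, 10)
  for (co in compounds) {
    for (g in genes) {
      x <- as.numeric(b$similarity[co, ])
      y <- as.numeric(clo[g, ])
      want <- if (stats::sd(x) == 0 || stats::sd(y) == 0) 0 else
        oracle_pearson(x, y)
      expect_equal(concordance_score(co, g, b$similarity, b$ppi,
                                     b$drug_targets),
                   want, tolerance = 1e-12)
    }
  }
})

test_that("concordance is invariant under positive affine transforms", {
  cfg <- small_config(seed = 81)
  b <- generate_synthetic_bundle(cfg)
  g <- b$true_pairs$gene[1]
  co <- b$true_pairs$compound[1]
  base <- concordance_score(co, g, b$similarity, b$ppi, b$drug_targets)
  for (i in 1:5) {
    a <- stats::runif(1, 0.1, 5)
    c0 <- stats::runif(1, -2, 2)
    sim2 <- b$similarity
    sim2[co, ] <- a * sim2[co, ] + c0
    expect_equal(concordance_score(co, g, sim2, b$ppi, b$drug_targets),
                 base, tolerance = 1e-9)
  }
  # positive scaling of the closeness channel: scale the kernel itself
  # (an additive kernel offset would shift each drug by its target count,
  # which is not an affine map of the closeness vector)
  expect_equal(
    concordance_score(co, g, b$similarity, b$ppi, b$drug_targets,
                      kernel = function(d) 3 * exp(-d^2)),
    base, tolerance = 1e-9
  )
})

test_that("zero-variance channels score zero, keeping the ranking total", {
  # isolated gene: closeness identically 0 across drugs
  ppi <- ppi_network(data.frame(from = "A", to = "B"), genes = c("A", "B", "Z"))
  sim <- matrix(stats::runif(3), nrow = 1,
                dimnames = list("c1", c("d1", "d2", "d3")))
  dt <- list(d1 = "A", d2 = "B", d3 = c("A", "B"))
  expect_equal(concordance_score("c1", "Z", sim, ppi, dt), 0)
  # constant similarity row
  sim2 <- matrix(0.4, nrow = 1, ncol = 3,
                 dimnames = list("c1", c("d1", "d2", "d3")))
  expect_equal(concordance_score("c1", "A", sim2, ppi, dt), 0)
  # fewer than 3 drugs is undefined
  expect_error(concordance_score("c1", "A", sim[, 1:2, drop = FALSE], ppi, dt),
               ">= 3")
})

test_that("target profiles are total, sorted, and tie-broken by symbol", {
  # symmetric graph: G001 and G002 are leaves of the same hub, hence
  # identical closeness vectors and identical scores
  ppi <- ppi_network(data.frame(from = c("HUB", "HUB"), to = c("G001", "G002")))
  dt_sym <- list(d1 = "HUB", d2 = "HUB", d3 = c("HUB", "G001", "G002"))
  sim <- matrix(c(0.9, 0.2, 0.5), nrow = 1,
                dimnames = list("c1", names(dt_sym)))
  prof <- build_target_profile("c1", sim, ppi, dt_sym)
  expect_equal(nrow(prof), 3L)                       # totality
  expect_identical(sort(prof$rank), 1:3)             # ranks are a permutation
  s1 <- prof$score[prof$gene == "G001"]
  s2 <- prof$score[prof$gene == "G002"]
  expect_equal(s1, s2)
  expect_lt(prof$rank[prof$gene == "G001"], prof$rank[prof$gene == "G002"])

  expect_error(build_target_profile("c1", sim, ppi, dt_sym,
                                    candidate_genes = character(0)),
               "empty")
  # two scored candidates get ranks 1 and 2 in score order
  prof2 <- build_target_profile("c1", sim, ppi, dt_sym,
                                candidate_genes = c("HUB", "G002"))
  expect_identical(prof2$rank, 1:2)
  expect_gte(prof2$score[1], prof2$score[2])
})

test_that("dense scoring matches the scalar route pair by pair", {
  cfg <- small_config(seed = 91)
  b <- generate_synthetic_bundle(cfg)
  genes <- sample(b$ppi$genes, 8)
  prof <- score_compounds(b$similarity, b$ppi, b$drug_targets,
                          candidate_genes = genes)
  for (co in rownames(b$similarity)[1:3]) {
    for (g in genes) {
      expect_equal(prof$scores[co, g],
                   concordance_score(co, g, b$similarity, b$ppi,
                                     b$drug_targets),
                   tolerance = 1e-12)
    }
    expect_identical(sort(as.integer(prof$ranks[co, ])),
                     seq_along(genes))
  }
})

test_that("putative target calling unions top-k lists and counts hits", {
  # hand-built profiles object: 2 compounds x 4 genes
  ranks <- matrix(c(1L, 2L, 3L, 4L,
                    2L, 1L, 4L, 3L), nrow = 2, byrow = TRUE,
                  dimnames = list(c("c1", "c2"), c("GA", "GB", "GC", "GD")))
  scores <- matrix(stats::runif(8), nrow = 2, dimnames = dimnames(ranks))
  prof <- structure(list(scores = scores, ranks = ranks, drugs = paste0("d", 1:3)),
                    class = "target_profiles")
  hc <- data.frame(herb = c("H1", "H1", "H2"), compound = c("c1", "c2", "c1"))

  # one compound, top 2: exactly its two best genes, hit count 1
  one <- call_putative_targets("H2", prof, hc, top_k = 2)
  expect_setequal(one$gene, c("GA", "GB"))
  expect_true(all(one$hits == 1L))

  # two compounds sharing the best gene at top_k = 1
  both <- call_putative_targets("H1", prof, hc, top_k = 1)
  expect_setequal(both$gene, c("GA", "GB"))
  expect_true(all(both$hits == 1L))
  both2 <- call_putative_targets("H1", prof, hc, top_k = 2)
  expect_identical(both2$hits[both2$gene %in% c("GA", "GB")], c(2L, 2L))

  expect_error(call_putative_targets("H9", prof, hc, top_k = 1), "H9")

  all_herbs <- herb_putative_targets(prof, hc, top_k = 2)
  expect_s3_class(all_herbs, "herb_targets")
  expect_setequal(unique(all_herbs$herb), c("H1", "H2"))
})

test_that("planted targets rank near the top under the study conditions", {
  ranks <- unlist(lapply(1:5, function(s) {
    b <- generate_synthetic_bundle(synthetic_config(seed = 400 + s))
    prof <- score_compounds(b$similarity, b$ppi, b$drug_targets)
    mapply(function(co, g) prof$ranks[co, g],
           b$true_pairs$compound, b$true_pairs$gene)
  }))
  expect_lt(median(ranks), 0.1 * 500)
})
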