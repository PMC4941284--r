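# Small, fast configurations and hand-built fixtures shared across tests.

small_config <- function(seed = 1, ...) {
  args <- list(n_genes = 120, n_reference_drugs = 12, n_herbs = 2,
               compounds_per_herb = 3, n_pathways = 8,
               pathway_size_range = c(6, 12), ppi_mean_degree = 4,
               n_disease_genes = 10, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(synthetic_config, args)
}

# study conditions: generator defaults, pipeline top_k = 10
study_run_config <- function(seed, ...) {
  run_config(synthetic = synthetic_config(seed = seed), top_k = 10, ...)
}

# path graph A - B - C
path_ppi <- function() {
  ppi_network(data.frame(from = c("A", "B"), to = c("B", "C")))
}

# tiny hand-enumerable network: herb H, putative {A, B}, known {B, C},
# PPI edges A-B, B-C
tiny_assembly_inputs <- function() {
  list(
    herb_targets = data.frame(herb = "H", gene = c("A", "B"),
                              hits = c(1L, 1L), stringsAsFactors = FALSE),
    known = c("B", "C"),
    ppi = path_ppi()
  )
}

# topology table built by hand (for median/selection tests)
manual_topology <- function(degree, betweenness = degree,
                            closeness = degree, k_core = pmin(degree, 3L),
                            role = "putative_target") {
  n <- length(degree)
  structure(
    data.frame(node = sprintf("N%03d", seq_len(n)),
               role = rep_len(role, n),
               degree = as.numeric(degree),
               betweenness = as.numeric(betweenness),
               closeness = as.numeric(closeness),
               k_core = as.integer(k_core),
               stringsAsFactors = FALSE),
    class = c("topology_table", "data.frame")
  )
}
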