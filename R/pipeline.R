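#' Pipeline run configuration
#'
#' Collects every pipeline-level choice: where the inputs come from
#' (exactly one of a [synthetic_config()] or a named list of input file
#' paths), the profile cutoff `top_k`, the closeness variant and
#' betweenness normalization, major-node eligibility, the enrichment
#' background mode, the significance level, the seed and the output
#' directory.
#'
#' @param synthetic a [synthetic_config()], or `NULL` when reading inputs
#'   from files. When both `synthetic` and `inputs` are `NULL` the default
#'   synthetic configuration is used.
#' @param inputs named list of file paths (`ppi`, `similarity`,
#'   `drug_targets`, `herb_compounds`, `disease_genes`, `gene_sets`,
#'   optionally `genes` for the full universe), or `NULL`.
#' @param top_k profile cutoff used for target calling and hit counting.
#' @param closeness_variant see [compute_topology()].
#' @param betweenness_normalized see [compute_topology()].
#' @param eligible_roles roles eligible for major-node selection.
#' @param universe_mode enrichment background: `"collection"` (union of all
#'   gene-set members, default) or `"ppi"` (every gene in the PPI universe).
#' @param significance_alpha threshold on the Bonferroni-corrected p-value.
#' @param seed integer; overrides the synthetic config's seed so one number
#'   controls the whole run. Ignored for file inputs (the pipeline is then
#'   deterministic anyway).
#' @param output_dir directory for intermediate artifacts and the run
#'   report; `NULL` keeps everything in memory.
#' @param n_reliability_targets how many top major nodes (by degree) enter
#'   the reliability table.
#' @return object of class `run_config`.
#' @export
run_config <- function(synthetic = NULL, inputs = NULL, top_k = 100,
                       closeness_variant = c("harmonic",
                                             "classic_inverse_farness",
                                             "classic_times_n_minus_1"),
                       betweenness_normalized = FALSE,
                       eligible_roles = c("putative_target",
                                          "known_disease_target", "both"),
                       universe_mode = c("collection", "ppi"),
                       significance_alpha = 0.05,
                       seed = NULL, output_dir = NULL,
                       n_reliability_targets = 10) {
  if (!is.null(synthetic) && !is.null(inputs)) {
    stop("provide exactly one of 'synthetic' and 'inputs'", call. = FALSE)
  }
  if (is.null(synthetic) && is.null(inputs)) synthetic <- synthetic_config()
  if (!is.null(synthetic)) {
    stopifnot(inherits(synthetic, "synthetic_config"))
    if (!is.null(seed)) {
      synthetic$seed <- check_count(seed, "seed", min = 0L)
    }
  } else {
    needed <- c("ppi", "similarity", "drug_targets", "herb_compounds",
                "disease_genes", "gene_sets")
    missing <- setdiff(needed, names(inputs))
    if (length(missing)) {
      stop("missing input path(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
  }
  if (!is.numeric(significance_alpha) || length(significance_alpha) != 1L ||
      significance_alpha <= 0 || significance_alpha > 1) {
    stop("significance_alpha must lie in (0, 1]", call. = FALSE)
  }
  structure(list(
    synthetic = synthetic, inputs = inputs,
    top_k = check_count(top_k, "top_k"),
    closeness_variant = match.arg(closeness_variant),
    betweenness_normalized = isTRUE(betweenness_normalized),
    eligible_roles = eligible_roles,
    universe_mode = match.arg(universe_mode),
    significance_alpha = as.numeric(significance_alpha),
    seed = if (!is.null(synthetic)) synthetic$seed else NULL,
    output_dir = output_dir,
    n_reliability_targets = check_count(n_reliability_targets,
                                        "n_reliability_targets")
  ), class = "run_config")
}

#' Read pipeline inputs from files
#'
#' @param paths named list of paths as in [run_config()].
#' @return list with elements `ppi`, `similarity`, `drug_targets`,
#'   `herb_compounds`, `disease_genes`, `gene_sets`.
#' @export
read_pipeline_inputs <- function(paths) {
  genes <- if (!is.null(paths$genes)) read_gene_list(paths$genes) else NULL
  ppi <- if (grepl("\\.sif$", paths$ppi)) {
    read_ppi_sif(paths$ppi, genes = genes)
  } else {
    read_ppi_tsv(paths$ppi, genes = genes)
  }
  list(
    ppi = ppi,
    similarity = read_similarity_tsv(paths$similarity),
    drug_targets = read_drug_targets_tsv(paths$drug_targets),
    herb_compounds = read_herb_compounds_tsv(paths$herb_compounds),
    disease_genes = read_gene_list(paths$disease_genes),
    gene_sets = read_gmt(paths$gene_sets)
  )
}

#' Run the full network-pharmacology pipeline
#'
#' Executes every stage in order: input generation (or loading), compound
#' target scoring, per-herb target calling, tripartite network assembly,
#' topology and median-filter major-node selection, pathway
#' over-representation of the major nodes, and the target-reliability
#' table. With an `output_dir`, every intermediate artifact and a JSON run
#' report are written; identical configurations (including seed) produce
#' byte-identical reports.
#'
#' @param config a [run_config()].
#' @return object of class `netpharm_run`: list with elements `inputs`
#'   (the bundle), `profiles`, `herb_targets`, `network`, `composition`,
#'   `topology`, `thresholds`, `major_nodes`, `enrichment`, `reliability`,
#'   `report` and `config`.
#' @examples
#' cfg <- synthetic_config(n_genes = 80, n_reference_drugs = 10, n_herbs = 2,
#'                         compounds_per_herb = 3, n_pathways = 5,
#'                         pathway_size_range = c(5, 10),
#'                         n_disease_genes = 8, seed = 7)
#' run <- run_pipeline(run_config(synthetic = cfg, top_k = 10))
#' run
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))

  bundle <- if (!is.null(config$synthetic)) {
    generate_synthetic_bundle(config$synthetic)
  } else {
    read_pipeline_inputs(config$inputs)
  }

  profiles <- score_compounds(bundle$similarity, bundle$ppi,
                              bundle$drug_targets)
  herb_targets <- herb_putative_targets(profiles, bundle$herb_compounds,
                                        top_k = config$top_k)
  network <- assemble_network(herb_targets, bundle$disease_genes, bundle$ppi)
  composition <- summary(network)

  topology <- compute_topology(network,
                               closeness = config$closeness_variant,
                               betweenness_normalized =
                                 config$betweenness_normalized)
  thresholds <- median_thresholds(topology)
  major <- select_major_nodes(topology, thresholds,
                              eligible_roles = config$eligible_roles)

  universe <- switch(config$universe_mode,
                     collection = NULL,
                     ppi = bundle$ppi$genes)
  query <- as.character(major)
  effective_univ <- if (is.null(universe)) bundle$gene_sets$universe else
    universe
  enrichment <- if (length(intersect(query, effective_univ)) == 0L) {
    message("no major node maps into the enrichment universe; ",
            "reporting an empty enrichment table")
    empty_enrichment(length(bundle$gene_sets$sets), config$significance_alpha)
  } else {
    enrich(query, bundle$gene_sets, universe = universe,
           alpha = config$significance_alpha)
  }

  major_set <- as.character(major)
  major_deg <- topology$degree[match(major_set, topology$node)]
  rel_targets <- head(major_set[order(-major_deg, major_set)],
                      config$n_reliability_targets)
  reliability <- if (length(rel_targets)) {
    reliability_table(rel_targets, profiles, bundle$herb_compounds,
                      top_k = config$top_k)
  } else {
    NULL
  }

  sig <- as.data.frame(enrichment[enrichment$significant, , drop = FALSE])
  report <- list(
    composition = composition,
    median_thresholds = unclass(thresholds),
    major_nodes = list(
      n_major = length(major),
      by_role = as.list(attr(major, "counts")),
      nodes = sort(as.character(major))
    ),
    significant_pathways = sig[, c("pathway", "k", "K", "n", "N",
                                   "p_raw", "p_bonf")],
    n_pathways_tested = attr(enrichment, "m_tested"),
    config = config_echo(config)
  )

  run <- structure(list(
    inputs = bundle, profiles = profiles, herb_targets = herb_targets,
    network = network, composition = composition, topology = topology,
    thresholds = thresholds, major_nodes = major, enrichment = enrichment,
    reliability = reliability, report = report, config = config
  ), class = "netpharm_run")

  if (!is.null(config$output_dir)) write_run_artifacts(run, config$output_dir)
  run
}

# plain-list echo of the configuration for the JSON report
config_echo <- function(config) {
  out <- unclass(config)
  out$output_dir <- NULL
  if (!is.null(out$synthetic)) out$synthetic <- unclass(out$synthetic)
  out$inputs <- if (is.null(out$inputs)) NULL else lapply(out$inputs, as.character)
  out
}

write_run_artifacts <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (inherits(run$inputs, "synthetic_bundle")) {
    write_synthetic_bundle(run$inputs, file.path(dir, "inputs"))
  }
  write_profiles_tsv(run$profiles, file.path(dir, "profiles.tsv"))
  write_herb_targets_tsv(run$herb_targets, file.path(dir, "herb_targets.tsv"))
  write_network_tsv(run$network, file.path(dir, "network_edges.tsv"))
  write_node_roles_tsv(run$network, file.path(dir, "network_nodes.tsv"))
  write_network_sif(run$network, file.path(dir, "network.sif"))
  write_topology_tsv(run$topology, file.path(dir, "topology.tsv"),
                     major = run$major_nodes)
  write_thresholds_json(run$thresholds, file.path(dir, "thresholds.json"))
  write_enrichment_tsv(run$enrichment, file.path(dir, "enrichment.tsv"))
  if (!is.null(run$reliability)) {
    write_reliability_tsv(run$reliability, file.path(dir, "reliability.tsv"))
  }
  jsonlite::write_json(run$report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.netpharm_run <- function(x, ...) {
  cat("Network-pharmacology pipeline run\n\n")
  print(x$network)
  cat("\n")
  print(x$thresholds)
  counts <- attr(x$major_nodes, "counts")
  counts <- counts[counts > 0]
  cat(sprintf("Major nodes: %d (%s)\n", length(x$major_nodes),
              paste(sprintf("%d %s", counts, names(counts)), collapse = ", ")))
  cat("\n")
  print(x$enrichment)
  invisible(x)
}
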