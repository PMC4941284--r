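#' Configuration for the synthetic-data generator
#'
#' Bundles every knob of the synthetic study: the gene universe and PPI
#' topology, the reference pharmacopeia (drugs with known targets, herbs
#' with compounds), the planted compound-target signal, the pathway
#' collection with one planted enriched pathway, and the disease gene list.
#' The full synthetic bundle is a pure function of this configuration:
#' identical configs (including `seed`) give bit-identical outputs.
#'
#' The signal model: each compound carries `targets_per_compound` planted
#' true targets drawn from a pool made of a `planted_target_fraction` core of
#' the planted pathway plus a smaller set of random off-pathway genes. The
#' compound's similarity profile across reference drugs is a mixture
#' `s * z + sqrt(1 - s^2) * eta + noise_sd * eps` of the mean standardized
#' closeness profile `z` of its true targets with independent Gaussian noise,
#' rescaled to `[0, 1]`; `s = signal_strength` is then (up to the extra
#' `noise_sd` channel) the Pearson correlation between the similarity and
#' closeness channels.
#'
#' @param n_genes number of genes in the universe.
#' @param n_reference_drugs number of reference drugs (each gets 1-5 known
#'   targets).
#' @param n_herbs number of herbs in the formula.
#' @param compounds_per_herb compounds per herb.
#' @param n_pathways number of gene sets in the collection.
#' @param pathway_size_range integer vector `c(min, max)` of gene-set sizes.
#' @param ppi_model `"scale_free"` (preferential attachment with
#'   `m = round(ppi_mean_degree / 2)`) or `"erdos_renyi"`.
#' @param ppi_mean_degree target mean degree of the PPI graph.
#' @param planted_pathway_index which pathway carries the planted signal.
#' @param planted_target_fraction fraction of the planted pathway that forms
#'   the shared true-target core.
#' @param signal_strength mixing weight in `[0, 1]` between the closeness
#'   channel and noise for true compound-target pairs.
#' @param noise_sd standard deviation of the additional additive noise.
#' @param targets_per_compound planted true targets per compound, drawn from
#'   the core-plus-extras pool.
#' @param n_disease_genes size of the known disease-gene list.
#' @param disease_overlap_fraction fraction of disease genes drawn from the
#'   planted pathway.
#' @param seed integer seed; every random choice in the generator derives
#'   from it.
#' @return object of class `synthetic_config` (a validated named list).
#' @seealso [generate_synthetic_bundle()]
#' @export
synthetic_config <- function(n_genes = 500,
                             n_reference_drugs = 40,
                             n_herbs = 5,
                             compounds_per_herb = 8,
                             n_pathways = 30,
                             pathway_size_range = c(10, 30),
                             ppi_model = c("scale_free", "erdos_renyi"),
                             ppi_mean_degree = 6,
                             planted_pathway_index = 1,
                             planted_target_fraction = 0.6,
                             signal_strength = 0.9,
                             noise_sd = 0.1,
                             targets_per_compound = 3,
                             n_disease_genes = 31,
                             disease_overlap_fraction = 0.3,
                             seed = 1L) {
  ppi_model <- match.arg(ppi_model)
  cfg <- list(
    n_genes = check_count(n_genes, "n_genes"),
    n_reference_drugs = check_count(n_reference_drugs, "n_reference_drugs"),
    n_herbs = check_count(n_herbs, "n_herbs"),
    compounds_per_herb = check_count(compounds_per_herb, "compounds_per_herb"),
    n_pathways = check_count(n_pathways, "n_pathways"),
    pathway_size_range = c(check_count(pathway_size_range[1L], "pathway_size_range[1]"),
                           check_count(pathway_size_range[2L], "pathway_size_range[2]")),
    ppi_model = ppi_model,
    ppi_mean_degree = as.numeric(ppi_mean_degree),
    planted_pathway_index = check_count(planted_pathway_index,
                                        "planted_pathway_index"),
    planted_target_fraction = check_fraction(planted_target_fraction,
                                             "planted_target_fraction"),
    signal_strength = as.numeric(signal_strength),
    noise_sd = as.numeric(noise_sd),
    targets_per_compound = check_count(targets_per_compound,
                                       "targets_per_compound"),
    n_disease_genes = check_count(n_disease_genes, "n_disease_genes"),
    disease_overlap_fraction = check_fraction(disease_overlap_fraction,
                                              "disease_overlap_fraction"),
    seed = check_count(seed, "seed", min = 0L)
  )
  if (cfg$pathway_size_range[1L] > cfg$pathway_size_range[2L] ||
      cfg$pathway_size_range[2L] > cfg$n_genes) {
    stop("pathway_size_range must satisfy min <= max <= n_genes", call. = FALSE)
  }
  if (!is.finite(cfg$ppi_mean_degree) || cfg$ppi_mean_degree <= 0) {
    stop("ppi_mean_degree must be a positive real", call. = FALSE)
  }
  if (cfg$ppi_mean_degree > cfg$n_genes - 1L) {
    stop("ppi_mean_degree >= n_genes is degenerate (denser than a complete graph)",
         call. = FALSE)
  }
  if (cfg$signal_strength < 0 || cfg$signal_strength > 1) {
    stop("signal_strength must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  if (cfg$planted_pathway_index > cfg$n_pathways) {
    stop("planted_pathway_index exceeds n_pathways", call. = FALSE)
  }
  if (cfg$n_disease_genes > cfg$n_genes) {
    stop("n_disease_genes exceeds n_genes", call. = FALSE)
  }
  structure(cfg, class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("Synthetic study configuration\n")
  cat(sprintf("  universe: %d genes, PPI %s (mean degree %.1f)\n",
              x$n_genes, x$ppi_model, x$ppi_mean_degree))
  cat(sprintf("  pharmacopeia: %d reference drugs; %d herbs x %d compounds\n",
              x$n_reference_drugs, x$n_herbs, x$compounds_per_herb))
  cat(sprintf("  signal: strength %.2f, noise sd %.2f, %d targets/compound\n",
              x$signal_strength, x$noise_sd, x$targets_per_compound))
  cat(sprintf("  pathways: %d (planted #%d), disease genes: %d (overlap %.2f)\n",
              x$n_pathways, x$planted_pathway_index, x$n_disease_genes,
              x$disease_overlap_fraction))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

gene_ids <- function(n) sprintf("G%0*d", max(4L, nchar(n)), seq_len(n))

#' Generate a synthetic PPI network
#'
#' Undirected simple graph over `n_genes` synthetic gene symbols
#' (`G0001`, ...). The scale-free model uses preferential attachment with
#' `m = round(ppi_mean_degree / 2)` edges per incoming node; the
#' Erdos-Renyi model uses G(n, p) with `p = ppi_mean_degree / (n - 1)`.
#'
#' @param config a [synthetic_config()].
#' @return a [ppi_network()].
#' @export
generate_ppi <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  genes <- gene_ids(config$n_genes)
  g <- switch(config$ppi_model,
    scale_free = igraph::sample_pa(config$n_genes,
                                   m = max(1L, round(config$ppi_mean_degree / 2)),
                                   directed = FALSE),
    erdos_renyi = igraph::sample_gnp(config$n_genes,
                                     p = min(1, config$ppi_mean_degree /
                                               max(1L, config$n_genes - 1L)))
  )
  el <- igraph::as_edgelist(g, names = FALSE)
  ppi_network(data.frame(from = genes[el[, 1L]], to = genes[el[, 2L]]),
              genes = genes)
}

#' Generate a synthetic gene-set collection
#'
#' `n_pathways` gene sets with sizes uniform in `pathway_size_range`. Each
#' set is grown as a snowball neighborhood around a random seed gene:
#' members are added by repeatedly sampling a PPI neighbor of the current
#' set (falling back to a random unused gene when the neighborhood is
#' exhausted). Real pathways are network-proximal modules in the
#' interactome, and this sampling reproduces that modularity; it is also
#' what makes the planted pathway recoverable as a coherent network module
#' downstream. The planted pathway (by `planted_pathway_index`) is recorded
#' in the `planted` attribute.
#'
#' @inheritParams generate_ppi
#' @param ppi the matching [generate_ppi()] output.
#' @return a [gene_set_collection()] with attribute `planted` (pathway name).
#' @export
generate_gene_sets <- function(config, ppi) {
  stopifnot(inherits(config, "synthetic_config"), inherits(ppi, "ppi_network"))
  set.seed(config$seed + 2L)
  rng <- config$pathway_size_range
  sizes <- rng[1L] + sample.int(rng[2L] - rng[1L] + 1L, config$n_pathways,
                                replace = TRUE) - 1L
  nbr <- adjacency_list(ppi)
  sets <- lapply(sizes, function(s) snowball_sample(ppi$genes, nbr, s))
  names(sets) <- sprintf("PW%03d", seq_len(config$n_pathways))
  out <- gene_set_collection(sets)
  attr(out, "planted") <- names(sets)[config$planted_pathway_index]
  out
}

# internal: named list gene -> character vector of PPI neighbours
adjacency_list <- function(ppi) {
  nbr <- setNames(vector("list", length(ppi$genes)), ppi$genes)
  if (nrow(ppi$edges)) {
    half <- split(c(ppi$edges$to, ppi$edges$from),
                  c(ppi$edges$from, ppi$edges$to))
    nbr[names(half)] <- half
  }
  nbr
}

# internal: snowball sample of `size` genes around a random seed
snowball_sample <- function(genes, nbr, size) {
  current <- sample(genes, 1L)
  while (length(current) < size) {
    frontier <- setdiff(unique(unlist(nbr[current], use.names = FALSE)),
                        current)
    nxt <- if (length(frontier)) {
      if (length(frontier) == 1L) frontier else sample(frontier, 1L)
    } else {
      pool <- setdiff(genes, current)
      if (length(pool) == 1L) pool else sample(pool, 1L)
    }
    current <- c(current, nxt)
  }
  current
}

#' Generate the synthetic reference pharmacopeia
#'
#' Produces the remaining compound-side inputs: a drug-to-target map (1-5
#' targets per reference drug), the herb-to-compound membership table, the
#' compound-by-drug similarity matrix with the planted concordance signal,
#' and the record of planted true compound-target pairs.
#'
#' @inheritParams generate_gene_sets
#' @param gene_sets the matching [generate_gene_sets()] output; regenerated
#'   from `config` when omitted.
#' @return list with elements `drug_targets` (named list), `similarity`
#'   (compound x drug matrix in `[0, 1]`), `herb_compounds` (data frame),
#'   `true_pairs` (data frame `compound`, `gene`) and `planted` (list with
#'   the pathway name, its members, the true-target `core` and the random
#'   `extras`).
#' @export
generate_reference_pharmacopeia <- function(config, ppi, gene_sets = NULL) {
  stopifnot(inherits(config, "synthetic_config"), inherits(ppi, "ppi_network"))
  if (is.null(gene_sets)) gene_sets <- generate_gene_sets(config, ppi)
  set.seed(config$seed + 1L)

  drugs <- sprintf("D%03d", seq_len(config$n_reference_drugs))
  drug_targets <- setNames(lapply(drugs, function(d) {
    sample(ppi$genes, sample(1:5, 1L))
  }), drugs)

  herbs <- sprintf("H%02d", seq_len(config$n_herbs))
  compounds <- sprintf("C%03d", seq_len(config$n_herbs * config$compounds_per_herb))
  herb_compounds <- data.frame(
    herb = rep(herbs, each = config$compounds_per_herb),
    compound = compounds, stringsAsFactors = FALSE
  )

  planted_name <- attr(gene_sets, "planted")
  pw <- gene_sets$sets[[planted_name]]
  core_size <- max(1L, round(config$planted_target_fraction * length(pw)))
  core <- sample(pw, core_size)
  n_extras <- max(1L, ceiling(core_size / 3))
  extras <- sample(setdiff(ppi$genes, pw), n_extras)
  pool <- c(core, extras)

  # closeness channel: gene x drug kernel-closeness, standardized per gene
  clo <- closeness_matrix(ppi, drug_targets)
  z <- t(apply(clo, 1L, function(r) {
    s <- stats::sd(r)
    if (is.na(s) || s == 0) rep(0, length(r)) else (r - mean(r)) / s
  }))

  m <- length(drugs)
  s <- config$signal_strength
  sim <- matrix(0, nrow = length(compounds), ncol = m,
                dimnames = list(compounds, drugs))
  true_pairs <- vector("list", length(compounds))
  for (i in seq_along(compounds)) {
    tc <- sample(pool, min(config$targets_per_compound, length(pool)))
    true_pairs[[i]] <- data.frame(compound = compounds[i], gene = tc,
                                  stringsAsFactors = FALSE)
    zt <- colMeans(z[tc, , drop = FALSE])
    sdt <- stats::sd(zt)
    if (!is.na(sdt) && sdt > 0) zt <- (zt - mean(zt)) / sdt else zt <- rep(0, m)
    raw <- s * zt + sqrt(max(0, 1 - s^2)) * rnorm(m) + config$noise_sd * rnorm(m)
    rng <- range(raw)
    sim[i, ] <- if (diff(rng) > 0) (raw - rng[1L]) / diff(rng) else rep(0.5, m)
  }

  list(drug_targets = drug_targets,
       similarity = sim,
       herb_compounds = herb_compounds,
       true_pairs = do.call(rbind, true_pairs),
       planted = list(pathway = planted_name, members = pw,
                      core = core, extras = extras))
}

#' Generate the synthetic disease-gene list
#'
#' `round(disease_overlap_fraction * n_disease_genes)` genes come from the
#' planted pathway, the rest from off-pathway genes, so the overlap with the
#' planted pathway equals the configured fraction up to rounding.
#'
#' @inheritParams generate_reference_pharmacopeia
#' @return character vector of disease gene symbols.
#' @export
generate_disease_genes <- function(config, ppi, gene_sets = NULL) {
  stopifnot(inherits(config, "synthetic_config"), inherits(ppi, "ppi_network"))
  if (is.null(gene_sets)) gene_sets <- generate_gene_sets(config, ppi)
  set.seed(config$seed + 3L)
  pw <- gene_sets$sets[[attr(gene_sets, "planted")]]
  n_overlap <- min(round(config$disease_overlap_fraction * config$n_disease_genes),
                   length(pw))
  from_pw <- sample(pw, n_overlap)
  rest <- sample(setdiff(ppi$genes, pw), config$n_disease_genes - n_overlap)
  sort(c(from_pw, rest))
}

#' Generate the full synthetic input bundle
#'
#' Deterministically derives all six pipeline inputs (PPI network, gene-set
#' collection, drug-target map, similarity matrix, herb-compound map,
#' disease-gene list) plus the planted ground truth from one
#' [synthetic_config()].
#'
#' @inheritParams generate_ppi
#' @return object of class `synthetic_bundle`: list with elements `config`,
#'   `ppi`, `gene_sets`, `drug_targets`, `similarity`, `herb_compounds`,
#'   `disease_genes`, `true_pairs`, `planted`.
#' @examples
#' cfg <- synthetic_config(n_genes = 60, n_reference_drugs = 8, n_herbs = 2,
#'                         compounds_per_herb = 2, n_pathways = 4,
#'                         pathway_size_range = c(5, 8), n_disease_genes = 6,
#'                         seed = 42)
#' bundle <- generate_synthetic_bundle(cfg)
#' bundle
#' @export
generate_synthetic_bundle <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  ppi <- generate_ppi(config)
  gene_sets <- generate_gene_sets(config, ppi)
  pharm <- generate_reference_pharmacopeia(config, ppi, gene_sets)
  disease <- generate_disease_genes(config, ppi, gene_sets)
  structure(
    list(config = config, ppi = ppi, gene_sets = gene_sets,
         drug_targets = pharm$drug_targets, similarity = pharm$similarity,
         herb_compounds = pharm$herb_compounds, disease_genes = disease,
         true_pairs = pharm$true_pairs, planted = pharm$planted),
    class = "synthetic_bundle"
  )
}

#' @export
print.synthetic_bundle <- function(x, ...) {
  cat("Synthetic network-pharmacology bundle\n")
  print(x$ppi)
  cat(sprintf("  %d reference drugs, %d compounds in %d herbs\n",
              length(x$drug_targets), nrow(x$similarity),
              length(unique(x$herb_compounds$herb))))
  cat(sprintf("  %d gene sets (planted: %s), %d disease genes\n",
              length(x$gene_sets$sets), x$planted$pathway,
              length(x$disease_genes)))
  cat(sprintf("  %d planted true compound-target pairs\n", nrow(x$true_pairs)))
  invisible(x)
}

#' Serialize a synthetic bundle to plain-text pipeline inputs
#'
#' Writes the six input files (PPI TSV and SIF, similarity TSV, drug-target
#' TSV, herb-compound TSV, disease-gene list, GMT) plus `genes.txt` (the
#' universe, so isolated genes survive a round trip) and `truth.json` (the
#' planted ground truth).
#'
#' @param bundle a [generate_synthetic_bundle()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, a named list of the written paths.
#' @export
write_synthetic_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "synthetic_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    ppi = file.path(dir, "ppi.tsv"),
    ppi_sif = file.path(dir, "ppi.sif"),
    genes = file.path(dir, "genes.txt"),
    similarity = file.path(dir, "similarity.tsv"),
    drug_targets = file.path(dir, "drug_targets.tsv"),
    herb_compounds = file.path(dir, "herb_compounds.tsv"),
    disease_genes = file.path(dir, "disease_genes.txt"),
    gene_sets = file.path(dir, "gene_sets.gmt"),
    truth = file.path(dir, "truth.json")
  )
  write_ppi_tsv(bundle$ppi, paths$ppi)
  write_ppi_sif(bundle$ppi, paths$ppi_sif)
  write_gene_list(bundle$ppi$genes, paths$genes)
  write_similarity_tsv(bundle$similarity, paths$similarity)
  write_drug_targets_tsv(bundle$drug_targets, paths$drug_targets)
  write_herb_compounds_tsv(bundle$herb_compounds, paths$herb_compounds)
  write_gene_list(bundle$disease_genes, paths$disease_genes)
  write_gmt(bundle$gene_sets, paths$gene_sets)
  truth <- list(
    planted_pathway = bundle$planted$pathway,
    planted_members = bundle$planted$members,
    true_target_core = bundle$planted$core,
    off_pathway_extras = bundle$planted$extras,
    true_pairs = bundle$true_pairs,
    config = unclass(bundle$config)
  )
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}
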