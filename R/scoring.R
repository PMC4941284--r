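#' Gaussian shortest-path kernel
#'
#' Default transform of unweighted shortest-path distance used by the
#' closeness channel: `exp(-d^2)`. Distance 0 (the gene is itself a target)
#' maps to 1; unreachable genes (`d = Inf`) map to 0.
#'
#' @param d numeric vector of shortest-path distances.
#' @return numeric vector of kernel values in `[0, 1]`.
#' @export
gaussian_distance_kernel <- function(d) {
  k <- exp(-d^2)
  k[!is.finite(d)] <- 0
  k
}

#' Closeness of a gene to a drug's known targets
#'
#' The network-closeness channel of the concordance score: the sum, over the
#' drug's known targets `t`, of `kernel(d(gene, t))` where `d` is the
#' unweighted shortest-path distance in the PPI network. Targets unreachable
#' from the gene contribute 0; `d(g, g) = 0` so a gene that is itself a
#' target contributes `kernel(0) = 1`.
#'
#' @param gene gene symbol.
#' @param drug drug identifier (must have at least one mapped target).
#' @param ppi a [ppi_network()].
#' @param drug_targets named list, drug id to character vector of target
#'   symbols. Targets absent from the PPI universe are dropped with a
#'   message.
#' @param kernel distance kernel, a function of numeric distance; default
#'   [gaussian_distance_kernel()].
#' @return non-negative scalar.
#' @examples
#' ppi <- ppi_network(data.frame(from = c("A", "B"), to = c("B", "C")))
#' gene_drug_closeness("A", "d1", ppi, list(d1 = "C"))  # exp(-4)
#' @export
gene_drug_closeness <- function(gene, drug, ppi, drug_targets,
                                kernel = gaussian_distance_kernel) {
  stopifnot(inherits(ppi, "ppi_network"))
  gene <- normalize_gene_symbol(gene)
  if (!gene %in% ppi$genes) stop("unknown gene: ", gene, call. = FALSE)
  cm <- closeness_matrix(ppi, drug_targets[drug], genes = gene, kernel = kernel)
  as.numeric(cm[1L, 1L])
}

#' Gene-by-drug closeness matrix
#'
#' Computes [gene_drug_closeness()] for every (gene, drug) pair in one pass:
#' one BFS distance matrix from the genes to the union of all drug targets,
#' then per-drug kernel sums.
#'
#' @inheritParams gene_drug_closeness
#' @param genes genes to score (rows); default the whole PPI universe.
#' @return numeric matrix, `genes` x `names(drug_targets)`.
#' @export
closeness_matrix <- function(ppi, drug_targets, genes = ppi$genes,
                             kernel = gaussian_distance_kernel) {
  stopifnot(inherits(ppi, "ppi_network"), is.list(drug_targets))
  if (length(drug_targets) == 0L) stop("no drugs supplied", call. = FALSE)
  if (is.null(names(drug_targets)) || any(!nzchar(names(drug_targets)))) {
    stop("drug_targets must be a named list", call. = FALSE)
  }
  genes <- normalize_gene_symbol(genes)
  unknown <- setdiff(genes, ppi$genes)
  if (length(unknown)) {
    stop("gene(s) outside the PPI universe: ",
         paste(head(unknown, 5L), collapse = ", "), call. = FALSE)
  }
  drug_targets <- lapply(drug_targets, normalize_gene_symbol)
  known <- lapply(drug_targets, intersect, ppi$genes)
  n_dropped <- sum(lengths(drug_targets)) - sum(lengths(known))
  if (n_dropped > 0L) {
    message(n_dropped, " drug target(s) absent from the PPI universe; dropped")
  }
  empty <- lengths(known) == 0L
  if (any(empty)) {
    stop("drug(s) with zero mapped targets: ",
         paste(names(known)[empty], collapse = ", "), call. = FALSE)
  }
  g <- as_igraph_ppi(ppi)
  all_targets <- unique(unlist(known, use.names = FALSE))
  d <- igraph::distances(g, v = genes, to = all_targets, algorithm = "unweighted")
  k <- kernel(d)
  k[!is.finite(d)] <- 0
  out <- vapply(known, function(tg) {
    rowSums(k[, tg, drop = FALSE])
  }, numeric(length(genes)))
  if (length(genes) == 1L) out <- matrix(out, nrow = 1L,
                                         dimnames = list(genes, names(known)))
  rownames(out) <- genes
  out
}

#' Concordance score of one compound-gene pair
#'
#' Pearson correlation, across reference drugs, between the compound's
#' chemical-similarity vector and the gene's network-closeness vector. If
#' either vector has zero variance the score is defined as 0 (a
#' constant-closeness gene carries no evidence, and the ranking stays
#' total).
#'
#' @param compound compound id (row of `sim`).
#' @param gene gene symbol.
#' @param sim compound x drug similarity matrix.
#' @inheritParams gene_drug_closeness
#' @return scalar in `[-1, 1]`.
#' @export
concordance_score <- function(compound, gene, sim, ppi, drug_targets,
                              kernel = gaussian_distance_kernel) {
  if (!compound %in% rownames(sim)) {
    stop("unknown compound: ", compound, call. = FALSE)
  }
  drugs <- colnames(sim)
  if (length(drugs) < 3L) {
    stop("concordance needs >= 3 reference drugs; got ", length(drugs),
         call. = FALSE)
  }
  if (!all(drugs %in% names(drug_targets))) {
    stop("similarity matrix names drugs with no target mapping", call. = FALSE)
  }
  x <- as.numeric(sim[compound, drugs])
  y <- as.numeric(closeness_matrix(ppi, drug_targets[drugs], genes = gene,
                                   kernel = kernel))
  pearson_or_zero(x, y)
}

# Pearson with the zero-variance convention
pearson_or_zero <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  as.numeric(cor(x, y))
}

#' Score all compounds against candidate genes
#'
#' Dense concordance scoring: every compound in the similarity matrix
#' against every candidate gene, with per-compound ranks. Ranks run 1 (best)
#' to `length(candidate_genes)`; ties on the score are broken by ascending
#' gene symbol, so the rank column is always a permutation of
#' `1..n_candidates`.
#'
#' @inheritParams concordance_score
#' @param candidate_genes genes to score; default the whole PPI universe.
#' @return object of class `target_profiles`: list with numeric matrices
#'   `scores` and `ranks` (compounds x candidate genes), plus `drugs`.
#' @export
score_compounds <- function(sim, ppi, drug_targets,
                            candidate_genes = ppi$genes,
                            kernel = gaussian_distance_kernel) {
  stopifnot(is.matrix(sim), inherits(ppi, "ppi_network"))
  candidate_genes <- unique(normalize_gene_symbol(candidate_genes))
  if (length(candidate_genes) == 0L) stop("empty candidate set", call. = FALSE)
  if (!all(candidate_genes %in% ppi$genes)) {
    stop("candidate genes outside the PPI universe", call. = FALSE)
  }
  drugs <- colnames(sim)
  if (length(drugs) < 3L) {
    stop("concordance needs >= 3 reference drugs; got ", length(drugs),
         call. = FALSE)
  }
  if (!all(drugs %in% names(drug_targets))) {
    stop("similarity matrix names drugs with no target mapping", call. = FALSE)
  }
  clo <- closeness_matrix(ppi, drug_targets[drugs], genes = candidate_genes,
                          kernel = kernel)
  m <- length(drugs)
  zr <- function(mat) {
    mu <- rowMeans(mat)
    sd_ <- sqrt(rowSums((mat - mu)^2) / (m - 1L))
    z <- (mat - mu) / ifelse(sd_ == 0, 1, sd_)
    z[sd_ == 0, ] <- 0
    z
  }
  zs <- zr(sim[, drugs, drop = FALSE])
  zg <- zr(clo)
  scores <- tcrossprod(zs, zg) / (m - 1L)
  scores <- pmin(pmax(scores, -1), 1)  # clamp tiny FP excursions
  dimnames(scores) <- list(rownames(sim), candidate_genes)

  ranks <- matrix(NA_integer_, nrow = nrow(scores), ncol = ncol(scores),
                  dimnames = dimnames(scores))
  sym_order <- order(colnames(scores))
  for (i in seq_len(nrow(scores))) {
    ord <- sym_order[order(-scores[i, sym_order])]  # stable: symbol asc within ties
    ranks[i, ord] <- seq_len(ncol(scores))
  }
  structure(list(scores = scores, ranks = ranks, drugs = drugs),
            class = "target_profiles")
}

#' @export
print.target_profiles <- function(x, ...) {
  cat(sprintf("Putative target profiles: %d compounds x %d candidate genes (%d drugs)\n",
              nrow(x$scores), ncol(x$scores), length(x$drugs)))
  invisible(x)
}

#' Ranked target profile of one compound
#'
#' @inheritParams score_compounds
#' @param compound compound id.
#' @return data frame with columns `gene`, `score`, `rank`, sorted by rank.
#' @export
build_target_profile <- function(compound, sim, ppi, drug_targets,
                                 candidate_genes = ppi$genes,
                                 kernel = gaussian_distance_kernel) {
  if (!compound %in% rownames(sim)) {
    stop("unknown compound: ", compound, call. = FALSE)
  }
  prof <- score_compounds(sim[compound, , drop = FALSE], ppi, drug_targets,
                          candidate_genes, kernel)
  df <- data.frame(gene = colnames(prof$scores),
                   score = as.numeric(prof$scores[1L, ]),
                   rank = as.integer(prof$ranks[1L, ]),
                   stringsAsFactors = FALSE)
  df[order(df$rank), , drop = FALSE]
}

# internal: genes in a compound's top-k list
top_k_genes <- function(profiles, compound, top_k) {
  r <- profiles$ranks[compound, ]
  names(r)[r <= top_k]
}

#' Call putative targets of one herb
#'
#' The herb's putative target set is the union, over its compounds, of each
#' compound's top-`top_k` ranked genes; the per-gene hit count is the number
#' of the herb's compounds whose top-`top_k` list contains the gene.
#'
#' @param herb herb id.
#' @param profiles a [score_compounds()] result.
#' @param herb_compounds data frame with columns `herb`, `compound`.
#' @param top_k profile cutoff defining a "hit" (default 100).
#' @return data frame with columns `herb`, `gene`, `hits`, sorted by
#'   decreasing hits then gene symbol.
#' @export
call_putative_targets <- function(herb, profiles, herb_compounds, top_k = 100) {
  stopifnot(inherits(profiles, "target_profiles"))
  top_k <- check_count(top_k, "top_k")
  compounds <- herb_compounds$compound[herb_compounds$herb == herb]
  if (length(compounds) == 0L) stop("unknown herb: ", herb, call. = FALSE)
  if (!all(compounds %in% rownames(profiles$ranks))) {
    stop("herb '", herb, "' lists compounds with no profile", call. = FALSE)
  }
  hits <- table(unlist(lapply(compounds, top_k_genes, profiles = profiles,
                              top_k = top_k)))
  df <- data.frame(herb = herb, gene = names(hits),
                   hits = as.integer(hits), stringsAsFactors = FALSE)
  df[order(-df$hits, df$gene), , drop = FALSE]
}

#' Call putative targets for every herb
#'
#' @inheritParams call_putative_targets
#' @return data frame with columns `herb`, `gene`, `hits` (one row per
#'   herb-gene pair), of class `herb_targets`.
#' @export
herb_putative_targets <- function(profiles, herb_compounds, top_k = 100) {
  herbs <- unique(herb_compounds$herb)
  out <- do.call(rbind, lapply(herbs, call_putative_targets,
                               profiles = profiles,
                               herb_compounds = herb_compounds, top_k = top_k))
  rownames(out) <- NULL
  class(out) <- c("herb_targets", "data.frame")
  out
}

#' @rdname netpharm-io
#' @export
write_profiles_tsv <- function(x, path) {
  stopifnot(inherits(x, "target_profiles"))
  long <- data.frame(
    compound = rep(rownames(x$scores), times = ncol(x$scores)),
    gene = rep(colnames(x$scores), each = nrow(x$scores)),
    score = as.numeric(x$scores),
    rank = as.integer(x$ranks),
    stringsAsFactors = FALSE
  )
  long <- long[order(long$compound, long$rank), , drop = FALSE]
  write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname netpharm-io
#' @export
write_herb_targets_tsv <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
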