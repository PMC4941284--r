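#' Topological measures of every network node
#'
#' Computes, on the untyped undirected simple graph (all nodes including
#' herbs, all edges regardless of type):
#'
#' * **degree** -- incident edge count;
#' * **betweenness** -- sum over unordered node pairs `(s, t)` of the
#'   fraction of unweighted shortest `s`-`t` paths passing through the node
#'   (unnormalized by default);
#' * **closeness** -- harmonic centrality `sum(1 / d(v, u))` by default,
#'   with `1/Inf = 0` so disconnected graphs are handled gracefully;
#'   classic variants are selectable;
#' * **k_core** (k-coreness) -- the largest `k` such that the node survives
#'   iterative deletion of nodes with degree `< k`.
#'
#' @param network a [assemble_network()] result or an `igraph` graph.
#' @param closeness one of `"harmonic"` (default), `"classic_inverse_farness"`
#'   (`1 / sum(d)`; 0 if any node is unreachable) or
#'   `"classic_times_n_minus_1"` (`(n-1) / sum(d)`).
#' @param betweenness_normalized divide betweenness by the number of
#'   considered pairs `(n-1)(n-2)/2`? Default `FALSE`.
#' @param ... passed between methods.
#' @return a `topology_table`: data frame with columns `node`, `role`,
#'   `degree`, `betweenness`, `closeness`, `k_core`, one row per node.
#' @examples
#' g <- igraph::make_graph(~ A - B - C)
#' compute_topology(g)  # B: betweenness 1, harmonic closeness 2
#' @export
compute_topology <- function(network, ...) UseMethod("compute_topology")

#' @rdname compute_topology
#' @export
compute_topology.tripartite_network <- function(network,
                                                closeness = c("harmonic",
                                                              "classic_inverse_farness",
                                                              "classic_times_n_minus_1"),
                                                betweenness_normalized = FALSE,
                                                ...) {
  g <- as_igraph_tripartite(network)
  tab <- topology_of_graph(g, match.arg(closeness), betweenness_normalized)
  tab$role <- network$nodes$role[match(tab$node, network$nodes$node)]
  tab <- tab[, c("node", "role", "degree", "betweenness", "closeness", "k_core")]
  class(tab) <- c("topology_table", "data.frame")
  tab
}

#' @rdname compute_topology
#' @export
compute_topology.igraph <- function(network,
                                    closeness = c("harmonic",
                                                  "classic_inverse_farness",
                                                  "classic_times_n_minus_1"),
                                    betweenness_normalized = FALSE, ...) {
  tab <- topology_of_graph(network, match.arg(closeness),
                           betweenness_normalized)
  tab$role <- NA_character_
  tab <- tab[, c("node", "role", "degree", "betweenness", "closeness", "k_core")]
  class(tab) <- c("topology_table", "data.frame")
  tab
}

topology_of_graph <- function(g, closeness_variant, betweenness_normalized) {
  if (igraph::vcount(g) == 0L) stop("empty network", call. = FALSE)
  n <- igraph::vcount(g)
  deg <- igraph::degree(g, loops = FALSE)
  btw <- igraph::betweenness(g, directed = FALSE, weights = NA,
                             normalized = isTRUE(betweenness_normalized))
  clo <- switch(closeness_variant,
    harmonic = igraph::harmonic_centrality(g, weights = NA,
                                           normalized = FALSE),
    classic_inverse_farness = ,
    classic_times_n_minus_1 = {
      d <- igraph::distances(g, algorithm = "unweighted")
      far <- rowSums(d) # includes d(v,v)=0; Inf when anything unreachable
      cl <- ifelse(is.finite(far) & far > 0, 1 / far, 0)
      if (closeness_variant == "classic_times_n_minus_1") cl <- cl * (n - 1L)
      if (n == 1L) cl <- 0
      cl
    }
  )
  kc <- igraph::coreness(g)
  data.frame(node = igraph::V(g)$name,
             degree = as.numeric(deg),
             betweenness = as.numeric(btw),
             closeness = as.numeric(clo),
             k_core = as.integer(kc),
             stringsAsFactors = FALSE)
}

#' Median thresholds of the four topological measures
#'
#' Sample median of each column of a topology table; for an even number of
#' nodes the mean of the two central order statistics.
#'
#' @param table a [compute_topology()] result.
#' @return object of class `median_thresholds`: named list `degree_med`,
#'   `betweenness_med`, `closeness_med`, `kcore_med`.
#' @export
median_thresholds <- function(table) {
  stopifnot(inherits(table, "topology_table"), nrow(table) > 0L)
  structure(list(
    degree_med = median(table$degree),
    betweenness_med = median(table$betweenness),
    closeness_med = median(table$closeness),
    kcore_med = median(table$k_core)
  ), class = "median_thresholds")
}

#' @export
print.median_thresholds <- function(x, ...) {
  cat(sprintf("Median thresholds: degree %.2f, betweenness %.2f, closeness %.2f, k-core %.2f\n",
              x$degree_med, x$betweenness_med, x$closeness_med, x$kcore_med))
  invisible(x)
}

#' Select major nodes by the all-above-median rule
#'
#' A node is major when its role is eligible and all four measures are
#' **strictly** greater than the corresponding threshold; a node sitting
#' exactly on any median is excluded. Herb nodes participate in the metric
#' computation and the medians but are not eligible by default (major nodes
#' are targets, not herbs).
#'
#' @param table a [compute_topology()] result.
#' @param thresholds a [median_thresholds()] result; defaults to the medians
#'   of `table` itself.
#' @param eligible_roles roles allowed into the selection; `NA` roles in the
#'   table (plain graphs) are treated as eligible when `NA` is included.
#' @return character vector of major node names, with attribute `counts`
#'   (named integer: selected nodes per role).
#' @export
select_major_nodes <- function(table, thresholds = median_thresholds(table),
                               eligible_roles = c("putative_target",
                                                  "known_disease_target",
                                                  "both")) {
  stopifnot(inherits(table, "topology_table"),
            inherits(thresholds, "median_thresholds"))
  if (length(eligible_roles) == 0L) {
    stop("eligible_roles must be non-empty", call. = FALSE)
  }
  eligible <- table$role %in% eligible_roles |
    (anyNA(eligible_roles) & is.na(table$role))
  sel <- eligible &
    table$degree > thresholds$degree_med &
    table$betweenness > thresholds$betweenness_med &
    table$closeness > thresholds$closeness_med &
    table$k_core > thresholds$kcore_med
  nodes <- table$node[sel]
  counts <- table(table$role[sel], useNA = "ifany")
  structure(nodes, counts = setNames(as.integer(counts), names(counts)))
}

#' @rdname netpharm-io
#' @param major optional character vector of major nodes; adds an
#'   `is_major` column.
#' @export
write_topology_tsv <- function(x, path, major = NULL) {
  stopifnot(inherits(x, "topology_table"))
  out <- as.data.frame(x)
  if (!is.null(major)) out$is_major <- out$node %in% major
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname netpharm-io
#' @export
write_thresholds_json <- function(x, path) {
  stopifnot(inherits(x, "median_thresholds"))
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
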