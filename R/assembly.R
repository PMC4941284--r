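#' Assemble the herb / putative-target / disease-target network
#'
#' Builds the tripartite pharmacological network: herb nodes linked to their
#' putative targets, plus the direct PPI edges whose both endpoints lie in
#' the combined putative-or-known gene set. Known disease genes that are not
#' putative targets and have no PPI edge into the network are dropped (a
#' node with no direct interaction has no place in a direct-interaction
#' network); the number dropped is reported via `message()` and kept on the
#' object.
#'
#' Node roles partition the network: `herb`, `putative_target`,
#' `known_disease_target`, and `both` for genes that are simultaneously
#' putative and known.
#'
#' @param herb_targets a [herb_putative_targets()] result (columns `herb`,
#'   `gene`, `hits`).
#' @param known_disease character vector of known disease gene symbols.
#' @param ppi a [ppi_network()].
#' @return object of class `tripartite_network`: list with `nodes` (data
#'   frame `node`, `role`), `edges` (data frame `from`, `to`, `type` with
#'   type in `herb_target`/`ppi`) and `dropped_known` (character).
#' @export
assemble_network <- function(herb_targets, known_disease, ppi) {
  stopifnot(is.data.frame(herb_targets), inherits(ppi, "ppi_network"))
  if (nrow(herb_targets) == 0L) stop("no herb-target links", call. = FALSE)
  known <- unique(normalize_gene_symbol(known_disease))
  if (length(known) == 0L) stop("empty disease-gene list", call. = FALSE)
  known_in <- intersect(known, ppi$genes)
  if (length(known_in) == 0L) {
    stop("no known disease gene maps into the gene universe", call. = FALSE)
  }
  if (length(known_in) < length(known)) {
    message(length(known) - length(known_in),
            " disease gene(s) absent from the gene universe; dropped")
  }

  putative <- unique(herb_targets$gene)
  pool <- union(putative, known_in)
  e <- ppi$edges
  ppi_edges <- e[e$from %in% pool & e$to %in% pool, , drop = FALSE]

  connected <- unique(c(ppi_edges$from, ppi_edges$to))
  isolated_known <- setdiff(known_in, union(putative, connected))
  if (length(isolated_known)) {
    message(length(isolated_known),
            " known disease gene(s) with no direct interaction; dropped")
  }
  known_kept <- setdiff(known_in, isolated_known)

  genes <- union(putative, known_kept)
  role <- ifelse(genes %in% putative & genes %in% known_kept, "both",
                 ifelse(genes %in% putative, "putative_target",
                        "known_disease_target"))
  herbs <- unique(herb_targets$herb)
  nodes <- rbind(
    data.frame(node = herbs, role = "herb", stringsAsFactors = FALSE),
    data.frame(node = genes, role = role, stringsAsFactors = FALSE)
  )
  nodes <- nodes[order(nodes$role != "herb", nodes$node), , drop = FALSE]
  rownames(nodes) <- NULL

  ht <- unique(herb_targets[, c("herb", "gene")])
  edges <- rbind(
    data.frame(from = ht$herb, to = ht$gene, type = "herb_target",
               stringsAsFactors = FALSE),
    data.frame(from = ppi_edges$from, to = ppi_edges$to, type = "ppi",
               stringsAsFactors = FALSE)
  )
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, dropped_known = isolated_known),
            class = "tripartite_network")
}

#' @export
print.tripartite_network <- function(x, ...) {
  s <- summary(x)
  cat(sprintf("Herb-target-disease network: %d nodes, %d edges\n",
              s$n_nodes, s$n_herb_target_edges + s$n_ppi_edges))
  cat(sprintf("  %d herbs, %d putative-only, %d known-only, %d overlap\n",
              s$n_herbs, s$n_putative_only, s$n_known_only, s$n_both))
  cat(sprintf("  %d herb-target edges, %d PPI edges\n",
              s$n_herb_target_edges, s$n_ppi_edges))
  invisible(x)
}

#' Composition summary of a tripartite network
#'
#' Counts nodes per role and edges per type. Because overlap genes are
#' single nodes of role `both`, two accountings are reported: exclusive
#' per-role counts (which sum to `n_nodes`) and inclusive totals
#' `n_putative_total` / `n_known_total` that count overlap genes in both
#' categories.
#'
#' @param object a [assemble_network()] result.
#' @param ... unused.
#' @return named list of counts.
#' @export
summary.tripartite_network <- function(object, ...) {
  role <- object$nodes$role
  type <- object$edges$type
  out <- list(
    n_nodes = nrow(object$nodes),
    n_herbs = sum(role == "herb"),
    n_putative_only = sum(role == "putative_target"),
    n_known_only = sum(role == "known_disease_target"),
    n_both = sum(role == "both"),
    n_herb_target_edges = sum(type == "herb_target"),
    n_ppi_edges = sum(type == "ppi"),
    n_dropped_known = length(object$dropped_known)
  )
  out$n_putative_total <- out$n_putative_only + out$n_both
  out$n_known_total <- out$n_known_only + out$n_both
  out$overlap <- out$n_both
  out
}

# internal: untyped undirected igraph over all nodes and edges
as_igraph_tripartite <- function(network) {
  stopifnot(inherits(network, "tripartite_network"))
  igraph::graph_from_data_frame(
    network$edges[, c("from", "to")], directed = FALSE,
    vertices = data.frame(name = network$nodes$node)
  )
}

#' @rdname netpharm-io
#' @export
write_network_tsv <- function(x, path) {
  stopifnot(inherits(x, "tripartite_network"))
  edges <- data.frame(source = x$edges$from, target = x$edges$to,
                      edge_type = x$edges$type, stringsAsFactors = FALSE)
  write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname netpharm-io
#' @export
write_node_roles_tsv <- function(x, path) {
  stopifnot(inherits(x, "tripartite_network"))
  write.table(x$nodes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname netpharm-io
#' @export
read_network_tsv <- function(path, node_path) {
  edges <- read.delim(path, stringsAsFactors = FALSE)
  nodes <- read.delim(node_path, stringsAsFactors = FALSE)
  structure(list(
    nodes = nodes,
    edges = data.frame(from = edges$source, to = edges$target,
                       type = edges$edge_type, stringsAsFactors = FALSE),
    dropped_known = character(0)
  ), class = "tripartite_network")
}

#' @rdname netpharm-io
#' @export
write_network_sif <- function(x, path) {
  stopifnot(inherits(x, "tripartite_network"))
  rel <- ifelse(x$edges$type == "ppi", "pp", "ht")
  writeLines(paste(x$edges$from, rel, x$edges$to, sep = "\t"), path)
  invisible(path)
}
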