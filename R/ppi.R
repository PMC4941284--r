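#' Protein-protein interaction network
#'
#' Container for an undirected simple PPI graph over gene symbols. Symbols
#' are normalized with [normalize_gene_symbol()]; self-loops and duplicate
#' (unordered) edges are removed.
#'
#' @param edges two-column character matrix or data frame of gene pairs.
#' @param genes optional character vector of the full gene universe; genes
#'   with no interaction are kept as isolated nodes. Defaults to the symbols
#'   appearing in `edges`.
#' @return object of class `ppi_network`: list with elements `genes`
#'   (character) and `edges` (data frame with columns `from`, `to`).
#' @seealso [generate_ppi()], [read_ppi_tsv()]
#' @export
ppi_network <- function(edges, genes = NULL) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) < 2L) stop("'edges' needs two columns", call. = FALSE)
  from <- normalize_gene_symbol(edges[[1L]])
  to <- normalize_gene_symbol(edges[[2L]])
  keep <- from != to & nzchar(from) & nzchar(to)
  from <- from[keep]; to <- to[keep]
  # canonical unordered orientation, then dedupe
  swap <- from > to
  tmp <- from[swap]; from[swap] <- to[swap]; to[swap] <- tmp
  dup <- duplicated(paste(from, to, sep = "\r"))
  from <- from[!dup]; to <- to[!dup]
  if (is.null(genes)) {
    genes <- sort(unique(c(from, to)))
  } else {
    genes <- sort(unique(normalize_gene_symbol(genes)))
    missing <- setdiff(unique(c(from, to)), genes)
    if (length(missing)) {
      stop("edge endpoints absent from the declared gene universe: ",
           paste(head(missing, 5L), collapse = ", "), call. = FALSE)
    }
  }
  structure(
    list(genes = genes,
         edges = data.frame(from = from, to = to, stringsAsFactors = FALSE)),
    class = "ppi_network"
  )
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("PPI network: %d genes, %d interactions\n",
              length(x$genes), nrow(x$edges)))
  invisible(x)
}

# internal: igraph view of a ppi_network (vertices = full gene universe)
as_igraph_ppi <- function(ppi) {
  stopifnot(inherits(ppi, "ppi_network"))
  igraph::graph_from_data_frame(ppi$edges, directed = FALSE,
                                vertices = data.frame(name = ppi$genes))
}
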