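#' Gene-set collection
#'
#' Named list of gene sets over a background universe. The default universe
#' is the union of all member genes (the standard self-contained background
#' for annotation-based over-representation analysis); it can be overridden,
#' e.g. with the full PPI gene universe.
#'
#' @param sets named list of character vectors of gene symbols.
#' @param universe optional background universe; must contain every member.
#' @return object of class `gene_set_collection`: list with `sets` (members
#'   normalized, deduplicated) and `universe`.
#' @export
gene_set_collection <- function(sets, universe = NULL) {
  stopifnot(is.list(sets))
  if (length(sets) == 0L) stop("empty gene-set collection", call. = FALSE)
  if (is.null(names(sets)) || anyDuplicated(names(sets)) ||
      any(!nzchar(names(sets)))) {
    stop("gene sets need unique non-empty names", call. = FALSE)
  }
  sets <- lapply(sets, function(s) unique(normalize_gene_symbol(s)))
  members <- sort(unique(unlist(sets, use.names = FALSE)))
  if (is.null(universe)) {
    universe <- members
  } else {
    universe <- sort(unique(normalize_gene_symbol(universe)))
    if (!all(members %in% universe)) {
      stop("gene-set members outside the declared universe", call. = FALSE)
    }
  }
  structure(list(sets = sets, universe = universe),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("Gene-set collection: %d sets (sizes %d-%d), universe %d genes\n",
              length(x$sets), min(lengths(x$sets)), max(lengths(x$sets)),
              length(x$universe)))
  invisible(x)
}

#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of drawing
#' at least `k` annotated genes when `n` genes are drawn without replacement
#' from a universe of `N` genes of which `K` are annotated. Computed through
#' `stats::phyper()`, which works in log space and is numerically stable for
#' extreme tails.
#'
#' @param k observed overlap (vectorized).
#' @param K pathway size in the universe.
#' @param n query size in the universe.
#' @param N universe size.
#' @return p-value(s) in `(0, 1]`.
#' @examples
#' hypergeom_upper_tail(5, 5, 5, 20)  # 1 / choose(20, 5)
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  if (any(k < 0 | K < 0 | n < 0 | N < 0) ||
      any(k != round(k) | K != round(K) | n != round(n) | N != round(N))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (any(K > N) || any(n > N)) stop("K and n cannot exceed N", call. = FALSE)
  if (any(k > pmin(K, n))) stop("k cannot exceed min(K, n)", call. = FALSE)
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Over-representation analysis with Bonferroni correction
#'
#' One-sided hypergeometric test of the overlap between a query gene set
#' and every pathway in a collection. The query is intersected with the
#' universe before counting (genes outside the background are dropped with
#' a message, mirroring annotation-based backgrounds); pathways with zero
#' overlap are tested but not reported. The Bonferroni factor `m` is the
#' total number of pathways in the collection, including zero-overlap ones.
#'
#' @param query character vector of gene symbols.
#' @param collection a [gene_set_collection()].
#' @param universe optional background override (e.g. all PPI genes);
#'   default `collection$universe`.
#' @param alpha significance level applied to the corrected p-value.
#' @return an `enrichment_table`: data frame with columns `pathway`, `k`
#'   (overlap), `K` (pathway size in universe), `n` (query size in
#'   universe), `N` (universe size), `p_raw`, `p_bonf`, `significant`,
#'   sorted by `p_bonf` then `p_raw` then name.
#' @export
enrich <- function(query, collection, universe = NULL, alpha = 0.05) {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (length(collection$sets) == 0L) {
    stop("empty gene-set collection", call. = FALSE)
  }
  if (!is.numeric(alpha) || alpha <= 0 || alpha > 1) {
    stop("alpha must lie in (0, 1]", call. = FALSE)
  }
  universe <- if (is.null(universe)) collection$universe else
    sort(unique(normalize_gene_symbol(universe)))
  query <- unique(normalize_gene_symbol(query))
  in_univ <- query %in% universe
  if (any(!in_univ)) {
    message(sum(!in_univ), " query gene(s) outside the universe; dropped")
  }
  query <- query[in_univ]
  if (length(query) == 0L) {
    stop("query and universe do not intersect", call. = FALSE)
  }
  N <- length(universe)
  n <- length(query)
  m <- length(collection$sets)
  rows <- lapply(names(collection$sets), function(nm) {
    members <- intersect(collection$sets[[nm]], universe)
    k <- length(intersect(members, query))
    if (k == 0L) return(NULL)
    data.frame(pathway = nm, k = k, K = length(members), n = n, N = N,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab)) {
    tab <- data.frame(pathway = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p_raw = numeric(0),
                      p_bonf = numeric(0), significant = logical(0))
  } else {
    tab$p_raw <- hypergeom_upper_tail(tab$k, tab$K, tab$n, tab$N)
    tab$p_bonf <- pmin(1, m * tab$p_raw)
    # alpha = 1 is the degenerate keep-everything boundary (p never exceeds 1)
    tab$significant <- if (alpha >= 1) rep(TRUE, nrow(tab)) else
      tab$p_bonf < alpha
    tab <- tab[order(tab$p_bonf, tab$p_raw, tab$pathway), , drop = FALSE]
    rownames(tab) <- NULL
  }
  attr(tab, "m_tested") <- m
  attr(tab, "alpha") <- alpha
  class(tab) <- c("enrichment_table", "data.frame")
  tab
}

# internal: 0-row enrichment table (no query gene maps into the universe)
empty_enrichment <- function(m, alpha) {
  tab <- data.frame(pathway = character(0), k = integer(0), K = integer(0),
                    n = integer(0), N = integer(0), p_raw = numeric(0),
                    p_bonf = numeric(0), significant = logical(0))
  attr(tab, "m_tested") <- m
  attr(tab, "alpha") <- alpha
  class(tab) <- c("enrichment_table", "data.frame")
  tab
}

#' @export
print.enrichment_table <- function(x, ...) {
  cat(sprintf("Over-representation analysis: %d/%d pathways with overlap, %d significant (alpha = %g, Bonferroni m = %d)\n",
              nrow(x), attr(x, "m_tested"), sum(x$significant),
              attr(x, "alpha"), attr(x, "m_tested")))
  if (nrow(x)) print.data.frame(head(as.data.frame(x), 10L), digits = 4)
  invisible(x)
}

#' @rdname netpharm-io
#' @export
write_enrichment_tsv <- function(x, path) {
  stopifnot(inherits(x, "enrichment_table"))
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
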