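#' Read and write pipeline input formats
#'
#' Plain-text readers and writers for the six pipeline inputs and the
#' intermediate artifacts. All readers normalize gene symbols through
#' [normalize_gene_symbol()].
#'
#' * PPI edge list: two-column TSV with header `from  to`, or SIF dialect
#'   (`A pp B`).
#' * Similarity matrix: TSV, compounds in rows (first column `compound`),
#'   reference drugs in columns.
#' * Drug-target map: TSV with columns `drug`, `target` (one row per pair).
#' * Herb-compound map: TSV with columns `herb`, `compound`.
#' * Disease genes: one symbol per line.
#' * Gene sets: GMT (name, description, then member genes, tab-separated).
#'
#' @param path file path.
#' @param x object to serialize.
#' @name netpharm-io
NULL

#' @rdname netpharm-io
#' @export
write_ppi_tsv <- function(x, path) {
  stopifnot(inherits(x, "ppi_network"))
  write.table(x$edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname netpharm-io
#' @param genes optional explicit gene universe (isolated genes are not
#'   recoverable from an edge list alone).
#' @export
read_ppi_tsv <- function(path, genes = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  ppi_network(df[, 1:2], genes = genes)
}

#' @rdname netpharm-io
#' @export
write_ppi_sif <- function(x, path) {
  stopifnot(inherits(x, "ppi_network"))
  writeLines(paste(x$edges$from, "pp", x$edges$to, sep = "\t"), path)
  invisible(path)
}

#' @rdname netpharm-io
#' @export
read_ppi_sif <- function(path, genes = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "[\t ]+")
  bad <- vapply(parts, length, 1L) < 3L
  if (any(bad)) stop("malformed SIF line(s): ", which(bad)[1L], call. = FALSE)
  ppi_network(data.frame(from = vapply(parts, `[`, "", 1L),
                         to = vapply(parts, `[`, "", 3L)), genes = genes)
}

#' @rdname netpharm-io
#' @export
write_similarity_tsv <- function(x, path) {
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
  df <- data.frame(compound = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname netpharm-io
#' @export
read_similarity_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  if (any(!is.finite(m))) stop("similarity matrix has non-finite entries",
                               call. = FALSE)
  m
}

#' @rdname netpharm-io
#' @export
write_drug_targets_tsv <- function(x, path) {
  df <- data.frame(
    drug = rep(names(x), lengths(x)),
    target = unlist(x, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname netpharm-io
#' @export
read_drug_targets_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  split(normalize_gene_symbol(df$target), df$drug)
}

#' @rdname netpharm-io
#' @export
write_herb_compounds_tsv <- function(x, path) {
  stopifnot(is.data.frame(x), all(c("herb", "compound") %in% names(x)))
  write.table(x[, c("herb", "compound")], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname netpharm-io
#' @export
read_herb_compounds_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  df[, c("herb", "compound")]
}

#' @rdname netpharm-io
#' @export
write_gene_list <- function(x, path) {
  writeLines(as.character(x), path)
  invisible(path)
}

#' @rdname netpharm-io
#' @export
read_gene_list <- function(path) {
  x <- readLines(path)
  unique(normalize_gene_symbol(x[nzchar(trimws(x))]))
}

#' @rdname netpharm-io
#' @param description character vector of per-set descriptions recycled to
#'   the number of sets.
#' @export
write_gmt <- function(x, path, description = "na") {
  sets <- if (inherits(x, "gene_set_collection")) x$sets else x
  stopifnot(is.list(sets), !is.null(names(sets)))
  description <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname netpharm-io
#' @param universe optional background universe passed on to
#'   [gene_set_collection()].
#' @export
read_gmt <- function(path, universe = NULL) {
  if (requireNamespace("fgsea", quietly = TRUE)) {
    sets <- fgsea::gmtPathways(path)
  } else {
    parts <- strsplit(readLines(path), "\t", fixed = TRUE)
    parts <- parts[vapply(parts, length, 1L) >= 3L]
    sets <- lapply(parts, function(p) p[-(1:2)])
    names(sets) <- vapply(parts, `[`, "", 1L)
  }
  gene_set_collection(sets, universe = universe)
}
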