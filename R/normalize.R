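#' Normalize gene symbols
#'
#' Single normalization shared by every reader and generator: trims
#' whitespace, uppercases, and strips hyphens, underscores and internal
#' spaces, so that symbol styles such as `"PPAR-g"` and `"PPARG"` (or
#' `"ncoa1"` and `"NCOA1"`) collapse to one identifier. All symbol lookups in
#' the package are performed on normalized symbols.
#'
#' @param x character vector of gene symbols.
#' @return character vector of normalized symbols.
#' @examples
#' normalize_gene_symbol(c(" ncoa1", "PPAR-G", "med_1"))
#' @export
normalize_gene_symbol <- function(x) {
  if (length(x) == 0L) return(character(0))
  toupper(gsub("[-_ ]+", "", trimws(as.character(x))))
}

# internal: stop unless all counts are positive whole numbers
check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x < min || x != round(x)) {
    stop(sprintf("'%s' must be a whole number >= %d", name, min), call. = FALSE)
  }
  as.integer(x)
}

check_fraction <- function(x, name, open_zero = TRUE) {
  lo_ok <- if (open_zero) x > 0 else x >= 0
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || !lo_ok || x > 1) {
    stop(sprintf("'%s' must be a fraction in %s0,1]", name,
                 if (open_zero) "(" else "["), call. = FALSE)
  }
  as.numeric(x)
}
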