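#' Hit times of a target under one herb
#'
#' The number of the herb's compounds whose top-`top_k` putative target
#' profile contains the target. This is the per-herb prediction-reliability
#' count: a gene hit by many independent compounds of the same herb is a
#' more trustworthy call than a one-off.
#'
#' @param target gene symbol.
#' @param herb herb id.
#' @inheritParams call_putative_targets
#' @return integer count (0 when the target never enters a top-`top_k`
#'   list).
#' @export
hit_times <- function(target, herb, profiles, herb_compounds, top_k = 100) {
  stopifnot(inherits(profiles, "target_profiles"))
  target <- normalize_gene_symbol(target)
  if (!target %in% colnames(profiles$ranks)) {
    stop("unknown target symbol: ", target, call. = FALSE)
  }
  compounds <- herb_compounds$compound[herb_compounds$herb == herb]
  if (length(compounds) == 0L) stop("unknown herb: ", herb, call. = FALSE)
  sum(profiles$ranks[compounds, target] <= top_k)
}

# internal: full per-herb ranking by hit times with the documented tie-break
herb_hit_ranking <- function(herb, profiles, herb_compounds, top_k) {
  compounds <- herb_compounds$compound[herb_compounds$herb == herb]
  if (length(compounds) == 0L) stop("unknown herb: ", herb, call. = FALSE)
  r <- profiles$ranks[compounds, , drop = FALSE]
  hits <- colSums(r <= top_k)
  mean_score <- colMeans(profiles$scores[compounds, , drop = FALSE])
  genes <- colnames(profiles$ranks)
  ord <- order(-hits, -mean_score, genes)
  data.frame(gene = genes[ord], hit_times = as.integer(hits[ord]),
             mean_score = as.numeric(mean_score[ord]),
             order = seq_along(genes), stringsAsFactors = FALSE)
}

#' Rank order of targets within a herb
#'
#' Ranks **all** candidate genes of the herb by hit times (descending),
#' breaking ties by mean concordance score across the herb's compounds
#' (descending) and then by gene symbol (ascending), and returns the
#' ordinal rank (1, 2, 3, ...) of each target of interest. Ordinal rather
#' than dense ranking is used so equal hit times still receive distinct
#' orders.
#'
#' @param herb herb id.
#' @param targets_of_interest non-empty character vector of gene symbols.
#' @inheritParams call_putative_targets
#' @return named integer vector of ranks.
#' @export
order_within_herb <- function(herb, targets_of_interest, profiles,
                              herb_compounds, top_k = 100) {
  stopifnot(inherits(profiles, "target_profiles"))
  targets_of_interest <- normalize_gene_symbol(targets_of_interest)
  if (length(targets_of_interest) == 0L) {
    stop("empty target set", call. = FALSE)
  }
  unknown <- setdiff(targets_of_interest, colnames(profiles$ranks))
  if (length(unknown)) {
    stop("unknown target symbol(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  ranking <- herb_hit_ranking(herb, profiles, herb_compounds, top_k)
  setNames(ranking$order[match(targets_of_interest, ranking$gene)],
           targets_of_interest)
}

#' Target-reliability table across herbs
#'
#' For each (target, herb) pair, the hit times and the target's ordinal
#' rank among all the herb's candidate genes, plus the conventional
#' `"hits(order)"` rendering (e.g. `"18(2)"`: hit by 18 compounds, second
#' most reliably predicted gene of that herb).
#'
#' @param targets character vector of gene symbols of interest.
#' @inheritParams call_putative_targets
#' @param herbs herbs to report; default all herbs in `herb_compounds`.
#' @return a `reliability_table`: data frame with columns `target`, `herb`,
#'   `hit_times`, `order`, `rendered`.
#' @export
reliability_table <- function(targets, profiles, herb_compounds,
                              top_k = 100,
                              herbs = unique(herb_compounds$herb)) {
  targets <- normalize_gene_symbol(targets)
  if (length(targets) == 0L) stop("empty target set", call. = FALSE)
  rows <- lapply(herbs, function(h) {
    ranking <- herb_hit_ranking(h, profiles, herb_compounds, top_k)
    i <- match(targets, ranking$gene)
    if (anyNA(i)) {
      stop("unknown target symbol(s): ",
           paste(targets[is.na(i)], collapse = ", "), call. = FALSE)
    }
    data.frame(target = targets, herb = h,
               hit_times = ranking$hit_times[i],
               order = ranking$order[i],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$rendered <- sprintf("%d(%d)", out$hit_times, out$order)
  rownames(out) <- NULL
  class(out) <- c("reliability_table", "data.frame")
  out
}

#' @export
print.reliability_table <- function(x, ...) {
  cat("Target reliability: hit times (order) per herb\n")
  wide <- tapply(x$rendered, list(x$target, x$herb), identity)
  print(as.data.frame(wide))
  invisible(x)
}

#' @rdname netpharm-io
#' @export
write_reliability_tsv <- function(x, path) {
  stopifnot(inherits(x, "reliability_table"))
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
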