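# Hypergeometric over-representation test for target-gene sets.

#' Read a gene-to-term annotation map
#'
#' @param path TSV with columns `gene_id`, `term_id` and optionally
#'   `term_name`.
#' @return data.frame with those columns (term_name defaults to term_id).
#' @export
read_term_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "term_id") %in% names(df))) {
    stop("term map needs gene_id and term_id columns: ", path)
  }
  if (!"term_name" %in% names(df)) df$term_name <- df$term_id
  df
}

#' Hypergeometric term over-representation
#'
#' For each term with m annotated genes in a universe of N genes, and a query
#' of n genes with k hits in the term, p is the upper-tail hypergeometric
#' probability of observing >= k hits. BH-adjusted values are reported
#' alongside; a term is significant iff raw p < `p_threshold` by default
#' (set `use_adjusted = TRUE` to gate on the adjusted value).
#'
#' @param query Character vector of query gene ids (must lie in the universe).
#' @param term_map data.frame as from [read_term_map].
#' @param universe Character vector of background gene ids; default all genes
#'   with at least one term annotation.
#' @param p_threshold Significance gate (default 0.05, strict).
#' @param use_adjusted Gate on BH-adjusted p instead of raw p.
#' @return data.frame: `term_id`, `term_name`, `k`, `m`, `n`, `N`,
#'   `fold_enrichment`, `p_value`, `p_adjusted`, `significant`, sorted by p.
#' @export
hypergeometric_enrichment <- function(query, term_map, universe = NULL,
                                      p_threshold = 0.05,
                                      use_adjusted = FALSE) {
  if (is.null(universe)) universe <- unique(term_map$gene_id)
  universe <- unique(universe)
  offenders <- setdiff(query, universe)
  if (length(offenders)) {
    stop("query genes outside the universe: ", paste(offenders, collapse = ", "))
  }
  term_map <- term_map[term_map$gene_id %in% universe, , drop = FALSE]
  query <- unique(query)
  N <- length(universe)
  n <- length(query)
  terms <- split(term_map, term_map$term_id)
  rows <- lapply(terms, function(tm) {
    genes <- unique(tm$gene_id)
    m <- length(genes)
    k <- length(intersect(query, genes))
    # upper tail: P(X >= k); k = 0 gives exactly 1
    p <- stats::phyper(k - 1, m, N - m, n, lower.tail = FALSE)
    data.frame(term_id = tm$term_id[1], term_name = tm$term_name[1],
               k = k, m = m, n = n, N = N,
               fold_enrichment = if (k > 0) (k / n) / (m / N) else 0,
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  out$p_adjusted <- benjamini_hochberg(out$p_value)
  gate <- if (use_adjusted) out$p_adjusted else out$p_value
  out$significant <- gate < p_threshold
  out <- out[order(out$p_value, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
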