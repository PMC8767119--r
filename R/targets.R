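# Cis and trans target-gene assignment for differential lncRNAs.

#' Pearson product-moment correlation
#'
#' @param x,y Equal-length numeric vectors (length >= 3).
#' @return The correlation coefficient, or `NA` when either vector is
#'   constant (the pair is then skipped by the callers).
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch: ", length(x), " vs ", length(y))
  if (length(x) < 3L) stop("at least 3 paired samples are required")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y, method = "pearson")
}

# orientation of a lncRNA relative to a gene, on the gene's strand;
# overlapping pairs are labelled by interval start order
lnc_orientation <- function(lnc_start, lnc_end, g_start, g_end, g_strand) {
  before <- if (lnc_end <= g_start) TRUE else if (lnc_start >= g_end) FALSE
    else lnc_start < g_start
  if (g_strand == "+") (if (before) "upstream" else "downstream")
  else (if (before) "downstream" else "upstream")
}

#' Assign cis target genes to differential lncRNAs
#'
#' Candidate genes are differential genes on the same chromosome whose
#' edge-to-edge distance from the lncRNA is at most `window` bp (inclusive
#' boundary, either strand; overlap counts as distance 0). A candidate is
#' retained iff |Pearson r| across all samples is at least `r_threshold`.
#'
#' @param del_ids Character vector of differential lncRNA ids.
#' @param deg_ids Character vector of differential gene ids.
#' @param ts A [transcript_set] containing all of them.
#' @param expr An [expression_matrix] (FPKM recommended) covering all ids.
#' @param window Window size in bp (default 100,000, inclusive).
#' @param r_threshold Correlation threshold (default 0.95, inclusive for cis).
#' @return data.frame: `lncRNA_id`, `gene_id`, `distance_bp`, `distance_kb`
#'   (2 decimals), `orientation` (lncRNA upstream/downstream of the gene on
#'   the gene's strand), `r`.
#' @export
assign_cis <- function(del_ids, deg_ids, ts, expr, window = 1e5,
                       r_threshold = 0.95) {
  stopifnot(inherits(ts, "transcript_set"), inherits(expr, "expression_matrix"))
  tr <- ts$transcripts
  missing <- setdiff(c(del_ids, deg_ids), tr$transcript_id)
  if (length(missing)) stop("ids absent from the annotation: ",
                            paste(missing, collapse = ", "))
  rows <- list()
  for (l in del_ids) {
    lt <- tr[tr$transcript_id == l, ]
    cand <- tr[tr$transcript_id %in% deg_ids & tr$chrom == lt$chrom, ]
    if (nrow(cand) == 0L) next
    d <- interval_gap(lt$start, lt$end, cand$start, cand$end)
    cand <- cand[d <= window, , drop = FALSE]
    d <- d[d <= window]
    for (k in seq_len(nrow(cand))) {
      r <- pearson_r(expr$values[l, ], expr$values[cand$transcript_id[k], ])
      if (!is.na(r) && abs(r) >= r_threshold) {
        rows[[paste(l, cand$transcript_id[k])]] <- data.frame(
          lncRNA_id = l, gene_id = cand$transcript_id[k],
          distance_bp = d[k], distance_kb = round(d[k] / 1e3, 2),
          orientation = lnc_orientation(lt$start, lt$end,
                                        cand$start[k], cand$end[k],
                                        cand$strand[k]),
          r = r, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
  else data.frame(lncRNA_id = character(), gene_id = character(),
                  distance_bp = numeric(), distance_kb = numeric(),
                  orientation = character(), r = numeric(),
                  stringsAsFactors = FALSE)
}

#' Assign trans target genes to differential lncRNAs
#'
#' Every lncRNA x gene pair is tested; pairs with |Pearson r| strictly above
#' `r_threshold` are retained. Pairs already reported by [assign_cis] are
#' excluded, so each pair carries one mechanism label.
#'
#' @param del_ids,deg_ids,expr As in [assign_cis].
#' @param cis_pairs Optional result of [assign_cis] used for exclusion.
#' @param r_threshold Correlation threshold (default 0.95, strict for trans).
#' @return data.frame: `lncRNA_id`, `gene_id`, `r`.
#' @export
assign_trans <- function(del_ids, deg_ids, expr, cis_pairs = NULL,
                         r_threshold = 0.95) {
  stopifnot(inherits(expr, "expression_matrix"))
  missing <- setdiff(c(del_ids, deg_ids), rownames(expr$values))
  if (length(missing)) stop("ids absent from the expression matrix: ",
                            paste(missing, collapse = ", "))
  cis_key <- if (!is.null(cis_pairs) && nrow(cis_pairs)) {
    paste(cis_pairs$lncRNA_id, cis_pairs$gene_id)
  } else character(0)
  rows <- list()
  for (l in del_ids) {
    for (gde in deg_ids) {
      if (paste(l, gde) %in% cis_key) next
      r <- pearson_r(expr$values[l, ], expr$values[gde, ])
      if (!is.na(r) && abs(r) > r_threshold) {
        rows[[paste(l, gde)]] <- data.frame(lncRNA_id = l, gene_id = gde,
                                            r = r, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
  else data.frame(lncRNA_id = character(), gene_id = character(), r = numeric(),
                  stringsAsFactors = FALSE)
}
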