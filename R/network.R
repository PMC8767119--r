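# Assembly and summary of the tripartite lncRNA-miRNA-mRNA network.

#' Build the lncRNA-miRNA-mRNA regulatory network
#'
#' Merges the upstream edge tables into one typed network. With the default
#' miRNA-anchored filter, a lncRNA node is kept only if it participates in at
#' least one miRNA edge (target or eTM), and an mRNA node is kept only if it
#' is reachable from a kept miRNA (miRNA target edge) or kept lncRNA
#' (cis/trans edge). `keep_all = TRUE` disables the filter and keeps every
#' input edge.
#'
#' @param cis data.frame from [assign_cis] (may be NULL/empty).
#' @param trans data.frame from [assign_trans].
#' @param mirna_targets Edge data.frame from [call_targets].
#' @param etms Edge data.frame from [call_etms].
#' @param precursors Edge data.frame from [identify_precursors].
#' @param node_classes Named character vector mapping every referenced id to
#'   `mRNA`, `lncRNA` or `miRNA`.
#' @param keep_all Disable the miRNA-anchored inclusion filter.
#' @return list with `edges` (source, target, edge_type, score, provenance),
#'   `nodes` (id, class, degree), and `summary` (node counts by class and
#'   edge counts by type).
#' @export
build_network <- function(cis = NULL, trans = NULL, mirna_targets = NULL,
                          etms = NULL, precursors = NULL, node_classes,
                          keep_all = FALSE) {
  as_edges <- function(df, type, src, tgt, score, provenance) {
    if (is.null(df) || nrow(df) == 0L) return(NULL)
    data.frame(source = df[[src]], target = df[[tgt]], edge_type = type,
               score = df[[score]],
               provenance = paste0(provenance, ":", seq_len(nrow(df))),
               stringsAsFactors = FALSE)
  }
  pick <- function(df) {
    if (is.null(df) || nrow(df) == 0L) return(NULL)
    data.frame(source = df$source, target = df$target,
               edge_type = df$edge_type, score = df$score,
               provenance = paste0(df$edge_type[1], ":", seq_len(nrow(df))),
               stringsAsFactors = FALSE)
  }
  edges <- rbind(as_edges(cis, "cis", "lncRNA_id", "gene_id", "r", "cis"),
                 as_edges(trans, "trans", "lncRNA_id", "gene_id", "r", "trans"),
                 pick(mirna_targets[, c("source", "target", "edge_type", "score")]),
                 pick(etms), pick(precursors[, c("source", "target", "edge_type", "score")]))
  if (is.null(edges)) {
    edges <- data.frame(source = character(), target = character(),
                        edge_type = character(), score = numeric(),
                        provenance = character(), stringsAsFactors = FALSE)
  }
  ids <- unique(c(edges$source, edges$target))
  missing <- setdiff(ids, names(node_classes))
  if (length(missing)) stop("node class undeclared for: ",
                            paste(missing, collapse = ", "))
  if (any(edges$source == edges$target)) stop("self-edges are not allowed")
  key <- paste(edges$source, edges$target, edges$edge_type)
  edges <- edges[!duplicated(key), , drop = FALSE]

  if (!keep_all && nrow(edges)) {
    cls <- node_classes
    mirna_edge <- edges$edge_type %in% c("miRNA_target_mRNA",
                                         "miRNA_target_lncRNA", "eTM",
                                         "precursor")
    lnc_with_mirna <- unique(c(
      edges$target[mirna_edge & cls[edges$target] == "lncRNA"],
      edges$source[mirna_edge & cls[edges$source] == "lncRNA"]))
    keep <- logical(nrow(edges))
    # miRNA edges: keep if any lncRNA endpoint is anchored (mRNA targets of
    # miRNAs are always reachable from the miRNA itself)
    for (i in seq_len(nrow(edges))) {
      e <- edges[i, ]
      ends <- c(e$source, e$target)
      lncs <- ends[cls[ends] == "lncRNA"]
      keep[i] <- if (length(lncs) == 0L) {
        e$edge_type %in% c("miRNA_target_mRNA")  # miRNA-mRNA direct edge
      } else all(lncs %in% lnc_with_mirna)
    }
    edges <- edges[keep, , drop = FALSE]
  }
  ids <- unique(c(edges$source, edges$target))
  deg <- table(factor(c(edges$source, edges$target), levels = ids))
  nodes <- data.frame(id = ids, class = unname(node_classes[ids]),
                      degree = as.integer(deg[ids]), stringsAsFactors = FALSE)
  summary <- list(
    nodes_by_class = as.data.frame(table(class = nodes$class),
                                   stringsAsFactors = FALSE),
    edges_by_type = as.data.frame(table(edge_type = edges$edge_type),
                                  stringsAsFactors = FALSE))
  rownames(edges) <- NULL
  list(edges = edges, nodes = nodes, summary = summary)
}
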