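#' Interaction edge table constructor
#'
#' @param source,target Character vectors of node ids.
#' @param edge_type One of `precursor`, `miRNA_target_mRNA`,
#'   `miRNA_target_lncRNA`, `eTM`, `cis`, `trans` (recycled).
#' @param score Numeric score; its semantics follow the edge type
#'   (expectation for miRNA target edges, alignment identity for precursor
#'   edges, Pearson r for cis/trans edges).
#' @return data.frame with columns `source`, `target`, `edge_type`, `score`.
#' @export
interaction_edges <- function(source = character(), target = character(),
                              edge_type = character(), score = numeric()) {
  valid <- c("precursor", "miRNA_target_mRNA", "miRNA_target_lncRNA",
             "eTM", "cis", "trans")
  df <- data.frame(source = as.character(source), target = as.character(target),
                   edge_type = as.character(edge_type), score = as.numeric(score),
                   stringsAsFactors = FALSE)
  if (nrow(df) && !all(df$edge_type %in% valid)) {
    stop("invalid edge_type: ",
         paste(unique(setdiff(df$edge_type, valid)), collapse = ", "))
  }
  df
}

#' Write a typed network to edge-list TSV or GraphML
#'
#' Every edge endpoint must have a declared node class (`mRNA`, `lncRNA`,
#' `miRNA`). The TSV format writes the edge list to `path` and the node table
#' to `<path>.nodes.tsv`; GraphML stores node class as a vertex attribute.
#' Both round-trip losslessly through [read_network].
#'
#' @param edges Edge data.frame as from [interaction_edges].
#' @param nodes data.frame with columns `id`, `class`.
#' @param path Output path.
#' @param format `"tsv"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(edges, nodes, path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  stopifnot(all(c("source", "target", "edge_type") %in% names(edges)),
            all(c("id", "class") %in% names(nodes)))
  if (!all(nodes$class %in% c("mRNA", "lncRNA", "miRNA"))) {
    stop("invalid node class: ",
         paste(setdiff(unique(nodes$class), c("mRNA", "lncRNA", "miRNA")),
               collapse = ", "))
  }
  unknown <- setdiff(c(edges$source, edges$target), nodes$id)
  if (length(unknown)) {
    stop("edges reference unknown nodes: ", paste(unknown, collapse = ", "))
  }
  if (!"score" %in% names(edges)) edges$score <- NA_real_
  if (format == "tsv") {
    utils::write.table(edges[, c("source", "target", "edge_type", "score")],
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(nodes[, c("id", "class")], paste0(path, ".nodes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    g <- igraph::graph_from_data_frame(
      edges[, c("source", "target", "edge_type", "score")],
      directed = TRUE,
      vertices = nodes[, c("id", "class")])
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read a network written by [write_network]
#'
#' @param path Path given to [write_network].
#' @param format `"tsv"` or `"graphml"`.
#' @return list with `edges` and `nodes` data.frames.
#' @export
read_network <- function(path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "tsv") {
    edges <- utils::read.delim(path, stringsAsFactors = FALSE)
    nodes <- utils::read.delim(paste0(path, ".nodes.tsv"),
                               stringsAsFactors = FALSE)
  } else {
    g <- igraph::read_graph(path, format = "graphml")
    el <- igraph::as_data_frame(g, what = "both")
    edges <- el$edges
    names(edges)[1:2] <- c("source", "target")
    nodes <- data.frame(id = el$vertices$name, class = el$vertices$class,
                        stringsAsFactors = FALSE)
  }
  edges$score <- as.numeric(edges$score)
  list(edges = edges, nodes = nodes)
}
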