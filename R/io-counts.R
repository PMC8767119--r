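#' Expression matrix container
#'
#' Features x samples matrix of non-negative values with per-sample group
#' labels and an explicit unit, so count/FPKM/TPM conversions are never
#' implicit.
#'
#' @param values Numeric matrix, features in rows (rownames required),
#'   samples in columns (colnames required). No negative entries.
#' @param groups Character/factor vector of group labels, one per column
#'   (e.g. `SRJC`/`DC`), or a named vector keyed by sample id.
#' @param unit One of `"count"`, `"FPKM"`, `"TPM"`.
#' @return An `expression_matrix` object.
#' @export
expression_matrix <- function(values, groups, unit = c("count", "FPKM", "TPM")) {
  unit <- match.arg(unit)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values must have feature rownames and sample colnames")
  }
  if (any(values < 0)) stop("negative entries are not allowed")
  if (!is.null(names(groups))) {
    missing <- setdiff(colnames(values), names(groups))
    if (length(missing)) stop("groups missing for samples: ",
                              paste(missing, collapse = ", "))
    groups <- groups[colnames(values)]
  }
  if (length(groups) != ncol(values)) {
    stop("groups must have one label per sample column")
  }
  structure(list(values = values,
                 groups = stats::setNames(as.character(groups), colnames(values)),
                 unit = unit),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix:", nrow(x$values), "features x", ncol(x$values),
      "samples, unit =", x$unit, "\n")
  cat("  groups:", paste(names(table(x$groups)), table(x$groups),
                         sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Write an expression matrix as TSV (plus a group sidecar)
#'
#' The matrix is written with a `feature_id` first column; group labels go to
#' `<path>.groups.tsv` (columns `sample_id`, `group`) since the matrix format
#' itself carries no group information.
#'
#' @param em An [expression_matrix].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(em, path) {
  stopifnot(inherits(em, "expression_matrix"))
  df <- data.frame(feature_id = rownames(em$values), em$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  gdf <- data.frame(sample_id = colnames(em$values), group = unname(em$groups),
                    stringsAsFactors = FALSE)
  utils::write.table(gdf, paste0(path, ".groups.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression matrix written by [write_counts]
#'
#' @param path TSV path; group labels are read from `<path>.groups.tsv`
#'   unless `groups` is given.
#' @param groups Optional named group vector overriding the sidecar.
#' @param unit Unit of the stored values.
#' @return An [expression_matrix].
#' @export
read_counts <- function(path, groups = NULL, unit = "count") {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "feature_id") stop("first column must be feature_id: ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$feature_id
  if (is.null(groups)) {
    gpath <- paste0(path, ".groups.tsv")
    if (!file.exists(gpath)) stop("group sidecar not found: ", gpath)
    g <- utils::read.delim(gpath, stringsAsFactors = FALSE)
    groups <- stats::setNames(g$group, g$sample_id)
  }
  expression_matrix(m, groups, unit)
}

# per-group means of an expression matrix, columns = groups
group_means <- function(em) {
  g <- factor(em$groups)
  sapply(levels(g), function(l) rowMeans(em$values[, g == l, drop = FALSE]))
}
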