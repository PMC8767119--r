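# Normalization and negative-binomial differential expression.

#' FPKM from raw counts
#'
#' FPKM = count / (transcript length in kb x mapped reads in millions), with
#' the per-sample mapped total taken as the column sum of the count matrix.
#' With `robust = TRUE` the per-sample totals are replaced by
#' median-of-ratios effective library sizes (size factor times the
#' geometric-mean library), which protects downstream co-expression analysis
#' from composition bias when a few features dominate a library.
#'
#' @param counts An [expression_matrix] with unit `"count"`.
#' @param lengths Named numeric vector of transcript lengths in nt (> 0),
#'   covering every feature.
#' @param robust Use median-of-ratios effective library sizes (default
#'   FALSE: plain column totals).
#' @return An [expression_matrix] with unit `"FPKM"`.
#' @export
compute_fpkm <- function(counts, lengths, robust = FALSE) {
  stopifnot(inherits(counts, "expression_matrix"))
  if (counts$unit != "count") stop("compute_fpkm needs raw counts")
  ids <- rownames(counts$values)
  missing <- setdiff(ids, names(lengths))
  if (length(missing)) stop("lengths missing for: ", paste(missing, collapse = ", "))
  len <- lengths[ids]
  if (any(len <= 0)) stop("non-positive transcript lengths")
  libs <- colSums(counts$values)
  if (any(libs == 0)) {
    stop("empty library (zero column sum): ",
         paste(colnames(counts$values)[libs == 0], collapse = ", "))
  }
  if (robust) {
    sf <- median_of_ratios(counts$values)
    libs <- sf * exp(mean(log(libs / sf)))
  }
  f <- sweep(counts$values / (len / 1e3), 2, libs / 1e6, "/")
  expression_matrix(f, counts$groups, "FPKM")
}

#' miRNA TPM normalization
#'
#' Per sample: normalized expression = mapped read count / total reads x 1e6,
#' so every non-empty column sums to exactly 1e6.
#'
#' @param counts An [expression_matrix] with unit `"count"`.
#' @return An [expression_matrix] with unit `"TPM"`.
#' @export
compute_mirna_tpm <- function(counts) {
  stopifnot(inherits(counts, "expression_matrix"))
  if (counts$unit != "count") stop("compute_mirna_tpm needs raw counts")
  libs <- colSums(counts$values)
  if (any(libs == 0)) {
    stop("empty library (zero column sum): ",
         paste(colnames(counts$values)[libs == 0], collapse = ", "))
  }
  expression_matrix(sweep(counts$values, 2, libs / 1e6, "/"),
                    counts$groups, "TPM")
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values: monotone, >= raw, capped at 1. NA values are
#'   passed through and excluded from the multiplicity count.
#' @export
benjamini_hochberg <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  m <- length(ok)
  if (m == 0L) return(out)
  o <- order(p[ok], decreasing = TRUE)
  ranks <- m:1L
  adj <- cummin(pmin(1, p[ok][o] * m / ranks))
  out[ok[o]] <- adj
  out
}

# DESeq-style median-of-ratios size factors
median_of_ratios <- function(counts) {
  lg <- log(counts)
  lg[!is.finite(lg)] <- NA
  loggeo <- rowMeans(lg)                 # NA when any sample has a zero
  use <- is.finite(loggeo)
  if (!any(use)) stop("no feature has positive counts in every sample; cannot normalize")
  sf <- apply(counts, 2, function(col) {
    r <- log(col[use]) - loggeo[use]
    exp(stats::median(r[is.finite(r)]))
  })
  if (any(!is.finite(sf) | sf <= 0)) stop("degenerate size factors")
  sf
}

#' Negative-binomial Wald differential-expression test
#'
#' One coherent NB pipeline: median-of-ratios library normalization,
#' per-feature method-of-moments dispersion moderated by a fitted
#' 1/mean trend (the estimate used is the maximum of the per-feature value
#' and the trend, floored at `dispersion_floor`), and a Wald test on the
#' log fold change with a normal approximation. The fold change is
#' log2((mean A + 0.5) / (mean B + 0.5)) on normalized counts. Features with
#' all-zero counts in both groups are excluded from testing and reported as
#' `not_DE` with NA p-values.
#'
#' Call rules (strict inequalities, configurable): mRNA/lncRNA features are
#' `up`/`down` iff |log2FC| > `lfc_threshold` and raw p < `p_threshold`;
#' miRNA features iff BH-adjusted p < `padj_threshold`.
#'
#' @param counts An [expression_matrix] of raw counts with exactly two
#'   groups and >= 2 replicates each.
#' @param feature_kind `"mRNA"`, `"lncRNA"` or `"miRNA"` (scalar or one per
#'   feature).
#' @param numerator Group label used as the fold-change numerator; default
#'   the first group level.
#' @param lfc_threshold,p_threshold Gates for mRNA/lncRNA calls (defaults 1
#'   and 0.05).
#' @param padj_threshold Gate for miRNA calls (default 0.05).
#' @param dispersion_floor Lower bound on the dispersion estimate.
#' @return data.frame: `feature_id`, `feature_kind`, `base_mean_A`,
#'   `base_mean_B` (normalized group means, A = numerator),
#'   `log2_fold_change`, `p_value`, `p_adjusted`, `call`.
#' @export
nb_differential_test <- function(counts, feature_kind = "mRNA",
                                 numerator = NULL,
                                 lfc_threshold = 1, p_threshold = 0.05,
                                 padj_threshold = 0.05,
                                 dispersion_floor = 1e-8) {
  stopifnot(inherits(counts, "expression_matrix"))
  if (counts$unit != "count") stop("nb_differential_test needs raw counts")
  g <- factor(counts$groups)
  if (nlevels(g) != 2L) stop("exactly two groups are required")
  if (any(table(g) < 2L)) stop("at least 2 replicates per group are required")
  if (is.null(numerator)) numerator <- levels(g)[1]
  if (!numerator %in% levels(g)) stop("unknown numerator group: ", numerator)
  A <- counts$values[, g == numerator, drop = FALSE]
  B <- counts$values[, g != numerator, drop = FALSE]
  if (all(colSums(A) == 0) || all(colSums(B) == 0)) {
    stop("a group is all-zero for every feature")
  }
  ids <- rownames(counts$values)
  kind <- rep(feature_kind, length.out = length(ids))

  sf <- median_of_ratios(counts$values)
  q <- sweep(counts$values, 2, sf, "/")
  qA <- q[, g == numerator, drop = FALSE]
  qB <- q[, g != numerator, drop = FALSE]
  nA <- ncol(qA); nB <- ncol(qB)
  mA <- rowMeans(qA); mB <- rowMeans(qB)
  vA <- apply(qA, 1, stats::var); vB <- apply(qB, 1, stats::var)

  tested <- mA + mB > 0
  # method-of-moments dispersion, pooled across groups
  vp <- ((nA - 1) * vA + (nB - 1) * vB) / (nA + nB - 2)
  mp <- (mA + mB) / 2
  araw <- ifelse(tested, (vp - mp) / mp^2, NA_real_)
  alpha <- pmax(araw, dispersion_floor)
  # moderation: fitted 1/mean trend; use the larger of trend and per-feature
  ok <- tested & is.finite(araw)
  if (sum(ok) >= 10L) {
    fit <- stats::lm(araw[ok] ~ I(1 / mp[ok]))
    co <- pmax(stats::coef(fit), 0)
    trend <- co[1] + co[2] / mp
    alpha <- pmax(alpha, ifelse(is.finite(trend), trend, dispersion_floor))
  }

  l2fc <- ifelse(tested, log2((mA + 0.5) / (mB + 0.5)), 0)
  se2 <- (mA + alpha * mA^2) / (nA * (mA + 0.5)^2) +
         (mB + alpha * mB^2) / (nB * (mB + 0.5)^2)
  z <- log((mA + 0.5) / (mB + 0.5)) / sqrt(se2)
  p <- ifelse(tested, 2 * stats::pnorm(-abs(z)), NA_real_)
  padj <- benjamini_hochberg(p)

  call <- rep("not_DE", length(ids))
  sig <- ifelse(kind == "miRNA",
                !is.na(padj) & padj < padj_threshold,
                !is.na(p) & p < p_threshold & abs(l2fc) > lfc_threshold)
  call[sig & l2fc > 0] <- "up"
  call[sig & l2fc < 0] <- "down"
  data.frame(feature_id = ids, feature_kind = kind,
             base_mean_A = mA, base_mean_B = mB,
             log2_fold_change = l2fc, p_value = p, p_adjusted = padj,
             call = call, stringsAsFactors = FALSE, row.names = NULL)
}
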