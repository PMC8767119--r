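# lncRNA identification cascade and positional classification.

#' Filter candidate transcripts for lncRNA discovery
#'
#' Applies, in order, the three removal predicates of the identification
#' cascade and logs per-step tallies: (1) transcripts with >= 1 bp exonic
#' same-strand overlap with a protein-coding gene; (2) transcripts whose
#' maximum FPKM across samples is below 0.5 (strict: exactly 0.5 is kept);
#' (3) transcripts shorter than 200 nt (spliced length; strict: exactly 200
#' is kept). The predicates are independent, so the surviving set does not
#' depend on the order; only the tallies do.
#'
#' @param ts A [transcript_set] of candidate transcripts.
#' @param fpkm An [expression_matrix] with unit `"FPKM"` covering every
#'   candidate.
#' @param coding A [transcript_set] of protein-coding gene models.
#' @param min_fpkm FPKM gate (default 0.5, max across samples, strict `<`
#'   removes).
#' @param min_length Length gate in nt (default 200, strict `<` removes).
#' @return list with `survivors` (a [transcript_set]) and `tally`
#'   (data.frame: step, removed, remaining).
#' @export
filter_candidates <- function(ts, fpkm, coding, min_fpkm = 0.5,
                              min_length = 200L) {
  stopifnot(inherits(ts, "transcript_set"), inherits(coding, "transcript_set"),
            inherits(fpkm, "expression_matrix"))
  if (fpkm$unit != "FPKM") stop("fpkm matrix unit must be FPKM, got ", fpkm$unit)
  ids <- ts$transcripts$transcript_id
  missing <- setdiff(ids, rownames(fpkm$values))
  if (length(missing)) {
    stop("transcripts absent from the FPKM matrix: ",
         paste(missing, collapse = ", "))
  }
  # step 1: exonic same-strand overlap with a coding gene
  olap <- exonic_same_strand_overlap(ts, coding)
  keep1 <- !olap
  # step 2: max FPKM across samples < 0.5
  maxf <- apply(fpkm$values[ids, , drop = FALSE], 1, max)
  keep2 <- maxf >= min_fpkm
  # step 3: spliced length < 200 nt
  keep3 <- ts$transcripts$length >= min_length
  tally <- data.frame(
    step = c("same_strand_exonic_overlap", "low_fpkm", "short"),
    removed = c(sum(!keep1), sum(keep1 & !keep2), sum(keep1 & keep2 & !keep3)),
    remaining = c(sum(keep1), sum(keep1 & keep2), sum(keep1 & keep2 & keep3)))
  surv <- ids[keep1 & keep2 & keep3]
  list(survivors = if (length(surv)) subset_transcripts(ts, surv) else NULL,
       survivor_ids = surv, tally = tally)
}

# TRUE per candidate transcript if any of its exons shares >= 1 bp
# same-strand overlap with any exon of a coding gene
exonic_same_strand_overlap <- function(ts, coding) {
  ce <- coding$exons
  vapply(ts$transcripts$transcript_id, function(tid) {
    e <- ts$exons[ts$exons$transcript_id == tid, ]
    hit <- FALSE
    for (r in seq_len(nrow(e))) {
      m <- ce$chrom == e$chrom[r] & ce$strand == e$strand[r] &
        interval_overlaps(ce$start, ce$end, e$start[r], e$end[r])
      if (any(m)) { hit <- TRUE; break }
    }
    hit
  }, TRUE)
}

#' Longest open reading frame across the three forward frames
#'
#' Scans ATG-to-stop ORFs (stop codons TAA/TAG/TGA) in frames 0, 1, 2 of the
#' given strand only. The ORF length excludes the stop codon.
#'
#' @param seq Nucleotide sequence (character scalar).
#' @return Longest ORF length in codons (0 when none).
#' @export
longest_orf <- function(seq) {
  n <- nchar(seq)
  if (n < 3L) return(0L)
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  best <- 0L
  stops <- c("TAA", "TAG", "TGA")
  for (frame in 0:2) {
    starts <- seq.int(1L + frame, n - 2L, by = 3L)
    if (length(starts) == 0L) next
    codons <- paste0(v[starts], v[starts + 1L], v[starts + 2L])
    open_at <- NA_integer_
    for (k in seq_along(codons)) {
      if (is.na(open_at)) {
        if (codons[k] == "ATG") open_at <- k
      } else if (codons[k] %in% stops) {
        best <- max(best, k - open_at)
        open_at <- NA_integer_
      }
    }
    # an ORF must terminate at a stop codon; an open run to the sequence end
    # does not count
  }
  best
}

#' Coding-potential surrogate
#'
#' A deterministic, dependency-free stand-in for coding-potential tools:
#' a transcript is classified `coding` iff its longest forward-frame
#' ATG-to-stop ORF is at least `threshold_codons` codons (default 100).
#' Sequences shorter than 3 nt are `noncoding` with ORF length 0.
#'
#' @param seq Nucleotide sequence.
#' @param threshold_codons Codon threshold (default 100).
#' @return list with `class` (`"coding"`/`"noncoding"`) and `orf_codons`.
#' @export
coding_potential_surrogate <- function(seq, threshold_codons = 100L) {
  orf <- longest_orf(seq)
  list(class = if (orf >= threshold_codons) "coding" else "noncoding",
       orf_codons = orf)
}

#' Positional classification of a lncRNA against gene models
#'
#' Classes: `lincRNA` (no overlap with any gene body on either strand),
#' `antisense` (overlap with an opposite-strand gene, exonic or intronic),
#' `sense` (same-strand overlap confined to intronic/non-exonic gene
#' regions), `overlapping` (the lncRNA fully contains a gene). When several
#' relations hold, precedence is overlapping > antisense > sense: the most
#' specific relation wins.
#'
#' @param ts A [transcript_set] containing the lncRNAs to classify.
#' @param genes A [transcript_set] of gene models.
#' @return Named character vector of classes, one per transcript in `ts`.
#' @export
classify_positional <- function(ts, genes) {
  stopifnot(inherits(ts, "transcript_set"), inherits(genes, "transcript_set"))
  g <- genes$transcripts
  out <- vapply(seq_len(nrow(ts$transcripts)), function(i) {
    l <- ts$transcripts[i, ]
    same <- g$chrom == l$chrom &
      interval_overlaps(g$start, g$end, l$start, l$end)
    if (!any(same)) return("lincRNA")
    gs <- g[same, ]
    if (any(l$start <= gs$start & l$end >= gs$end)) return("overlapping")
    if (any(gs$strand != l$strand)) return("antisense")
    "sense"
  }, "")
  stats::setNames(out, ts$transcripts$transcript_id)
}

#' Summaries of lncRNA length, exon count and positional class
#'
#' Length bins follow the conventional report layout: 200-600, 601-1000,
#' 1001-1400 and >1400 nt.
#'
#' @param records data.frame with columns `length`, `n_exons`,
#'   `positional_class` (as built by [discover_lncrnas]).
#' @return list of data.frames `length_bins`, `exon_counts`, `classes`, each
#'   with counts and percentages summing to 100 within rounding.
#' @export
summarize_features <- function(records) {
  if (nrow(records) == 0L) {
    warning("no lncRNA records to summarize")
    return(list(length_bins = data.frame(), exon_counts = data.frame(),
                classes = data.frame()))
  }
  bins <- cut(records$length, c(199.5, 600.5, 1000.5, 1400.5, Inf),
              labels = c("200-600", "601-1000", "1001-1400", ">1400"))
  lb <- as.data.frame(table(bin = bins), stringsAsFactors = FALSE)
  lb$percent <- 100 * lb$Freq / sum(lb$Freq)
  ec <- as.data.frame(table(n_exons = records$n_exons), stringsAsFactors = FALSE)
  ec$percent <- 100 * ec$Freq / sum(ec$Freq)
  cl <- as.data.frame(table(class = records$positional_class),
                      stringsAsFactors = FALSE)
  cl$percent <- 100 * cl$Freq / sum(cl$Freq)
  list(length_bins = lb, exon_counts = ec, classes = cl)
}

#' Run the full lncRNA discovery cascade
#'
#' Chains [filter_candidates], the ORF-based coding filter
#' ([coding_potential_surrogate]) and [classify_positional], and returns the
#' per-lncRNA record table plus the per-filter tally.
#'
#' @param candidates A [transcript_set] of assembled candidate transcripts.
#' @param coding A [transcript_set] of protein-coding genes.
#' @param fpkm FPKM [expression_matrix] covering the candidates.
#' @param seqs Named character vector of candidate spliced sequences.
#' @param orf_threshold Codon threshold of the coding surrogate.
#' @param min_fpkm,min_length Gates passed to [filter_candidates].
#' @return list with `records` (data.frame: transcript_id, positional_class,
#'   length, n_exons, per-group mean FPKM columns), `lncrnas` (a
#'   [transcript_set]), and `tally`.
#' @export
discover_lncrnas <- function(candidates, coding, fpkm, seqs,
                             orf_threshold = 100L, min_fpkm = 0.5,
                             min_length = 200L) {
  flt <- filter_candidates(candidates, fpkm, coding,
                           min_fpkm = min_fpkm, min_length = min_length)
  ids <- flt$survivor_ids
  missing <- setdiff(ids, names(seqs))
  if (length(missing)) stop("sequences missing for: ",
                            paste(missing, collapse = ", "))
  orf <- vapply(seqs[ids], longest_orf, 0L)
  noncoding <- ids[orf < orf_threshold]
  tally <- rbind(flt$tally,
                 data.frame(step = "coding_orf",
                            removed = length(ids) - length(noncoding),
                            remaining = length(noncoding)))
  if (length(noncoding) == 0L) {
    return(list(records = data.frame(), lncrnas = NULL, tally = tally))
  }
  lnc <- subset_transcripts(candidates, noncoding)
  cls <- classify_positional(lnc, coding)
  gm <- group_means(fpkm)
  records <- data.frame(
    transcript_id = lnc$transcripts$transcript_id,
    positional_class = unname(cls[lnc$transcripts$transcript_id]),
    length = lnc$transcripts$length,
    n_exons = lnc$transcripts$n_exons,
    stringsAsFactors = FALSE)
  gmx <- gm[records$transcript_id, , drop = FALSE]
  colnames(gmx) <- paste0("mean_FPKM_", colnames(gmx))
  records <- cbind(records, as.data.frame(gmx))
  rownames(records) <- NULL
  list(records = records, lncrnas = lnc, tally = tally)
}
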