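#' Transcript set container
#'
#' A `transcript_set` holds stranded, exon-structured transcript models in a
#' single fixed coordinate convention: 0-based, half-open `[start, end)`.
#' GTF/GFF3 readers and writers convert to/from the 1-based inclusive file
#' convention at the boundary, so window arithmetic (e.g. the 100 kb cis
#' window) never mixes conventions.
#'
#' @param transcripts data.frame with columns `transcript_id`, `gene_id`,
#'   `chrom`, `start`, `end`, `strand` (`+`/`-`) and `biotype` (one of
#'   `protein_coding`, `candidate`, `lncRNA`, `miRNA_precursor`).
#' @param exons data.frame with columns `transcript_id`, `chrom`, `start`,
#'   `end`, `strand`. Exons of one transcript must be non-overlapping, sorted
#'   by start, on the transcript's chrom/strand and within its bounds.
#' @return A `transcript_set` object. Two derived columns are added to
#'   `transcripts`: `length` (sum of exon widths, the spliced length) and
#'   `n_exons`.
#' @export
transcript_set <- function(transcripts, exons) {
  req_t <- c("transcript_id", "gene_id", "chrom", "start", "end", "strand", "biotype")
  req_e <- c("transcript_id", "chrom", "start", "end", "strand")
  if (!all(req_t %in% names(transcripts))) {
    stop("transcripts is missing columns: ",
         paste(setdiff(req_t, names(transcripts)), collapse = ", "))
  }
  if (!all(req_e %in% names(exons))) {
    stop("exons is missing columns: ",
         paste(setdiff(req_e, names(exons)), collapse = ", "))
  }
  transcripts <- as.data.frame(transcripts, stringsAsFactors = FALSE)
  exons <- as.data.frame(exons, stringsAsFactors = FALSE)
  if (anyDuplicated(transcripts$transcript_id)) {
    stop("duplicate transcript ids: ",
         paste(unique(transcripts$transcript_id[duplicated(transcripts$transcript_id)]),
               collapse = ", "))
  }
  validate_intervals(transcripts$start, transcripts$end, transcripts$strand,
                     what = "transcript")
  validate_intervals(exons$start, exons$end, exons$strand, what = "exon")
  if (!all(exons$transcript_id %in% transcripts$transcript_id)) {
    stop("exons reference unknown transcripts: ",
         paste(unique(setdiff(exons$transcript_id, transcripts$transcript_id)),
               collapse = ", "))
  }
  exons <- exons[order(match(exons$transcript_id, transcripts$transcript_id),
                       exons$start), , drop = FALSE]
  rownames(exons) <- NULL
  # per-transcript validation: containment, same chrom/strand, no overlap
  idx <- split(seq_len(nrow(exons)), exons$transcript_id)
  for (tid in transcripts$transcript_id) {
    i <- idx[[tid]]
    if (is.null(i) || length(i) == 0L) {
      stop("transcript without exons: ", tid)
    }
    tr <- transcripts[transcripts$transcript_id == tid, ]
    ex <- exons[i, ]
    if (any(ex$chrom != tr$chrom) || any(ex$strand != tr$strand)) {
      stop("exon on wrong chrom/strand for transcript ", tid)
    }
    if (any(ex$start < tr$start) || any(ex$end > tr$end)) {
      stop("exon outside transcript bounds for transcript ", tid)
    }
    if (nrow(ex) > 1L && any(ex$start[-1L] < ex$end[-nrow(ex)])) {
      stop("overlapping exons in transcript ", tid)
    }
  }
  lens <- vapply(split(exons$end - exons$start, exons$transcript_id), sum, 0)
  nex <- vapply(split(exons$end - exons$start, exons$transcript_id), length, 0L)
  transcripts$length <- unname(lens[transcripts$transcript_id])
  transcripts$n_exons <- unname(nex[transcripts$transcript_id])
  rownames(transcripts) <- NULL
  structure(list(transcripts = transcripts, exons = exons),
            class = "transcript_set")
}

validate_intervals <- function(start, end, strand, what = "interval") {
  if (any(start < 0)) stop(what, " with negative start")
  if (any(end <= start)) stop(what, " with end <= start (empty or inverted)")
  bad <- !strand %in% c("+", "-")
  if (any(bad)) {
    stop("unstranded or invalid strand for ", what, ": ",
         paste(unique(strand[bad]), collapse = ", "))
  }
  invisible(TRUE)
}

#' @export
print.transcript_set <- function(x, ...) {
  bt <- table(x$transcripts$biotype)
  cat("transcript_set:", nrow(x$transcripts), "transcripts,",
      nrow(x$exons), "exons\n")
  cat("  biotypes:", paste(names(bt), bt, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Subset a transcript set by transcript id
#'
#' @param ts A `transcript_set`.
#' @param ids Character vector of transcript ids to keep.
#' @return A `transcript_set` restricted to `ids`.
#' @export
subset_transcripts <- function(ts, ids) {
  stopifnot(inherits(ts, "transcript_set"))
  missing <- setdiff(ids, ts$transcripts$transcript_id)
  if (length(missing)) {
    stop("unknown transcript ids: ", paste(missing, collapse = ", "))
  }
  transcript_set(ts$transcripts[ts$transcripts$transcript_id %in% ids,
                                setdiff(names(ts$transcripts), c("length", "n_exons")),
                                drop = FALSE],
                 ts$exons[ts$exons$transcript_id %in% ids, , drop = FALSE])
}

# edge-to-edge gap between two half-open intervals on one sequence; 0 if they
# overlap or touch
interval_gap <- function(start1, end1, start2, end2) {
  pmax(0, pmax(start1, start2) - pmin(end1, end2))
}

interval_overlaps <- function(start1, end1, start2, end2) {
  start1 < end2 & start2 < end1
}
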