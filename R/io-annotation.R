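#' Read transcript models from GTF or GFF3
#'
#' Accepts Ensembl-dialect GTF (exon features carrying `gene_id` and
#' `transcript_id` attributes) or GFF3 (exon features carrying `Parent`,
#' with transcript-level features supplying `ID`/`Parent`). File coordinates
#' (1-based inclusive) are converted to the internal 0-based half-open
#' convention. Unstranded records are rejected.
#'
#' @param path Path to a `.gtf`, `.gff` or `.gff3` file.
#' @param format `"auto"` (from extension), `"gtf"` or `"gff3"`.
#' @return A [transcript_set].
#' @export
read_annotation <- function(path, format = c("auto", "gtf", "gff3")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  check_tabular_gff(path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "gtf") "gtf" else "gff3"
  }
  gr <- rtracklayer::import(path, format = if (format == "gtf") "gtf" else "gff3")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  if (format == "gtf") {
    ex <- df[df$type == "exon", , drop = FALSE]
    ex$tx <- ex$transcript_id
    ex$gene <- ex$gene_id
    tx_rows <- df[df$type == "transcript", , drop = FALSE]
    bt <- if ("biotype" %in% names(df)) {
      stats::setNames(tx_rows$biotype, tx_rows$transcript_id)
    } else NULL
    tx_bounds <- tx_rows
    tx_bounds$tx <- tx_bounds$transcript_id
    tx_bounds$gene <- tx_bounds$gene_id
  } else {
    tx_types <- c("transcript", "mRNA", "lnc_RNA", "ncRNA", "lincRNA")
    tx_rows <- df[df$type %in% tx_types, , drop = FALSE]
    ex <- df[df$type == "exon", , drop = FALSE]
    ex$tx <- vapply(ex$Parent, function(p) p[[1]], "")
    gene_of <- stats::setNames(vapply(tx_rows$Parent, function(p)
      if (length(p)) p[[1]] else NA_character_, ""), tx_rows$ID)
    ex$gene <- unname(gene_of[ex$tx])
    bt <- if ("biotype" %in% names(tx_rows)) {
      stats::setNames(tx_rows$biotype, tx_rows$ID)
    } else NULL
    tx_bounds <- tx_rows
    tx_bounds$tx <- tx_bounds$ID
    tx_bounds$gene <- unname(gene_of[tx_bounds$ID])
  }
  if (nrow(ex) == 0L) stop("no exon records in ", path)
  if (any(is.na(ex$tx))) stop("exon records without transcript_id in ", path)
  if (any(ex$strand == "*")) {
    stop("unstranded records (strand '.') are not allowed: transcripts ",
         paste(unique(ex$tx[ex$strand == "*"]), collapse = ", "))
  }
  exons <- data.frame(transcript_id = ex$tx, chrom = ex$seqnames,
                      start = ex$start - 1L, end = ex$end,
                      strand = ex$strand, stringsAsFactors = FALSE)
  if (nrow(tx_bounds) > 0L) {
    transcripts <- data.frame(
      transcript_id = tx_bounds$tx,
      gene_id = ifelse(is.na(tx_bounds$gene), tx_bounds$tx, tx_bounds$gene),
      chrom = tx_bounds$seqnames,
      start = tx_bounds$start - 1L, end = tx_bounds$end,
      strand = tx_bounds$strand, stringsAsFactors = FALSE)
  } else {
    # no transcript-level rows: infer bounds from the exon span
    sp <- split(exons, exons$transcript_id)
    transcripts <- do.call(rbind, lapply(sp, function(e) {
      data.frame(transcript_id = e$transcript_id[1],
                 gene_id = ex$gene[match(e$transcript_id[1], ex$tx)],
                 chrom = e$chrom[1], start = min(e$start), end = max(e$end),
                 strand = e$strand[1], stringsAsFactors = FALSE)
    }))
  }
  transcripts$biotype <- if (!is.null(bt)) {
    ifelse(is.na(bt[transcripts$transcript_id]), "candidate",
           unname(bt[transcripts$transcript_id]))
  } else "candidate"
  transcript_set(transcripts, exons)
}

# cheap structural pre-scan so malformed lines are reported with their number
check_tabular_gff <- function(path) {
  lines <- readLines(path, warn = FALSE)
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!nzchar(ln) || startsWith(ln, "#")) next
    nf <- length(strsplit(ln, "\t", fixed = TRUE)[[1]])
    if (nf < 9L) {
      stop("parse error at line ", i, " of ", path,
           ": expected 9 tab-separated fields, found ", nf)
    }
  }
  invisible(TRUE)
}

#' Write a transcript set as GTF
#'
#' Internal 0-based half-open coordinates are converted back to the 1-based
#' inclusive GTF convention, so a read/write round trip preserves file
#' coordinates exactly.
#'
#' @param ts A [transcript_set].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ts, path) {
  stopifnot(inherits(ts, "transcript_set"))
  tr <- ts$transcripts
  ex <- ts$exons
  attr9 <- function(gene, tx, biotype) {
    sprintf('gene_id "%s"; transcript_id "%s"; biotype "%s";', gene, tx, biotype)
  }
  bt <- stats::setNames(tr$biotype, tr$transcript_id)
  gid <- stats::setNames(tr$gene_id, tr$transcript_id)
  tl <- sprintf("%s\tlncnet\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
                tr$chrom, tr$start + 1L, tr$end, tr$strand,
                attr9(tr$gene_id, tr$transcript_id, tr$biotype))
  el <- sprintf("%s\tlncnet\texon\t%d\t%d\t.\t%s\t.\t%s",
                ex$chrom, ex$start + 1L, ex$end, ex$strand,
                attr9(gid[ex$transcript_id], ex$transcript_id,
                      bt[ex$transcript_id]))
  # transcript line followed by its exons, in transcript order
  ord <- order(match(ex$transcript_id, tr$transcript_id), ex$start)
  out <- character(0)
  el <- el[ord]
  ex_tx <- ex$transcript_id[ord]
  for (i in seq_len(nrow(tr))) {
    out <- c(out, tl[i], el[ex_tx == tr$transcript_id[i]])
  }
  writeLines(out, path)
  invisible(path)
}

#' Extract spliced transcript sequences from a genome
#'
#' Exon sequences are concatenated in genomic order and reverse-complemented
#' for minus-strand transcripts, so the result reads 5' to 3'.
#'
#' @param ts A [transcript_set].
#' @param genome Named character vector of chromosome sequences
#'   (DNA alphabet, as returned by [read_fasta]).
#' @return Named character vector of spliced sequences, one per transcript.
#' @export
extract_transcript_seqs <- function(ts, genome) {
  stopifnot(inherits(ts, "transcript_set"))
  missing <- setdiff(ts$transcripts$chrom, names(genome))
  if (length(missing)) stop("chromosomes missing from genome: ",
                            paste(missing, collapse = ", "))
  sp <- split(ts$exons, ts$exons$transcript_id)
  out <- vapply(ts$transcripts$transcript_id, function(tid) {
    e <- sp[[tid]]
    seqs <- substring(genome[[e$chrom[1]]], e$start + 1L, e$end)
    s <- paste(seqs, collapse = "")
    if (e$strand[1] == "-") s <- revcomp(s)
    s
  }, "")
  names(out) <- ts$transcripts$transcript_id
  out
}

#' Reverse complement of a DNA string
#'
#' @param x Character vector of DNA sequences (A/C/G/T/N).
#' @return Reverse-complemented sequences.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
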