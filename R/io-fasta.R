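#' Read a FASTA file into a normalized named character vector
#'
#' Sequences are uppercased and U is mapped to T so genomic logic and the
#' RNA duplex engine share one internal alphabet; pairing rules elsewhere are
#' stated on the RNA sense. Only A/C/G/T/U/N (any case) are accepted.
#'
#' @param path FASTA file path.
#' @return Named character vector; names are the first whitespace-delimited
#'   token of each header.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (any(Biostrings::width(ss) == 0L)) {
    stop("empty FASTA record: ",
         paste(ids[Biostrings::width(ss) == 0L], collapse = ", "))
  }
  seqs <- toupper(as.character(ss))
  seqs <- chartr("U", "T", seqs)
  bad <- regexpr("[^ACGTN]", seqs)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1]
    stop("illegal character in sequence '", ids[i], "' at position ", bad[i])
  }
  stats::setNames(seqs, ids)
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  ss <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}
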