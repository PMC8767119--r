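# miRNA-target duplex engine.
#
# The miRNA is read 5'->3' and paired against the target 3'->5', so miRNA
# position 1 (its 5' end) pairs the 3'-most nucleotide of the target window.
# Pair classes on the RNA sense (stored in the DNA alphabet, U == T):
#   WC  A:U, U:A, G:C, C:G            penalty 0
#   GU  G:U, U:G wobble               penalty 0.5
#   MM  anything else                 penalty 1.0
# One target-side bulge of 1..max_bulge_len unpaired target nucleotides is
# allowed, 0.5 penalty per bulged nucleotide. A bulge's "position" is the
# miRNA position immediately 5' of the insertion point. All penalties are
# doubled when the miRNA position (or bulge position) falls in the
# seed-weighted region, positions 2-13. The expectation of an alignment is
# the summed weighted penalty; targets are called at expectation <= 3 by
# default, mirroring the plant-target scoring convention.

DUPLEX_ALPHABET <- c("A", "C", "G", "T")

encode_seq <- function(seq) {
  v <- match(strsplit(seq, "", fixed = TRUE)[[1]], DUPLEX_ALPHABET)
  if (anyNA(v)) stop("sequence contains characters outside A/C/G/T")
  v
}

# base penalty and state lookup tables, rows = miRNA nt, cols = target nt
duplex_penalty_table <- function(gu_penalty = 0.5, mm_penalty = 1) {
  P <- matrix(mm_penalty, 4, 4, dimnames = list(DUPLEX_ALPHABET, DUPLEX_ALPHABET))
  wc <- rbind(c("A", "T"), c("T", "A"), c("G", "C"), c("C", "G"))
  P[wc] <- 0
  P[rbind(c("G", "T"), c("T", "G"))] <- gu_penalty
  P
}

duplex_state_table <- function() {
  S <- matrix("M", 4, 4, dimnames = list(DUPLEX_ALPHABET, DUPLEX_ALPHABET))
  S[rbind(c("A", "T"), c("T", "A"), c("G", "C"), c("C", "G"))] <- "W"
  S[rbind(c("G", "T"), c("T", "G"))] <- "G"
  S
}

# position weights: penalties doubled in the seed-weighted region
duplex_weights <- function(L, seed_region = 2:13) {
  w <- rep(1, L)
  w[intersect(seed_region, seq_len(L))] <- 2
  w
}

# target indices (1-based) paired by miRNA position i for windows starting at
# every 0-based offset s = 0..n_windows-1, given bulge length b after miRNA
# position p (b = 0, p = 0 for no bulge). W = L + b.
.pair_index_offset <- function(i, L, b, p) {
  (L + b) - i + 1L - if (b > 0L && i > p) b else 0L
}

#' Scan a target sequence for miRNA duplex alignments
#'
#' Slides the miRNA over every target window, with and without a single
#' target-side bulge, scores each alignment with the seed-weighted
#' expectation penalty, and returns every alignment at or below the
#' expectation threshold. See the package vignette for the scoring scheme.
#'
#' @param mirna miRNA sequence, 5' to 3' (18-30 nt; DNA or RNA alphabet).
#' @param target Target sequence (length >= miRNA length).
#' @param max_expectation Inclusive expectation threshold (default 3).
#' @param max_bulge_len Maximum bulge length in nt (default 3; 0 disables
#'   bulges).
#' @param bulge_positions Integer vector of allowed bulge positions (miRNA
#'   position immediately 5' of the insertion); default all of 1..L-1.
#' @param bulge_lens Allowed bulge lengths; default `1:max_bulge_len`.
#' @param gu_penalty,mm_penalty,bulge_penalty Penalty weights per G:U pair,
#'   mismatch, and bulged nucleotide.
#' @param seed_region miRNA positions whose penalties are doubled.
#' @param mirna_id,target_id Optional ids copied into the result.
#' @return data.frame with one row per qualifying alignment: `mirna_id`,
#'   `target_id`, `target_start`/`target_end` (0-based half-open window on
#'   the target), `bulge_len`, `bulge_after` (0 when bulge-free),
#'   `expectation`, and `states` (one character per miRNA position from its
#'   5' end: W/G/M). Sorted by expectation, then window start, then bulge.
#' @export
duplex_scan <- function(mirna, target, max_expectation = 3,
                        max_bulge_len = 3, bulge_positions = NULL,
                        bulge_lens = NULL,
                        gu_penalty = 0.5, mm_penalty = 1, bulge_penalty = 0.5,
                        seed_region = 2:13,
                        mirna_id = "miRNA", target_id = "target") {
  if (nchar(mirna) < 18L) {
    stop("miRNA shorter than 18 nt: ", mirna_id)
  }
  if (nchar(target) < nchar(mirna)) {
    stop("target shorter than the miRNA: ", target_id)
  }
  m <- encode_seq(mirna)
  t_ <- encode_seq(target)
  L <- length(m)
  n <- length(t_)
  P <- duplex_penalty_table(gu_penalty, mm_penalty)
  w <- duplex_weights(L, seed_region)
  if (is.null(bulge_lens)) bulge_lens <- if (max_bulge_len > 0) seq_len(max_bulge_len) else integer(0)
  combos <- rbind(data.frame(b = 0L, p = 0L),
                  expand.grid(b = as.integer(bulge_lens),
                              p = as.integer(if (is.null(bulge_positions))
                                seq_len(L - 1L) else bulge_positions)))
  hits <- vector("list", nrow(combos))
  for (k in seq_len(nrow(combos))) {
    b <- combos$b[k]; p <- combos$p[k]
    W <- L + b
    if (n < W) next
    nw <- n - W + 1L
    expv <- numeric(nw)
    for (i in seq_len(L)) {
      off <- .pair_index_offset(i, L, b, p)
      expv <- expv + w[i] * P[cbind(m[i], t_[off + 0:(nw - 1L)])]
    }
    if (b > 0L) {
      expv <- expv + b * bulge_penalty * (if (p %in% seed_region) 2 else 1)
    }
    keep <- which(expv <= max_expectation + 1e-9)
    if (length(keep)) {
      hits[[k]] <- data.frame(target_start = keep - 1L,
                              target_end = keep - 1L + W,
                              bulge_len = b, bulge_after = p,
                              expectation = expv[keep])
    }
  }
  out <- do.call(rbind, hits)
  if (is.null(out)) {
    out <- data.frame(target_start = integer(), target_end = integer(),
                      bulge_len = integer(), bulge_after = integer(),
                      expectation = numeric())
  }
  S <- duplex_state_table()
  out$states <- vapply(seq_len(nrow(out)), function(r) {
    b <- out$bulge_len[r]; p <- out$bulge_after[r]; s <- out$target_start[r]
    idx <- vapply(seq_len(L), .pair_index_offset, numeric(1), L = L, b = b, p = p) + s
    paste(S[cbind(m, t_[idx])], collapse = "")
  }, "")
  out <- cbind(data.frame(mirna_id = rep(mirna_id, nrow(out)),
                          target_id = rep(target_id, nrow(out)),
                          stringsAsFactors = FALSE), out)
  ord <- order(out$expectation, out$target_start, out$bulge_len, out$bulge_after)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# recompute the expectation of one alignment row from its states string and
# bulge annotation (used by invariant tests and the eTM re-validator)
expectation_from_states <- function(states, bulge_len, bulge_after,
                                    gu_penalty = 0.5, mm_penalty = 1,
                                    bulge_penalty = 0.5, seed_region = 2:13) {
  st <- strsplit(states, "", fixed = TRUE)[[1]]
  w <- duplex_weights(length(st), seed_region)
  pen <- ifelse(st == "M", mm_penalty, ifelse(st == "G", gu_penalty, 0))
  e <- sum(w * pen)
  if (bulge_len > 0) {
    e <- e + bulge_len * bulge_penalty * (if (bulge_after %in% seed_region) 2 else 1)
  }
  e
}

#' Call miRNA target edges over transcript sequences
#'
#' One edge is emitted per (miRNA, transcript) pair with at least one duplex
#' alignment at or below the expectation threshold; the best (lowest)
#' expectation and the number of distinct qualifying windows are reported.
#'
#' @param mirnas Named character vector of mature miRNA sequences.
#' @param seqs Named character vector of transcript sequences.
#' @param kinds Named character vector mapping transcript id to `"mRNA"` or
#'   `"lncRNA"` (drives the edge type).
#' @param max_expectation Expectation threshold (default 3).
#' @param ... Passed to [duplex_scan].
#' @return list with `edges` (source, target, edge_type, score = best
#'   expectation, n_sites) and `sites` (all qualifying alignments).
#' @export
call_targets <- function(mirnas, seqs, kinds, max_expectation = 3, ...) {
  missing <- setdiff(names(seqs), names(kinds))
  if (length(missing)) stop("kinds missing for: ", paste(missing, collapse = ", "))
  sites <- list()
  rows <- list()
  for (mid in names(mirnas)) {
    for (tid in names(seqs)) {
      h <- duplex_scan(mirnas[[mid]], seqs[[tid]],
                       max_expectation = max_expectation,
                       mirna_id = mid, target_id = tid, ...)
      if (nrow(h)) {
        sites[[paste(mid, tid)]] <- h
        rows[[paste(mid, tid)]] <- data.frame(
          source = mid, target = tid,
          edge_type = if (kinds[[tid]] == "mRNA") "miRNA_target_mRNA"
                      else "miRNA_target_lncRNA",
          score = min(h$expectation),
          n_sites = length(unique(h$target_start)),
          stringsAsFactors = FALSE)
      }
    }
  }
  list(edges = if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
       else cbind(interaction_edges(), n_sites = integer()),
       sites = if (length(sites)) do.call(rbind, c(sites, make.row.names = FALSE))
       else NULL)
}

#' Call endogenous target mimic (eTM) sites
#'
#' An alignment qualifies as an eTM site iff (i) miRNA positions 2-8 from the
#' 5' end are all Watson-Crick paired (G:U does not count as perfect); (ii)
#' the total number of mismatches plus G:U pairs across the pairing region,
#' bulge excluded, is at most `max_mm_gu`; and (iii) any bulge is target-side,
#' exactly `bulge_len` nucleotides, and inserted after miRNA positions
#' `bulge_window`. A bulge is permitted, not required, unless
#' `require_bulge = TRUE` (the canonical central-bulge reading).
#'
#' @param mirnas Named character vector of mature miRNA sequences.
#' @param seqs Named character vector of lncRNA sequences.
#' @param max_mm_gu Mismatch + G:U budget outside the bulge (default 3).
#' @param bulge_len Required bulge length when a bulge is present (default 3).
#' @param bulge_window Allowed bulge positions (default 9:12).
#' @param require_bulge Require the central bulge (default FALSE).
#' @return list with `edges` (one per qualifying miRNA-lncRNA pair, score =
#'   lowest mismatch+G:U count) and `sites` (qualifying alignments with
#'   window coordinates and states).
#' @export
call_etms <- function(mirnas, seqs, max_mm_gu = 3, bulge_len = 3,
                      bulge_window = 9:12, require_bulge = FALSE) {
  sites <- list()
  for (mid in names(mirnas)) {
    for (tid in names(seqs)) {
      h <- etm_scan_pair(mirnas[[mid]], seqs[[tid]], max_mm_gu, bulge_len,
                         bulge_window, require_bulge, mid, tid)
      if (nrow(h)) sites[[paste(mid, tid)]] <- h
    }
  }
  sites <- if (length(sites)) do.call(rbind, c(sites, make.row.names = FALSE)) else NULL
  edges <- if (!is.null(sites)) {
    agg <- stats::aggregate(mm_gu ~ mirna_id + target_id, data = sites, FUN = min)
    data.frame(source = agg$mirna_id, target = agg$target_id,
               edge_type = "eTM", score = agg$mm_gu, stringsAsFactors = FALSE)
  } else interaction_edges()
  list(edges = edges, sites = sites)
}

# search space for eTM sites: bulge-free alignments plus alignments with the
# one permitted bulge shape (exactly bulge_len nt at bulge_window)
etm_scan_pair <- function(mirna, target, max_mm_gu, bulge_len, bulge_window,
                          require_bulge, mirna_id, target_id) {
  m <- encode_seq(mirna)
  t_ <- encode_seq(target)
  L <- length(m)
  n <- length(t_)
  P <- duplex_penalty_table()
  S <- duplex_state_table()
  combos <- expand.grid(b = bulge_len, p = as.integer(bulge_window))
  if (!require_bulge) combos <- rbind(data.frame(b = 0L, p = 0L), combos)
  out <- list()
  for (k in seq_len(nrow(combos))) {
    b <- combos$b[k]; p <- combos$p[k]
    W <- L + b
    if (n < W || (b > 0L && p >= L)) next
    nw <- n - W + 1L
    n_imperfect <- integer(nw)   # MM + GU count over all miRNA positions
    seed_bad <- integer(nw)      # non-WC states among positions 2..8
    for (i in seq_len(L)) {
      off <- .pair_index_offset(i, L, b, p)
      pen <- P[cbind(m[i], t_[off + 0:(nw - 1L)])]
      bad <- pen > 0
      n_imperfect <- n_imperfect + bad
      if (i >= 2L && i <= 8L) seed_bad <- seed_bad + bad
    }
    keep <- which(seed_bad == 0L & n_imperfect <= max_mm_gu)
    if (length(keep)) {
      st <- vapply(keep, function(s0) {
        idx <- vapply(seq_len(L), .pair_index_offset, numeric(1), L = L, b = b, p = p) + (s0 - 1L)
        paste(S[cbind(m, t_[idx])], collapse = "")
      }, "")
      out[[k]] <- data.frame(mirna_id = mirna_id, target_id = target_id,
                             target_start = keep - 1L, target_end = keep - 1L + W,
                             bulge_len = b, bulge_after = p,
                             mm_gu = n_imperfect[keep], states = st,
                             stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(mirna_id = character(), target_id = character(),
                      target_start = integer(), target_end = integer(),
                      bulge_len = integer(), bulge_after = integer(),
                      mm_gu = integer(), states = character(),
                      stringsAsFactors = FALSE)
  }
  out <- out[order(out$target_start, out$bulge_len, out$bulge_after), , drop = FALSE]
  rownames(out) <- NULL
  out
}
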