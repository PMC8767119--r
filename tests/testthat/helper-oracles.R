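# Independent oracles used across the suite. Each re-derives its answer from
# the rule definitions with a different construction than the package code,
# so agreement is evidence, not tautology.

# --- duplex enumeration oracle -------------------------------------------
# Enumerates every window and every single-bulge placement, classifying each
# pair with explicit character-by-character rules on the reversed window.
oracle_pair_penalty <- function(a, b) {
  if ((a == "A" && b == "T") || (a == "T" && b == "A") ||
      (a == "G" && b == "C") || (a == "C" && b == "G")) return(0)
  if ((a == "G" && b == "T") || (a == "T" && b == "G")) return(0.5)
  1
}

oracle_pair_state <- function(a, b) {
  p <- oracle_pair_penalty(a, b)
  if (p == 0) "W" else if (p == 0.5) "G" else "M"
}

# Geometry, derived from scratch: reading the reversed window (target
# 3'->5'), miRNA position i sits at reversed-window index i, shifted by the
# bulge width once it has passed the insertion (i > p). Converting the
# reversed-window index r back to the forward target gives
# forward index = window_start + W - r (1-based). Every (window, bulge
# length, bulge position) triple is enumerated; penalties come from a
# string-keyed table.
oracle_duplex <- function(mirna, target, max_expectation = 3,
                          max_bulge = 3) {
  mc <- strsplit(mirna, "", fixed = TRUE)[[1]]
  tc <- strsplit(target, "", fixed = TRUE)[[1]]
  L <- length(mc)
  n <- length(tc)
  nts <- c("A", "C", "G", "T")
  keys <- as.vector(outer(nts, nts, paste0))
  pen_lut <- vapply(keys, function(k)
    oracle_pair_penalty(substr(k, 1, 1), substr(k, 2, 2)), 0)
  st_lut <- vapply(keys, function(k)
    oracle_pair_state(substr(k, 1, 1), substr(k, 2, 2)), "")
  combos <- rbind(cbind(b = 0L, p = 0L),
                  as.matrix(expand.grid(b = seq_len(max_bulge),
                                        p = seq_len(L - 1L))))
  rows <- list()
  for (k in seq_len(nrow(combos))) {
    b <- combos[k, "b"]; p <- combos[k, "p"]
    W <- L + b
    if (n < W) next
    nw <- n - W + 1L
    ev <- numeric(nw)
    aligned_idx <- integer(L)   # forward target index for window start 0
    for (i in seq_len(L)) {
      r <- i + if (b > 0L && i > p) b else 0L   # reversed-window index
      fwd <- W - r + 1L                          # forward index, window at 0
      aligned_idx[i] <- fwd
      slice <- tc[fwd + 0:(nw - 1L)]
      wgt <- if (i >= 2 && i <= 13) 2 else 1
      ev <- ev + wgt * unname(pen_lut[paste0(mc[i], slice)])
    }
    if (b > 0L) ev <- ev + 0.5 * b * (if (p >= 2 && p <= 13) 2 else 1)
    for (s in which(ev <= max_expectation) - 1L) {
      aligned <- tc[aligned_idx + s]
      rows[[length(rows) + 1L]] <- data.frame(
        target_start = s, target_end = s + W, bulge_len = b,
        bulge_after = p, expectation = ev[s + 1L],
        states = paste(unname(st_lut[paste0(mc, aligned)]), collapse = ""),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(target_start = integer(), target_end = integer(),
               bulge_len = integer(), bulge_after = integer(),
               expectation = numeric(), states = character(),
               stringsAsFactors = FALSE)
  out[order(out$expectation, out$target_start, out$bulge_len,
            out$bulge_after), , drop = FALSE]
}

# --- brute-force ORF oracle ----------------------------------------------
# For every ATG occurrence, walk codon by codon to the first in-frame stop.
oracle_longest_orf <- function(seq) {
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(v)
  best <- 0L
  atg <- which(v == "A")
  for (i in atg) {
    if (i + 2L > n) next
    if (paste(v[i:(i + 2L)], collapse = "") != "ATG") next
    j <- i
    len <- 0L
    repeat {
      if (j + 2L > n) { len <- 0L; break }   # never terminated: not an ORF
      codon <- paste(v[j:(j + 2L)], collapse = "")
      if (j > i && codon %in% c("TAA", "TAG", "TGA")) break
      len <- len + 1L
      j <- j + 3L
    }
    best <- max(best, len)
  }
  best
}

# --- Smith-Waterman oracle ------------------------------------------------
# Textbook DP with the same documented tie-break (diagonal > up > left,
# first maximal cell in row-major order), implemented over character
# vectors rather than integer encodings.
oracle_sw <- function(pattern, subject, match = 1, mismatch = -1, gap = -2) {
  a <- strsplit(pattern, "", fixed = TRUE)[[1]]
  b <- strsplit(subject, "", fixed = TRUE)[[1]]
  n <- length(a); m <- length(b)
  H <- matrix(0, n + 1, m + 1)
  best <- 0; bi <- 0; bj <- 0
  for (i in 1:n) {
    for (j in 1:m) {
      d <- H[i, j] + if (a[i] == b[j]) match else mismatch
      u <- H[i, j + 1] + gap
      l <- H[i + 1, j] + gap
      H[i + 1, j + 1] <- max(0, d, u, l)
      if (H[i + 1, j + 1] > best) {
        best <- H[i + 1, j + 1]; bi <- i + 1; bj <- j + 1
      }
    }
  }
  matches <- 0; cols <- 0
  i <- bi; j <- bj
  while (i > 1 && j > 1 && H[i, j] > 0) {
    sub <- if (a[i - 1] == b[j - 1]) match else mismatch
    if (H[i, j] == H[i - 1, j - 1] + sub) {
      if (a[i - 1] == b[j - 1]) matches <- matches + 1
      i <- i - 1; j <- j - 1
    } else if (H[i, j] == H[i - 1, j] + gap) {
      i <- i - 1
    } else {
      j <- j - 1
    }
    cols <- cols + 1
  }
  list(score = best, matches = matches, columns = cols,
       identity = if (cols > 0) matches / cols else 0,
       pattern_span = if (bi > 0) c(i, bi - 1) else c(0, 0))
}

# --- hypergeometric oracle ------------------------------------------------
# Upper tail assembled from explicit binomial-coefficient arithmetic.
oracle_hyper_upper <- function(k, m, N, n) {
  js <- k:min(m, n)
  if (length(js) == 0L || k > min(m, n)) return(0)
  sum(exp(lchoose(m, js) + lchoose(N - m, n - js) - lchoose(N, n)))
}

# --- misc -----------------------------------------------------------------
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# a minimal transcript set builder for interval logic tests; coords 0-based
make_ts <- function(df) {
  ex <- df
  ex$transcript_id <- df$transcript_id
  transcript_set(
    data.frame(transcript_id = df$transcript_id, gene_id = df$transcript_id,
               chrom = df$chrom, start = df$start, end = df$end,
               strand = df$strand, biotype = df$biotype,
               stringsAsFactors = FALSE),
    data.frame(transcript_id = df$transcript_id, chrom = df$chrom,
               start = df$start, end = df$end, strand = df$strand,
               stringsAsFactors = FALSE))
}

# independent eTM criteria checker: knows only the three criteria, reads an
# alignment's states string and bulge annotation
oracle_etm_ok <- function(states, bulge_len, bulge_after, max_mm_gu = 3) {
  st <- strsplit(states, "", fixed = TRUE)[[1]]
  crit1 <- all(st[2:8] == "W")
  crit2 <- sum(st != "W") <= max_mm_gu
  crit3 <- bulge_len == 0 || (bulge_len == 3 && bulge_after %in% 9:12)
  crit1 && crit2 && crit3
}
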