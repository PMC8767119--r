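# Synthetic genome and annotation with planted positional classes and
# filter decoys.

#' Simulate the toy genome, annotation and planted feature truth
#'
#' Lays out protein-coding genes and noncoding candidates in non-overlapping
#' blocks (so every planted spatial relation is true by construction):
#' intergenic lincRNAs, antisense lncRNAs inside opposite-strand gene bodies,
#' sense lncRNAs confined to same-strand introns, overlapping lncRNAs fully
#' containing an opposite-strand gene, cis lncRNA-gene pairs at a recorded
#' gap distance, and one decoy class per discovery filter. Noncoding
#' transcripts are post-edited so no forward-frame ORF reaches the coding
#' surrogate threshold; coding genes and coding decoys get a planted long
#' ORF. lincRNA spliced lengths cycle the four report bins (200-600,
#' 601-1000, 1001-1400, >1400 nt).
#'
#' @param config A [simulation_config].
#' @return list with `annotation` (combined [transcript_set]), `genes` and
#'   `candidates` (subsets), `genome` (named character vector),
#'   `truth_features` (one row per transcript: planted class, host gene,
#'   expected filter fate) and `pair_skeleton` (planted cis/trans pair and
#'   decoy layout, completed by [simulate_counts]).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  ids <- new.env()
  ids$gene <- 0L; ids$cand <- 0L
  next_gene <- function() { ids$gene <- ids$gene + 1L; sprintf("%03d", ids$gene) }
  next_cand <- function() { ids$cand <- ids$cand + 1L; sprintf("cand_%03d", ids$cand) }
  rstrand <- function() c("+", "-")[rint(1L, 1L, 2L)]

  feat <- function(id, gene_id, strand, biotype, class, host, exons) {
    list(id = id, gene_id = gene_id, strand = strand, biotype = biotype,
         class = class, host_gene = host,
         exons = exons)
  }
  gene_exons <- function(n_exons = rint(1L, 2L, 3L), exon_len = NULL,
                         intron_len = NULL) {
    if (is.null(exon_len)) exon_len <- rint(n_exons, 180L, 500L)
    if (is.null(intron_len)) intron_len <- rint(max(n_exons - 1L, 0L), 200L, 1200L)
    s <- 0L; starts <- integer(n_exons); ends <- integer(n_exons)
    for (k in seq_len(n_exons)) {
      starts[k] <- s; ends[k] <- s + exon_len[k]
      s <- ends[k] + if (k < n_exons) intron_len[k] else 0L
    }
    data.frame(start = starts, end = ends)
  }
  # lincRNA spliced lengths cycle the four report bins
  linc_len <- function(i) {
    switch((i - 1L) %% 4L + 1L,
           rint(1L, 200L, 600L), rint(1L, 601L, 1000L),
           rint(1L, 1001L, 1400L), rint(1L, 1401L, 2200L))
  }
  lnc_exons <- function(total_len) {
    # 1-2 exons; multi-exon only when each piece stays >= 100 nt
    if (total_len >= 300L && stats::runif(1) < 0.5) {
      e1 <- rint(1L, 100L, total_len - 100L)
      gap <- rint(1L, 150L, 600L)
      data.frame(start = c(0L, e1 + gap),
                 end = c(e1, e1 + gap + (total_len - e1)))
    } else {
      data.frame(start = 0L, end = total_len)
    }
  }

  new_gene_feat <- function(class = "coding", exons = gene_exons(),
                            strand = rstrand()) {
    g <- next_gene()
    feat(paste0("mRNA_", g), paste0("gene_", g), strand, "protein_coding",
         class, NA_character_, exons)
  }

  blocks <- list()
  add_block <- function(type, features, role = NULL) {
    blocks[[length(blocks) + 1L]] <<- list(type = type, features = features,
                                           role = role)
  }

  for (i in seq_len(config$n_coding_genes)) add_block("plain_gene", list(new_gene_feat()))
  for (i in seq_len(config$n_lincRNA)) {
    L <- linc_len(i)
    add_block("linc", list(feat(next_cand(), NA_character_, rstrand(),
                                "candidate", "lincRNA", NA_character_,
                                lnc_exons(L))))
  }
  for (i in seq_len(config$n_antisense)) {
    L <- rint(1L, 200L, 600L)
    g <- new_gene_feat(exons = gene_exons(2L, exon_len = c(L + 300L, rint(1L, 180L, 400L))))
    anti_strand <- if (g$strand == "+") "-" else "+"
    lnc <- feat(next_cand(), NA_character_, anti_strand, "candidate",
                "antisense", g$gene_id,
                data.frame(start = 100L, end = 100L + L))
    add_block("gene_antisense", list(g, lnc))
  }
  for (i in seq_len(config$n_sense)) {
    L <- rint(1L, 200L, 600L)
    e1 <- rint(1L, 180L, 400L)
    g <- new_gene_feat(exons = gene_exons(2L, exon_len = c(e1, rint(1L, 180L, 400L)),
                                          intron_len = L + 300L))
    lnc <- feat(next_cand(), NA_character_, g$strand, "candidate",
                "sense", g$gene_id,
                data.frame(start = e1 + 150L, end = e1 + 150L + L))
    add_block("gene_sense", list(g, lnc))
  }
  for (i in seq_len(config$n_overlapping)) {
    g <- new_gene_feat(exons = gene_exons(2L, exon_len = rint(2L, 180L, 320L),
                                          intron_len = rint(1L, 200L, 400L)))
    gw <- max(g$exons$end)
    L <- gw + 400L
    lnc_strand <- if (g$strand == "+") "-" else "+"
    g$exons <- g$exons + 200L   # gene sits inside the lncRNA
    lnc <- feat(next_cand(), NA_character_, lnc_strand, "candidate",
                "overlapping", g$gene_id, data.frame(start = 0L, end = L))
    add_block("olap_gene", list(lnc, g))
  }
  for (i in seq_len(config$n_cis_pairs + config$n_cis_decoys)) {
    decoy <- i > config$n_cis_pairs
    L <- rint(1L, 400L, 1200L)
    d <- rint(1L, 2000L, 50000L)
    g <- new_gene_feat()
    gw <- max(g$exons$end)
    lnc_first <- i %% 2L == 0L
    if (lnc_first) {
      lnc_ex <- lnc_exons(L)
      g$exons <- g$exons + (max(lnc_ex$end) + d)
    } else {
      lnc_ex <- lnc_exons(L) + (gw + d)
    }
    lnc <- feat(next_cand(), NA_character_, rstrand(), "candidate",
                if (decoy) "cis_decoy_lnc" else "cis_lnc", g$gene_id, lnc_ex)
    add_block(if (decoy) "cis_decoy" else "cis_pair", list(lnc, g),
              role = list(lnc = lnc$id, gene = g$id, gap = d,
                          kind = if (decoy) "cis_decoy" else "cis"))
  }
  for (i in seq_len(config$n_exonic_decoys)) {
    g <- new_gene_feat()
    dec <- feat(next_cand(), NA_character_, g$strand, "candidate",
                "exonic_decoy", g$gene_id,
                data.frame(start = 50L, end = 50L + rint(1L, 250L, 500L)))
    add_block("gene_exonic_decoy", list(g, dec))
  }
  for (i in seq_len(config$n_coding_decoys)) {
    add_block("coding_decoy",
              list(feat(next_cand(), NA_character_, rstrand(), "candidate",
                        "coding_decoy", NA_character_,
                        data.frame(start = 0L, end = rint(1L, 500L, 900L)))))
  }
  for (i in seq_len(config$n_short_decoys)) {
    add_block("short_decoy",
              list(feat(next_cand(), NA_character_, rstrand(), "candidate",
                        "short_decoy", NA_character_,
                        data.frame(start = 0L, end = rint(1L, 150L, 199L)))))
  }
  for (i in seq_len(config$n_low_expr_decoys)) {
    add_block("low_expr_decoy",
              list(feat(next_cand(), NA_character_, rstrand(), "candidate",
                        "low_expr_decoy", NA_character_,
                        data.frame(start = 0L, end = rint(1L, 400L, 800L)))))
  }

  # place blocks round-robin over chromosomes with random gaps
  ord <- sample(length(blocks))
  blocks <- blocks[ord]
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  cursor <- stats::setNames(rep(2000L, config$n_chromosomes), chroms)
  placed <- list()
  for (k in seq_along(blocks)) {
    blk <- blocks[[k]]
    chrom <- chroms[(k - 1L) %% config$n_chromosomes + 1L]
    width <- max(vapply(blk$features, function(f) max(f$exons$end), 0))
    gap <- rint(1L, 3000L, 9000L)
    start <- cursor[[chrom]] + gap
    if (start + width > config$chrom_length - 2000L) {
      stop("chromosome ", chrom, " too short to place all features; ",
           "increase chrom_length")
    }
    cursor[[chrom]] <- start + width
    blk$chrom <- chrom
    blk$offset <- start
    placed[[k]] <- blk
  }

  tx_rows <- list(); ex_rows <- list(); truth <- list()
  roles <- list()
  for (blk in placed) {
    if (!is.null(blk$role)) roles[[length(roles) + 1L]] <- blk$role
    for (f in blk$features) {
      ex <- f$exons + blk$offset
      tx_rows[[f$id]] <- data.frame(
        transcript_id = f$id,
        gene_id = if (is.na(f$gene_id)) f$id else f$gene_id,
        chrom = blk$chrom, start = min(ex$start), end = max(ex$end),
        strand = f$strand, biotype = f$biotype, stringsAsFactors = FALSE)
      ex_rows[[f$id]] <- data.frame(
        transcript_id = f$id, chrom = blk$chrom,
        start = ex$start, end = ex$end, strand = f$strand,
        stringsAsFactors = FALSE)
      truth[[f$id]] <- data.frame(
        transcript_id = f$id, biotype = f$biotype, planted_class = f$class,
        host_gene = f$host_gene, chrom = blk$chrom,
        start = min(ex$start), end = max(ex$end), strand = f$strand,
        stringsAsFactors = FALSE)
    }
  }
  transcripts <- do.call(rbind, c(tx_rows, make.row.names = FALSE))
  exons <- do.call(rbind, c(ex_rows, make.row.names = FALSE))
  truth <- do.call(rbind, c(truth, make.row.names = FALSE))
  ts <- transcript_set(transcripts, exons)
  truth$spliced_length <- ts$transcripts$length[match(truth$transcript_id,
                                                      ts$transcripts$transcript_id)]
  lnc_classes <- c("lincRNA", "antisense", "sense", "overlapping",
                   "cis_lnc", "cis_decoy_lnc")
  truth$expected_survivor <- truth$planted_class %in% lnc_classes
  truth$expected_positional_class <- ifelse(
    truth$planted_class %in% c("lincRNA", "cis_lnc", "cis_decoy_lnc"), "lincRNA",
    ifelse(truth$planted_class %in% c("antisense", "sense", "overlapping"),
           truth$planted_class, NA_character_))

  # random genome, then plant coding ORFs, then break candidate ORFs
  genome <- stats::setNames(
    vapply(chroms, function(ch) rand_dna(config$chrom_length), ""), chroms)
  coding_ids <- truth$transcript_id[truth$biotype == "protein_coding" |
                                      truth$planted_class == "coding_decoy"]
  for (tid in coding_ids) {
    genome <- plant_orf(genome, ts, tid, config$orf_threshold)
  }
  noncoding_ids <- truth$transcript_id[truth$biotype == "candidate" &
                                         truth$planted_class != "coding_decoy"]
  for (tid in noncoding_ids) {
    genome <- break_orfs(genome, ts, tid, config$orf_threshold)
  }

  # designate trans pairs/decoys among plain lincRNAs and plain genes on
  # different chromosomes
  plain_lincs <- truth$transcript_id[truth$planted_class == "lincRNA"]
  plain_genes <- setdiff(truth$transcript_id[truth$biotype == "protein_coding" &
                                               is.na(truth$host_gene)],
                         unlist(lapply(roles, `[[`, "gene")))
  # also drop genes hosting decoys/antisense/etc: host genes carry host refs
  hosted <- unique(stats::na.omit(truth$host_gene))
  hosted_tx <- ts$transcripts$transcript_id[ts$transcripts$gene_id %in% hosted]
  plain_genes <- setdiff(plain_genes, hosted_tx)
  n_trans_all <- config$n_trans_pairs + config$n_trans_decoys
  chrom_of <- stats::setNames(truth$chrom, truth$transcript_id)
  used_l <- character(0); used_g <- character(0)
  for (i in seq_len(n_trans_all)) {
    l <- setdiff(plain_lincs, used_l)[1]
    gpool <- setdiff(plain_genes, used_g)
    g <- gpool[chrom_of[gpool] != chrom_of[l]][1]
    if (is.na(l) || is.na(g)) stop("not enough plain features for trans pairs")
    used_l <- c(used_l, l); used_g <- c(used_g, g)
    roles[[length(roles) + 1L]] <- list(
      lnc = l, gene = g, gap = NA_integer_,
      kind = if (i <= config$n_trans_pairs) "trans" else "trans_decoy")
  }
  pair_skeleton <- if (length(roles)) {
    do.call(rbind, lapply(roles, function(r) {
      data.frame(lncRNA_id = r$lnc, gene_id = r$gene, kind = r$kind,
                 gap_bp = r$gap, stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(lncRNA_id = character(), gene_id = character(),
               kind = character(), gap_bp = integer(),
               stringsAsFactors = FALSE)
  }

  list(annotation = ts,
       genes = subset_transcripts(ts, transcripts$transcript_id[
         transcripts$biotype == "protein_coding"]),
       candidates = subset_transcripts(ts, transcripts$transcript_id[
         transcripts$biotype == "candidate"]),
       genome = genome, truth_features = truth,
       pair_skeleton = pair_skeleton, config = config)
}

# genomic positions (1-based, 5'->3' along the transcript) of a spliced
# transcript, used to write spliced-coordinate edits back into the genome
spliced_positions <- function(ts, tid) {
  e <- ts$exons[ts$exons$transcript_id == tid, ]
  pos <- unlist(Map(seq.int, e$start + 1L, e$end))
  if (e$strand[1] == "-") pos <- rev(pos)
  pos
}

# overwrite transcript-coordinate window [tstart, tend) (0-based) with
# replacement (given 5'->3' on the transcript sense)
write_spliced <- function(genome, ts, tid, tstart, replacement) {
  e <- ts$exons[ts$exons$transcript_id == tid, ]
  chrom <- e$chrom[1]
  pos <- spliced_positions(ts, tid)
  nts <- strsplit(replacement, "", fixed = TRUE)[[1]]
  if (e$strand[1] == "-") nts <- chartr("ACGT", "TGCA", nts)
  idx <- pos[tstart + seq_along(nts)]
  g <- strsplit(genome[[chrom]], "", fixed = TRUE)[[1]]
  g[idx] <- nts
  genome[[chrom]] <- paste(g, collapse = "")
  genome
}

# plant an ATG..stop ORF comfortably above the surrogate threshold
plant_orf <- function(genome, ts, tid, threshold) {
  len <- ts$transcripts$length[ts$transcripts$transcript_id == tid]
  k <- min(len %/% 3L - 8L, threshold + rint(1L, 10L, 60L))
  if (k < threshold) stop("transcript ", tid, " too short to host an ORF")
  non_stop <- setdiff(apply(expand.grid(c("A", "C", "G", "T"),
                                        c("A", "C", "G", "T"),
                                        c("A", "C", "G", "T")), 1, paste,
                            collapse = ""),
                      c("TAA", "TAG", "TGA"))
  orf <- paste0("ATG", paste(non_stop[rint(k - 1L, 1L, length(non_stop))],
                             collapse = ""), "TAA")
  off <- rint(1L, 0L, len - nchar(orf))
  write_spliced(genome, ts, tid, off, orf)
}

# repeatedly stop-codon-break the longest ORF until below threshold
break_orfs <- function(genome, ts, tid, threshold, max_iter = 20L) {
  for (it in seq_len(max_iter)) {
    seq <- extract_transcript_seqs(subset_transcripts(ts, tid), genome)[[1]]
    d <- orf_detail(seq)
    if (d$codons < threshold) return(genome)
    # overwrite a mid-ORF codon with TAA
    mid_codon <- d$start_nt + 3L * (d$codons %/% 2L)
    genome <- write_spliced(genome, ts, tid, mid_codon - 1L, "TAA")
  }
  stop("could not break ORFs in ", tid)
}

# longest forward-frame ORF with its location (0-based nt offset of its ATG)
orf_detail <- function(seq) {
  n <- nchar(seq)
  best <- list(codons = 0L, start_nt = NA_integer_)
  if (n < 3L) return(best)
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
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
        if (k - open_at > best$codons) {
          best <- list(codons = k - open_at, start_nt = starts[open_at])
        }
        open_at <- NA_integer_
      }
    }
  }
  best
}
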