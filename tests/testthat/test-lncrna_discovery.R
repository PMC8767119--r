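# Discovery cascade: filters, ORF surrogate, positional classification.

fpkm_of <- function(ids, value) {
  m <- matrix(value, length(ids), 2,
              dimnames = list(ids, c("s1", "s2")))
  expression_matrix(m, c(s1 = "A", s2 = "B"), "FPKM")
}

test_that("filter gates are strict at their documented boundaries", {
  tr <- data.frame(
    transcript_id = c("short199", "len200", "low", "at_gate", "anti"),
    chrom = "c", strand = c("+", "+", "+", "+", "-"),
    start = c(0, 1000, 2000, 3000, 10000),
    end = c(199, 1200, 2400, 3200, 10300),
    biotype = "candidate")
  ts <- make_ts(tr)
  # a coding gene overlapping 'anti' on the opposite strand
  genes <- make_ts(data.frame(transcript_id = "g1", chrom = "c", strand = "+",
                              start = 10000, end = 10500,
                              biotype = "protein_coding"))
  f <- matrix(c(10, 10, 10, 0.5, 0.5, 0.5, 0.2, 0.4, 0.1, 0.5, 0.3, 3),
              nrow = 4, byrow = TRUE,
              dimnames = list(c("short199", "len200", "low", "anti"),
                              c("x", "y", "z")))
  f <- rbind(f, at_gate = c(0.5, 0.5, 0.5))
  em <- expression_matrix(f, c(x = "A", y = "A", z = "B"), "FPKM")
  res <- filter_candidates(ts, em, genes)
  # 199 nt removed; 200 nt with max FPKM exactly 0.5 retained; max FPKM
  # 0.4 < 0.5 removed; antisense exonic overlap retained at step 1
  expect_setequal(res$survivor_ids, c("len200", "at_gate", "anti"))
  expect_equal(res$tally$removed, c(0, 1, 1))
  # a same-strand exonic overlap is removed at step 1
  genes2 <- make_ts(data.frame(transcript_id = "g1", chrom = "c",
                               strand = "-", start = 10000, end = 10500,
                               biotype = "protein_coding"))
  res2 <- filter_candidates(ts, em, genes2)
  expect_false("anti" %in% res2$survivor_ids)
  expect_equal(res2$tally$removed[1], 1)
})

test_that("missing FPKM rows and wrong units are errors", {
  ts <- make_ts(data.frame(transcript_id = "t1", chrom = "c", strand = "+",
                           start = 0, end = 300, biotype = "candidate"))
  genes <- make_ts(data.frame(transcript_id = "g", chrom = "c", strand = "+",
                              start = 5000, end = 5400,
                              biotype = "protein_coding"))
  expect_error(filter_candidates(ts, fpkm_of("other", 1), genes), "t1")
  cm <- expression_matrix(matrix(1, 1, 2, dimnames = list("t1", c("a", "b"))),
                          c(a = "A", b = "B"), "count")
  expect_error(filter_candidates(ts, cm, genes), "FPKM")
})

test_that("the surviving set is invariant to filter order", {
  # predicates are independent; check the survivor set equals the
  # intersection of the three keep-predicates applied in any order
  set.seed(5)
  study <- simulate_study(simulation_config(seed = 11))
  ts <- study$candidates
  genes <- study$genes
  lengths <- setNames(study$annotation$transcripts$length,
                      study$annotation$transcripts$transcript_id)
  fpkm <- compute_fpkm(study$counts, lengths)
  fsub <- expression_matrix(fpkm$values[ts$transcripts$transcript_id, ,
                                        drop = FALSE], fpkm$groups, "FPKM")
  res <- filter_candidates(ts, fsub, genes)
  keep_overlap <- !lncnet:::exonic_same_strand_overlap(ts, genes)
  keep_fpkm <- apply(fsub$values, 1, max) >= 0.5
  keep_len <- ts$transcripts$length >= 200
  expect_setequal(res$survivor_ids,
                  ts$transcripts$transcript_id[keep_overlap & keep_fpkm & keep_len])
})

test_that("ORF surrogate matches the brute-force oracle on random sequences", {
  set.seed(17)
  for (i in 1:1000) {
    s <- random_dna(sample(30:320, 1))
    expect_identical(longest_orf(s), oracle_longest_orf(s))
  }
})

test_that("ORF surrogate boundary behavior", {
  expect_equal(longest_orf("CCCCCC"), 0L)           # no ATG
  expect_equal(coding_potential_surrogate("AC")$orf_codons, 0L)
  # exactly 100 codons incl. ATG, then a stop
  orf <- paste0("ATG", strrep("GCT", 99), "TAA")
  seq <- paste0(random_dna(40), orf, random_dna(50))
  # guard against an accidental longer ORF in the random flanks
  r <- coding_potential_surrogate(seq)
  expect_gte(r$orf_codons, 100L)
  expect_equal(r$class, "coding")
  expect_equal(coding_potential_surrogate(paste0("ATG", strrep("GCT", 98),
                                                 "TAA"))$class, "noncoding")
  # an unterminated run is not an ORF
  expect_equal(longest_orf(paste0("ATG", strrep("GCT", 120))), 0L)
})

test_that("positional classification follows definitions and precedence", {
  genes <- make_ts(data.frame(transcript_id = "g", chrom = "c", strand = "+",
                              start = 10000, end = 12000,
                              biotype = "protein_coding"))
  lncs <- make_ts(data.frame(
    transcript_id = c("far", "anti", "in_same", "spans"),
    chrom = "c", strand = c("+", "-", "+", "+"),
    start = c(40000, 10500, 10500, 9500),
    end = c(41000, 11000, 11000, 12500), biotype = "candidate"))
  cls <- classify_positional(lncs, genes)
  expect_equal(unname(cls),
               c("lincRNA", "antisense", "sense", "overlapping"))
})

test_that("classification agrees with an exhaustive interval-relation oracle", {
  study <- simulate_study(simulation_config(seed = 3))
  lengths <- setNames(study$annotation$transcripts$length,
                      study$annotation$transcripts$transcript_id)
  fpkm <- compute_fpkm(study$counts, lengths)
  disc <- discover_lncrnas(
    study$candidates, study$genes,
    expression_matrix(fpkm$values[study$candidates$transcripts$transcript_id, ,
                                  drop = FALSE], fpkm$groups, "FPKM"),
    study$seqs[study$candidates$transcripts$transcript_id])
  got <- setNames(disc$records$positional_class, disc$records$transcript_id)
  g <- study$genes$transcripts
  for (tid in names(got)) {
    l <- study$annotation$transcripts[
      study$annotation$transcripts$transcript_id == tid, ]
    rel <- "lincRNA"
    for (k in seq_len(nrow(g))) {
      if (g$chrom[k] != l$chrom) next
      if (l$start < g$end[k] && g$start[k] < l$end) {
        this <- if (l$start <= g$start[k] && l$end >= g$end[k]) "overlapping"
                else if (g$strand[k] != l$strand) "antisense" else "sense"
        pr <- c(lincRNA = 0, sense = 1, antisense = 2, overlapping = 3)
        if (pr[this] > pr[rel]) rel <- this
      }
    }
    expect_identical(unname(got[tid]), rel)
  }
})

test_that("summaries bin lengths as documented and percentages close", {
  rec <- data.frame(length = c(250, 800, 1200, 2000), n_exons = 1,
                    positional_class = "lincRNA")
  s <- summarize_features(rec)
  expect_equal(s$length_bins$Freq, c(1, 1, 1, 1))
  expect_equal(s$length_bins$percent, rep(25, 4))
  rec2 <- data.frame(length = rep(300, 7), n_exons = 1,
                     positional_class = "lincRNA")
  s2 <- summarize_features(rec2)
  expect_equal(s2$length_bins$percent[1], 100)
  expect_equal(sum(s2$length_bins$percent), 100)
  expect_warning(summarize_features(rec[0, ]), "no lncRNA")
})
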