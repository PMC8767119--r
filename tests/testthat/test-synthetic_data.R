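# Generator: determinism and mechanical checkability of every truth claim.

test_that("identical seeds give identical studies; different seeds differ", {
  cfg <- simulation_config(seed = 4)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$genome, s2$genome)
  expect_identical(s1$seqs, s2$seqs)
  expect_identical(s1$counts$values, s2$counts$values)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_genome(simulation_config(seed = 5))
  expect_false(identical(s1$genome, s3$genome))
  # schema is seed-independent
  expect_identical(names(s3$truth_features), names(s1$truth$features))
})

test_that("planted spatial relations hold in the emitted annotation", {
  sim <- simulate_genome(simulation_config(seed = 8))
  tr <- sim$annotation$transcripts
  truth <- sim$truth_features
  g <- tr[tr$biotype == "protein_coding", ]
  overlaps_gene <- function(row, same_strand = NULL) {
    hit <- g$chrom == row$chrom & g$start < row$end & row$start < g$end
    if (!is.null(same_strand)) hit <- hit & ((g$strand == row$strand) == same_strand)
    any(hit)
  }
  for (i in seq_len(nrow(truth))) {
    row <- tr[tr$transcript_id == truth$transcript_id[i], ]
    cls <- truth$planted_class[i]
    if (cls %in% c("lincRNA", "cis_lnc", "cis_decoy_lnc", "coding_decoy",
                   "short_decoy", "low_expr_decoy")) {
      expect_false(overlaps_gene(row), info = row$transcript_id)
    } else if (cls == "antisense") {
      expect_true(overlaps_gene(row, same_strand = FALSE))
      expect_false(overlaps_gene(row, same_strand = TRUE))
    } else if (cls == "sense") {
      host <- g[g$gene_id == truth$host_gene[i], ]
      expect_true(row$start >= host$start && row$end <= host$end)
      expect_equal(row$strand, host$strand)
      # confined to the intron: no exonic overlap
      he <- sim$annotation$exons[sim$annotation$exons$transcript_id ==
                                   host$transcript_id, ]
      expect_false(any(he$start < row$end & row$start < he$end))
    } else if (cls == "overlapping") {
      host <- g[g$gene_id == truth$host_gene[i], ]
      expect_true(row$start <= host$start && row$end >= host$end)
    } else if (cls == "exonic_decoy") {
      host <- g[g$gene_id == truth$host_gene[i], ]
      he <- sim$annotation$exons[sim$annotation$exons$transcript_id ==
                                   host$transcript_id, ]
      expect_true(any(he$strand == row$strand & he$start < row$end &
                        row$start < he$end))
    }
  }
})

test_that("exon-union length equals spliced sequence length for all transcripts", {
  study <- simulate_study(simulation_config(seed = 9))
  ts <- study$annotation
  expect_identical(unname(nchar(study$seqs[ts$transcripts$transcript_id])),
                   as.integer(ts$transcripts$length))
  # lincRNA lengths cover the four report bins
  truth <- study$truth$features
  linc_len <- truth$spliced_length[truth$planted_class == "lincRNA"]
  bins <- cut(linc_len, c(199.5, 600.5, 1000.5, 1400.5, Inf))
  expect_equal(length(unique(bins)), 4L)
})

test_that("noncoding transcripts carry no ORF at the surrogate threshold", {
  study <- simulate_study(simulation_config(seed = 10))
  truth <- study$truth$features
  nc <- truth$transcript_id[truth$biotype == "candidate" &
                              truth$planted_class != "coding_decoy"]
  orf <- vapply(study$seqs[nc], longest_orf, 0L)
  expect_true(all(orf < study$config$orf_threshold))
  cd <- truth$transcript_id[truth$planted_class == "coding_decoy"]
  expect_true(all(vapply(study$seqs[cd], longest_orf, 0L) >=
                    study$config$orf_threshold))
})

test_that("planted counts reproduce the planted fold changes", {
  # dispersion -> 0 with no planted effect: group means agree within
  # Poisson noise
  cfg0 <- simulation_config(seed = 12, de_fraction = 0, n_cis_pairs = 0,
                            n_cis_decoys = 0, n_trans_pairs = 0,
                            n_trans_decoys = 0, dispersion = 1e-13)
  sim0 <- simulate_genome(cfg0)
  cnt0 <- simulate_counts(sim0, cfg0)
  v <- cnt0$counts$values
  v <- v[rowSums(v) > 0, ]
  a <- rowMeans(v[, 1:3]); b <- rowMeans(v[, 4:6])
  # sample-size-3 Poisson means with library factors in [0.7, 1.4]:
  # log2 ratios concentrate near log2 of the library-factor ratio
  expect_lt(median(abs(log2(a / b))), 0.6)

  # planted log2FC = 2 at moderate dispersion: empirical log2 ratio within
  # +-0.5 of 2 for >= 90% of >= 200 planted features
  set.seed(13)
  nfeat <- 250
  lib <- runif(6, 0.9, 1.1)
  up <- matrix(rnbinom(nfeat * 3, mu = 500 * 2 * rep(lib[1:3], each = nfeat),
                       size = 1 / 0.05), nfeat)
  dn <- matrix(rnbinom(nfeat * 3, mu = 500 / 2 * rep(lib[4:6], each = nfeat),
                       size = 1 / 0.05), nfeat)
  ratio <- log2(rowMeans(up) / rowMeans(dn))
  expect_gte(mean(abs(ratio - 2) <= 0.5), 0.9)
})

test_that("partner and decoy pair structure is as planted", {
  cfg <- simulation_config(seed = 14)
  sim <- simulate_genome(cfg)
  cnt <- simulate_counts(sim, cfg)
  pairs <- cnt$truth_pairs
  expect_equal(sum(pairs$kind == "cis"), cfg$n_cis_pairs)
  expect_equal(sum(pairs$kind == "trans"), cfg$n_trans_pairs)
  # partner pairs: noiseless profile correlation is exactly 1
  expect_true(all(abs(pairs$induced_r[pairs$kind %in% c("cis", "trans")] - 1)
                  < 1e-12))
  expect_true(all(abs(pairs$induced_r[grepl("decoy", pairs$kind)]) <= 0.5))
  # cis pairs within the window on one chromosome; trans pairs cross-chromosome
  tr <- sim$annotation$transcripts
  chrom <- setNames(tr$chrom, tr$transcript_id)
  cis <- pairs[pairs$kind == "cis", ]
  expect_true(all(chrom[cis$lncRNA_id] == chrom[cis$gene_id]))
  expect_true(all(cis$distance_bp <= 1e5))
  trp <- pairs[pairs$kind == "trans", ]
  expect_true(all(chrom[trp$lncRNA_id] != chrom[trp$gene_id]))
  cfg1 <- cfg; cfg1$replicates <- 1L
  expect_error(simulate_counts(sim, cfg1), "2 replicates")
})

test_that("planted sites carry their rule classes; clean hosts stay clean", {
  set.seed(15)
  mirnas <- setNames(vapply(1:4, function(i) random_dna(21), ""),
                     paste0("m", 1:4))
  hosts <- setNames(vapply(1:8, function(i) random_dna(300), ""),
                    paste0("h", 1:8))
  p <- plant_mirna_sites(hosts, mirnas,
                         c(target = 2L, etm = 2L, near_miss_seed = 2L,
                           near_miss_budget = 2L, near_miss_bulge = 2L))
  tr <- p$truth_sites
  expect_equal(nrow(tr), 10L)
  expect_true(all(nchar(p$seqs) == nchar(hosts)))   # length preserved
  expect_true(all(tr$valid_etm[tr$rule_class == "etm"]))
  expect_false(any(tr$valid_etm[grepl("near_miss", tr$rule_class)]))
  expect_true(all(tr$valid_target[tr$rule_class == "target"]))
  expect_false(any(tr$valid_target[tr$rule_class == "near_miss_budget"]))
  # a sequence with no planted site for a miRNA yields no eTM calls
  # (verified against the exhaustive duplex oracle on one pair)
  clean <- setdiff(names(hosts), tr$host_id)
  if (length(clean) == 0L) clean <- "h1"
  fresh <- c(clean1 = random_dna(400))
  expect_equal(nrow(call_etms(mirnas, fresh)$edges), 0L)
  expect_equal(nrow(oracle_duplex(mirnas[[1]], fresh[[1]], 3)), 0L)
})

test_that("impossible placements raise informative errors", {
  set.seed(16)
  mirnas <- c(m = random_dna(21))
  expect_error(plant_mirna_sites(c(tiny = random_dna(30)), mirnas,
                                 c(etm = 5L)), "collision")
  cfg <- simulation_config(seed = 1, chrom_length = 30000L)
  expect_error(simulate_genome(cfg), "chrom_length")
})
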