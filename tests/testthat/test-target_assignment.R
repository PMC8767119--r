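# Cis / trans target assignment.

test_that("pearson_r matches direct formula and handles degenerate input", {
  expect_equal(pearson_r(1:5, 2 * (1:5) + 1), 1)
  expect_equal(pearson_r(1:5, -(1:5)), -1)
  x <- c(1, 2, 3, 4); y <- c(1, 2, 3, 5)
  direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_r(x, y), direct, tolerance = 1e-12)
  expect_true(is.na(pearson_r(rep(1, 4), y)))
  expect_error(pearson_r(1:4, 1:5), "length mismatch")
  expect_error(pearson_r(1:2, 1:2), "3")
})

cis_fixture <- function(gap) {
  # lncRNA [0, 1000); gene starts 'gap' bp after it on a + strand
  ts <- make_ts(data.frame(
    transcript_id = c("L", "G"), chrom = "c", strand = "+",
    start = c(0, 1000 + gap), end = c(1000, 1500 + gap),
    biotype = c("candidate", "protein_coding")))
  v <- rbind(L = c(1, 2, 3, 10, 11, 12), G = c(1.1, 2, 3.2, 10, 11.5, 12))
  colnames(v) <- paste0("s", 1:6)
  em <- expression_matrix(v, setNames(rep(c("A", "B"), each = 3),
                                      colnames(v)), "FPKM")
  list(ts = ts, em = em)
}

test_that("the 100 kb window boundary is inclusive at exactly 100,000", {
  fx <- cis_fixture(100000)
  res <- assign_cis("L", "G", fx$ts, fx$em)
  expect_equal(nrow(res), 1L)
  expect_equal(res$distance_bp, 100000)
  expect_equal(res$distance_kb, 100)
  expect_equal(res$orientation, "upstream")
  fx2 <- cis_fixture(100001)
  expect_equal(nrow(assign_cis("L", "G", fx2$ts, fx2$em)), 0L)
})

test_that("orientation follows the gene's strand and overlap gives distance 0", {
  ts <- make_ts(data.frame(
    transcript_id = c("L", "Gm", "Go"), chrom = "c",
    strand = c("+", "-", "+"),
    start = c(5000, 10000, 4500), end = c(6000, 11000, 5500),
    biotype = c("candidate", "protein_coding", "protein_coding")))
  v <- rbind(L = 1:6, Gm = 1:6 + 0.01, Go = 1:6 + 0.02)
  colnames(v) <- paste0("s", 1:6)
  em <- expression_matrix(v, setNames(rep(c("A", "B"), each = 3),
                                      colnames(v)), "FPKM")
  res <- assign_cis("L", c("Gm", "Go"), ts, em)
  # L sits before the minus-strand gene Gm -> downstream on Gm's strand
  expect_equal(res$orientation[res$gene_id == "Gm"], "downstream")
  expect_equal(res$distance_bp[res$gene_id == "Go"], 0)
})

test_that("cis threshold is inclusive, trans threshold strict", {
  # profiles engineered to correlate exactly 1
  ts <- make_ts(data.frame(
    transcript_id = c("L", "G"), chrom = "c", strand = "+",
    start = c(0, 2000), end = c(1000, 3000),
    biotype = c("candidate", "protein_coding")))
  v <- rbind(L = c(1, 2, 3, 4, 5, 6), G = c(2, 4, 6, 8, 10, 12))
  colnames(v) <- paste0("s", 1:6)
  em <- expression_matrix(v, setNames(rep(c("A", "B"), each = 3),
                                      colnames(v)), "FPKM")
  expect_equal(nrow(assign_cis("L", "G", ts, em, r_threshold = 1)), 1L)
  expect_equal(nrow(assign_trans("L", "G", em, r_threshold = 1)), 0L)
  expect_equal(nrow(assign_trans("L", "G", em, r_threshold = 0.999)), 1L)
})

test_that("cis pairs are excluded from the trans table", {
  fx <- cis_fixture(5000)
  cis <- assign_cis("L", "G", fx$ts, fx$em)
  expect_equal(nrow(cis), 1L)
  tr <- assign_trans("L", "G", fx$em, cis_pairs = cis)
  expect_equal(nrow(tr), 0L)
})

test_that("coordinate mirroring flips orientations but keeps the pair set", {
  study <- simulate_study(simulation_config(seed = 5))
  truth <- study$truth
  pairs <- truth$pairs[truth$pairs$kind == "cis", ]
  lengths <- setNames(study$annotation$transcripts$length,
                      study$annotation$transcripts$transcript_id)
  fpkm <- compute_fpkm(study$counts, lengths, robust = TRUE)
  dels <- pairs$lncRNA_id; degs <- pairs$gene_id
  cis1 <- assign_cis(dels, degs, study$annotation, fpkm)
  # mirror every chromosome position (x -> L - x); strands unchanged, so
  # each lncRNA moves to the other side of its partner gene
  ts <- study$annotation
  L <- max(ts$transcripts$end) + 1000
  mirror <- function(df) {
    s <- df$start; df$start <- L - df$end; df$end <- L - s
    df
  }
  ts2 <- transcript_set(mirror(ts$transcripts[, setdiff(names(ts$transcripts),
                                                        c("length", "n_exons"))]),
                        mirror(ts$exons))
  cis2 <- assign_cis(dels, degs, ts2, fpkm)
  key <- function(d) sort(paste(d$lncRNA_id, d$gene_id, d$distance_bp, d$r))
  expect_identical(key(cis2), key(cis1))
  m <- merge(cis1, cis2, by = c("lncRNA_id", "gene_id"))
  flip <- c(upstream = "downstream", downstream = "upstream")
  expect_true(all(m$orientation.y == unname(flip[m$orientation.x]) |
                    m$distance_bp.x == 0))
  expect_true(nrow(m) > 0)
})

test_that("shuffling sample labels on one side destroys trans pairs", {
  study <- simulate_study(simulation_config(seed = 6))
  truth <- study$truth
  pairs <- truth$pairs[truth$pairs$kind == "trans", ]
  lengths <- setNames(study$annotation$transcripts$length,
                      study$annotation$transcripts$transcript_id)
  fpkm <- compute_fpkm(study$counts, lengths, robust = TRUE)
  set.seed(1001)
  retained <- 0L
  for (shuffle in 1:20) {
    v <- fpkm$values
    v[pairs$gene_id, ] <- v[pairs$gene_id, sample(ncol(v))]
    em <- expression_matrix(v, fpkm$groups, "FPKM")
    retained <- retained + nrow(assign_trans(pairs$lncRNA_id, pairs$gene_id, em))
  }
  # expected ~0 over 20 shuffles of 4 planted pairs
  expect_lte(retained, 2L)
})
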