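# Duplex engine, target/eTM callers, precursor identification.

rc <- function(s) revcomp(s)

test_that("a perfect complement gives exactly one zero-expectation window", {
  set.seed(71)
  for (i in 1:10) {
    m <- random_dna(21)
    flank1 <- random_dna(120); flank2 <- random_dna(130)
    tgt <- paste0(flank1, rc(m), flank2)
    hits <- duplex_scan(m, tgt, max_expectation = 0)
    expect_equal(nrow(hits), 1L)
    expect_equal(hits$expectation, 0)
    expect_equal(hits$target_start, 120L)
    expect_equal(hits$target_end, 141L)
    expect_equal(hits$states, strrep("W", 21))
    expect_equal(hits$bulge_len, 0L)
    # scanning a miRNA against its own exact reverse complement
    self <- duplex_scan(m, rc(m), max_expectation = 0)
    expect_equal(nrow(self), 1L)
  }
})

test_that("single penalties score as documented", {
  # build a miRNA whose position 1 is G so the complement can be wobbled
  m <- paste0("G", random_dna(20))
  site <- rc(m)
  # miRNA position 1 pairs the LAST character of the site; G:C -> G:U
  substr(site, 21, 21) <- "T"
  h <- duplex_scan(m, paste0("AAAA", site, "CCCC"), max_expectation = 1)
  h0 <- h[h$bulge_len == 0 & h$target_start == 4, ]
  expect_equal(h0$expectation, 0.5)          # G:U outside the seed region
  expect_equal(substr(h0$states, 1, 1), "G")
  # same change at position 2 (seed-weighted) doubles the penalty
  m2 <- paste0("AG", random_dna(19))
  site2 <- rc(m2)
  substr(site2, 20, 20) <- "T"
  h2 <- duplex_scan(m2, site2, max_expectation = 3)
  h20 <- h2[h2$bulge_len == 0, ]
  expect_equal(h20$expectation, 1.0)
})

test_that("bulge geometry and penalties follow the insertion rule", {
  set.seed(72)
  m <- random_dna(20)
  tp <- strsplit(rc(m), "", fixed = TRUE)[[1]]   # site chars 5'->3'
  # insert a 2-nt bulge after miRNA position 15: in site coordinates the
  # insertion sits before the partner of position 15
  ins_at <- 20 - 15
  site <- paste(c(tp[seq_len(ins_at)], c("A", "A"), tp[(ins_at + 1):20]),
                collapse = "")
  h <- duplex_scan(m, site, max_expectation = 3)
  hb <- h[h$bulge_len == 2 & h$bulge_after == 15 & h$target_start == 0, ]
  expect_equal(nrow(hb), 1L)
  expect_equal(hb$expectation, 1.0)   # 2 bulged nt x 0.5, outside 2-13
  expect_equal(hb$states, strrep("W", 20))
})

test_that("duplex_scan equals the exhaustive oracle on random pairs", {
  set.seed(73)
  for (i in 1:12) {
    m <- random_dna(sample(20:24, 1))
    tgt <- random_dna(sample(300:600, 1))
    # plant one near-perfect site so the comparison covers hits, not just
    # empty agreement
    site <- rc(m)
    pos <- sample(nchar(tgt) - nchar(site), 1)
    substr(tgt, pos, pos + nchar(site) - 1) <- site
    got <- duplex_scan(m, tgt, max_expectation = 3)
    want <- oracle_duplex(m, tgt, max_expectation = 3)
    expect_equal(nrow(got), nrow(want))
    for (col in c("target_start", "target_end", "bulge_len", "bulge_after",
                  "expectation", "states")) {
      expect_equal(unname(got[[col]]), unname(want[[col]]), info = col)
    }
  }
})

test_that("raising the threshold never removes a hit", {
  set.seed(74)
  m <- random_dna(21)
  tgt <- paste0(random_dna(80), rc(m), random_dna(80))
  h3 <- duplex_scan(m, tgt, max_expectation = 3)
  h6 <- duplex_scan(m, tgt, max_expectation = 6)
  key <- function(d) paste(d$target_start, d$bulge_len, d$bulge_after)
  expect_true(all(key(h3) %in% key(h6)))
  expect_gte(nrow(h6), nrow(h3))
})

test_that("expectation is recomputable from states plus bulge annotation", {
  set.seed(75)
  m <- random_dna(22)
  tgt <- paste0(random_dna(50), rc(m), random_dna(50))
  h <- duplex_scan(m, tgt, max_expectation = 5)
  for (r in seq_len(nrow(h))) {
    expect_equal(lncnet:::expectation_from_states(h$states[r], h$bulge_len[r],
                                                  h$bulge_after[r]),
                 h$expectation[r])
  }
})

test_that("short miRNAs and short targets are rejected", {
  expect_error(duplex_scan(random_dna(17), random_dna(100)), "18 nt")
  expect_error(duplex_scan(random_dna(20), random_dna(10)), "shorter")
})

test_that("call_targets aggregates sites per pair with the best expectation", {
  set.seed(76)
  m <- c(mirX = random_dna(21))
  tgt <- paste0(random_dna(60), rc(m[[1]]), random_dna(60), rc(m[[1]]),
                random_dna(60))
  res <- call_targets(m, c(tx = tgt), kinds = c(tx = "mRNA"))
  expect_equal(nrow(res$edges), 1L)
  expect_equal(res$edges$score, 0)
  expect_gte(res$edges$n_sites, 2L)
  expect_equal(res$edges$edge_type, "miRNA_target_mRNA")
  # a near-miss-budget site (4 seed-weighted mismatches, expectation 8)
  # yields no edge
  p <- plant_mirna_sites(c(tx2 = random_dna(300)), m,
                         c(near_miss_budget = 1L))
  res2 <- call_targets(m, p$seqs, kinds = c(tx2 = "lncRNA"))
  expect_equal(nrow(res2$edges), 0L)
  expect_error(call_targets(m, c(tx = tgt), kinds = c(other = "mRNA")),
               "kinds missing")
})

test_that("eTM calling enforces all three criteria", {
  set.seed(77)
  mir <- c(mir1 = random_dna(21))
  hosts <- setNames(vapply(1:4, function(i) random_dna(200), ""),
                    paste0("h", 1:4))
  p <- plant_mirna_sites(hosts, mir,
                         c(etm = 1L, near_miss_seed = 1L,
                           near_miss_budget = 1L, near_miss_bulge = 1L))
  tr <- p$truth_sites
  res <- call_etms(mir, p$seqs)
  called_hosts <- unique(res$sites$target_id)
  expect_true(tr$host_id[tr$rule_class == "etm"] %in% called_hosts)
  for (cls in c("near_miss_seed", "near_miss_budget", "near_miss_bulge")) {
    host <- tr$host_id[tr$rule_class == cls]
    win <- tr[tr$rule_class == cls, ]
    overlap <- res$sites[res$sites$target_id == host &
                           res$sites$target_start < win$site_end &
                           win$site_start < res$sites$target_end, ]
    expect_equal(nrow(overlap), 0L, info = cls)
  }
  # every reported site re-validates against the criteria text
  for (r in seq_len(nrow(res$sites))) {
    expect_true(oracle_etm_ok(res$sites$states[r], res$sites$bulge_len[r],
                              res$sites$bulge_after[r]))
  }
  # with require_bulge, the bulge-free qualifying geometry disappears
  p2 <- plant_mirna_sites(c(z = random_dna(200)), mir, c(target = 1L))
  free <- call_etms(mir, p2$seqs)                      # GU at position 1 only
  strict <- call_etms(mir, p2$seqs, require_bulge = TRUE)
  expect_gte(nrow(free$edges), 1L)
  expect_equal(nrow(strict$edges), 0L)
})

test_that("eTM sites with zero-bulge and low budget also appear in duplex_scan", {
  set.seed(78)
  mir <- c(m = random_dna(22))
  p <- plant_mirna_sites(c(h = random_dna(250)), mir, c(target = 1L))
  et <- call_etms(mir, p$seqs)
  sc <- duplex_scan(mir[[1]], p$seqs[[1]], max_expectation = 3,
                    mirna_id = "m", target_id = "h")
  for (r in which(et$sites$bulge_len == 0)) {
    e <- lncnet:::expectation_from_states(et$sites$states[r], 0, 0)
    if (e <= 3) {
      expect_true(any(sc$target_start == et$sites$target_start[r] &
                        sc$bulge_len == 0))
    }
  }
})

test_that("precursor identification applies the strict identity gate", {
  set.seed(79)
  hp <- c(hairpin = random_dna(90))
  # exact containment -> identity 1
  del1 <- paste0(random_dna(100), hp[[1]], random_dna(100))
  res1 <- identify_precursors(c(d1 = del1), hp)
  expect_equal(nrow(res1), 1L)
  expect_equal(res1$score, 1)
  # 10 substitutions in the 90-nt copy: identity 80/90 < 0.90 -> rejected
  v <- strsplit(hp[[1]], "")[[1]]
  pos <- round(seq(5, 85, length.out = 10))
  v[pos] <- c(A = "C", C = "G", G = "T", T = "A")[v[pos]]
  del2 <- paste0(random_dna(100), paste(v, collapse = ""), random_dna(100))
  res2 <- identify_precursors(c(d2 = del2), hp)
  expect_equal(nrow(res2), 0L)
  expect_warning(identify_precursors(c(d = del1), character(0)), "empty")
})

test_that("Smith-Waterman agrees with the textbook DP oracle", {
  set.seed(80)
  for (i in 1:15) {
    a <- random_dna(sample(40:70, 1))
    b <- random_dna(sample(150:250, 1))
    if (i %% 3 == 0) {
      # embed a mutated copy so strong alignments are exercised
      v <- strsplit(a, "")[[1]]
      idx <- sample(length(v), 3)
      v[idx] <- c(A = "C", C = "G", G = "T", T = "A")[v[idx]]
      pos <- sample(nchar(b) - length(v), 1)
      substr(b, pos, pos + length(v) - 1) <- paste(v, collapse = "")
    }
    got <- sw_align(a, b)
    want <- oracle_sw(a, b)
    expect_equal(got$score, want$score)
    expect_equal(got$matches, want$matches)
    expect_equal(got$columns, want$columns)
    expect_equal(got$identity, want$identity)
  }
})
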