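#' Configuration of the synthetic toy study
#'
#' One object fixes every tunable of the generator; the seed fully determines
#' the output. Defaults emulate a 3-vs-3 replicate two-clone latex RNA-seq
#' design: a toy annotated genome with protein-coding genes plus noncoding
#' transcripts of each positional class, NB count matrices with planted
#' log2 fold changes, lncRNA sequences carrying planted miRNA binding sites
#' that satisfy or violate the target/eTM criteria, and precursor-like
#' lncRNAs carrying >= 95 percent identity hairpin copies (plus 88.9 percent
#' identity decoys).
#'
#' @param seed Integer seed; byte-identical output under the same seed.
#' @param n_chromosomes,chrom_length Genome shape (>= 2 chromosomes so trans
#'   partners can be placed cross-chromosome).
#' @param n_coding_genes Plain protein-coding genes (hosts for antisense,
#'   sense, overlapping and decoy layouts are added on top).
#' @param n_lincRNA,n_antisense,n_sense,n_overlapping Planted noncoding
#'   transcripts per positional class.
#' @param n_exonic_decoys,n_coding_decoys,n_short_decoys,n_low_expr_decoys
#'   Candidates that must be removed by, respectively, the same-strand
#'   exonic-overlap, ORF, length, and FPKM filters.
#' @param n_cis_pairs,n_cis_decoys Planted cis lncRNA-gene pairs (correlated)
#'   and near-located decoy pairs (uncorrelated).
#' @param n_trans_pairs,n_trans_decoys Cross-chromosome correlated pairs and
#'   uncorrelated decoy pairs.
#' @param replicates Replicates per group (>= 2; default 3).
#' @param de_fraction Fraction of unreserved features planted DE.
#' @param planted_l2fc Magnitude of planted log2 fold changes.
#' @param dispersion Baseline NB dispersion (Var = mu + alpha mu^2).
#' @param partner_dispersion Dispersion of planted partner features (small,
#'   so the co-expression signal survives counting noise).
#' @param partner_base_mean Baseline mean of planted partner features. With
#'   six samples the 0.95 correlation rule only recovers pairs whose
#'   counting noise is small, so partners are well-expressed by
#'   construction; the down-regulated group still sits near
#'   `partner_base_mean / 2^planted_l2fc` counts.
#' @param latent_sd Log-scale sd of the shared per-sample latent factor that
#'   induces partner correlation (target correlation before counting noise
#'   is 1.0 by construction).
#' @param decoy_latent_sd Log-scale sd of the independent latent factors
#'   given to decoy pairs; decoy latents are resampled until the noiseless
#'   profile correlation satisfies |r| <= `decoy_max_r`.
#' @param decoy_max_r Cap on decoy induced correlation (default 0.5).
#' @param lib_size_range Per-sample library size factors, sampled uniformly.
#' @param mean_log_mu,mean_log_sd Log-normal parameters of baseline means.
#' @param n_mirnas,n_dems miRNA count and how many are planted differential.
#' @param mirna_dispersion NB dispersion of miRNA counts.
#' @param mirna_l2fc Magnitude of planted miRNA log2 fold changes.
#' @param n_hairpins Known hairpin references.
#' @param sites_per_class Named integer vector of planted site counts:
#'   `target`, `target_mrna`, `etm`, `near_miss_seed`, `near_miss_budget`,
#'   `near_miss_bulge`.
#' @param n_precursor_pos,n_precursor_neg Planted hairpin copies at about 98
#'   percent identity and decoy copies at about 88.9 percent identity.
#' @param orf_threshold Codon threshold of the coding surrogate.
#' @param n_terms Annotation terms in the synthetic gene-term map.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              n_chromosomes = 2L, chrom_length = 600000L,
                              n_coding_genes = 30L,
                              n_lincRNA = 10L, n_antisense = 6L,
                              n_sense = 6L, n_overlapping = 2L,
                              n_exonic_decoys = 4L, n_coding_decoys = 4L,
                              n_short_decoys = 3L, n_low_expr_decoys = 3L,
                              n_cis_pairs = 4L, n_cis_decoys = 2L,
                              n_trans_pairs = 4L, n_trans_decoys = 3L,
                              replicates = 3L,
                              de_fraction = 0.3, planted_l2fc = 2,
                              dispersion = 0.05, partner_dispersion = 0.001,
                              partner_base_mean = 2000,
                              latent_sd = 0.4, decoy_latent_sd = 1.2,
                              decoy_max_r = 0.5,
                              lib_size_range = c(0.7, 1.4),
                              mean_log_mu = log(300), mean_log_sd = 0.8,
                              n_mirnas = 6L, n_dems = 4L,
                              mirna_dispersion = 0.01, mirna_l2fc = 2,
                              n_hairpins = 3L,
                              sites_per_class = c(target = 3L,
                                                  target_mrna = 3L,
                                                  etm = 3L,
                                                  near_miss_seed = 3L,
                                                  near_miss_budget = 3L,
                                                  near_miss_bulge = 3L),
                              n_precursor_pos = 2L, n_precursor_neg = 2L,
                              orf_threshold = 100L,
                              n_terms = 8L) {
  cfg <- as.list(environment())
  counts <- c(cfg$n_chromosomes, cfg$chrom_length, cfg$n_coding_genes,
              cfg$n_lincRNA, cfg$n_antisense, cfg$n_sense, cfg$n_overlapping,
              cfg$n_exonic_decoys, cfg$n_coding_decoys, cfg$n_short_decoys,
              cfg$n_low_expr_decoys, cfg$n_cis_pairs, cfg$n_cis_decoys,
              cfg$n_trans_pairs, cfg$n_trans_decoys, cfg$n_mirnas,
              cfg$n_hairpins, cfg$n_terms, cfg$sites_per_class)
  if (any(counts < 0)) stop("all counts must be >= 0")
  if (cfg$replicates < 2L) stop("at least 2 replicates per group are required")
  if (cfg$n_chromosomes < 2L && (cfg$n_trans_pairs + cfg$n_trans_decoys) > 0L) {
    stop("trans pairs need at least 2 chromosomes")
  }
  needed <- c("target", "target_mrna", "etm", "near_miss_seed",
              "near_miss_budget", "near_miss_bulge")
  if (!all(needed %in% names(cfg$sites_per_class))) {
    stop("sites_per_class must name: ", paste(needed, collapse = ", "))
  }
  if (cfg$n_lincRNA < cfg$n_trans_pairs + cfg$n_trans_decoys) {
    stop("n_lincRNA must cover the trans pairs and decoys")
  }
  if (cfg$n_coding_genes < cfg$n_trans_pairs + cfg$n_trans_decoys) {
    stop("n_coding_genes must cover the trans pairs and decoys")
  }
  structure(cfg, class = "simulation_config")
}

# deterministic integer sampler helpers
rint <- function(n, lo, hi) lo + floor(stats::runif(n) * (hi - lo + 1L))
rand_dna <- function(n) {
  paste(c("A", "C", "G", "T")[rint(n, 1L, 4L)], collapse = "")
}
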