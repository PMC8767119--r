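# NB count simulation with planted fold changes and partner correlations.

rnb <- function(n, mu, disp) {
  if (disp < 1e-12) stats::rpois(n, mu) else stats::rnbinom(n, mu = mu, size = 1 / disp)
}

#' Simulate count matrices with planted differential expression
#'
#' Draws NB(mean, dispersion) counts per feature and replicate for the
#' transcriptome (mRNAs + candidates) and the miRNA set. Planted DE features
#' have group-mean ratio `2^planted_l2fc`. Planted cis/trans partner pairs
#' share a per-sample log-normal latent factor and a common fold-change
#' direction, so their noiseless profiles correlate at exactly 1; decoy
#' pairs receive independent latent factors (and opposite fold directions),
#' resampled until the noiseless profile correlation satisfies
#' |r| <= `decoy_max_r`. The low-expression decoy class is all-zero.
#'
#' @param sim Result of [simulate_genome].
#' @param config The same [simulation_config].
#' @return list with `counts` (transcript [expression_matrix]),
#'   `mirna_counts` (miRNA [expression_matrix]), `truth_expression`
#'   (per-feature planted parameters) and `truth_pairs` (completed pair
#'   table with induced correlations, gap distances and orientations).
#' @export
simulate_counts <- function(sim, config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed + 2L)
  R <- config$replicates
  if (R < 2L) stop("at least 2 replicates per group are required")
  groups <- stats::setNames(rep(c("SRJC", "DC"), each = R),
                            c(paste0("SRJC_", seq_len(R)),
                              paste0("DC_", seq_len(R))))
  nS <- 2L * R
  is_srjc <- unname(groups == "SRJC")
  libfac <- config$lib_size_range[1] +
    stats::runif(nS) * diff(config$lib_size_range)

  truth <- sim$truth_features
  ids <- truth$transcript_id
  n <- length(ids)
  base <- pmax(stats::rlnorm(n, config$mean_log_mu, config$mean_log_sd), 50)
  l2fc <- rep(0, n)
  disp <- rep(config$dispersion, n)
  latent <- matrix(1, n, nS, dimnames = list(ids, names(groups)))
  pair_id <- rep(NA_character_, n)
  pair_kind <- rep(NA_character_, n)
  names(base) <- names(l2fc) <- names(disp) <- ids

  base[truth$planted_class == "low_expr_decoy"] <- 0

  sk <- sim$pair_skeleton
  pair_rows <- list()
  tr <- sim$annotation$transcripts
  loc <- function(id) tr[tr$transcript_id == id, ]
  for (i in seq_len(nrow(sk))) {
    l <- sk$lncRNA_id[i]; g <- sk$gene_id[i]; kind <- sk$kind[i]
    pid <- sprintf("P%02d", i)
    pair_id[match(c(l, g), ids)] <- pid
    pair_kind[match(c(l, g), ids)] <- kind
    # partners are well-expressed by construction: at n = 6 samples the
    # |r| > 0.95 rule only works when counting noise is small relative to
    # the shared signal, so the low-expression group must stay in the
    # hundreds of counts
    base[c(l, g)] <- config$partner_base_mean
    disp[c(l, g)] <- config$partner_dispersion
    sign_ <- if (i %% 2L == 0L) 1 else -1
    if (kind %in% c("cis", "trans")) {
      l2fc[c(l, g)] <- sign_ * config$planted_l2fc
      lam <- exp(stats::rnorm(nS, 0, config$latent_sd))
      latent[l, ] <- lam
      latent[g, ] <- lam
    } else {
      l2fc[l] <- sign_ * config$planted_l2fc
      l2fc[g] <- -sign_ * config$planted_l2fc
      for (try in seq_len(100L)) {
        latent[l, ] <- exp(stats::rnorm(nS, 0, config$decoy_latent_sd))
        latent[g, ] <- exp(stats::rnorm(nS, 0, config$decoy_latent_sd))
        mu_l <- base[l] * 2^(l2fc[l] * is_srjc) * latent[l, ]
        mu_g <- base[g] * 2^(l2fc[g] * is_srjc) * latent[g, ]
        if (abs(stats::cor(mu_l, mu_g)) <= config$decoy_max_r) break
        if (try == 100L) stop("could not decorrelate decoy pair ", pid)
      }
    }
    mu_l <- base[l] * 2^(l2fc[l] * is_srjc) * latent[l, ]
    mu_g <- base[g] * 2^(l2fc[g] * is_srjc) * latent[g, ]
    lt <- loc(l); gt <- loc(g)
    same_chrom <- lt$chrom == gt$chrom
    gap <- if (same_chrom) interval_gap(lt$start, lt$end, gt$start, gt$end)
      else NA_integer_
    orientation <- if (same_chrom) {
      lnc_orientation(lt$start, lt$end, gt$start, gt$end, gt$strand)
    } else NA_character_
    pair_rows[[pid]] <- data.frame(
      pair_id = pid, kind = kind, lncRNA_id = l, gene_id = g,
      induced_r = stats::cor(mu_l, mu_g), distance_bp = gap,
      orientation = orientation, l2fc_lnc = l2fc[l], l2fc_gene = l2fc[g],
      stringsAsFactors = FALSE)
  }
  truth_pairs <- if (length(pair_rows)) {
    do.call(rbind, c(pair_rows, make.row.names = FALSE))
  } else {
    data.frame(pair_id = character(), kind = character(),
               lncRNA_id = character(), gene_id = character(),
               induced_r = numeric(), distance_bp = integer(),
               orientation = character(), l2fc_lnc = numeric(),
               l2fc_gene = numeric(), stringsAsFactors = FALSE)
  }

  # unreserved DE: a fraction of remaining true lncRNAs and plain genes
  lnc_classes <- c("lincRNA", "antisense", "sense", "overlapping")
  free_lnc <- ids[truth$planted_class %in% lnc_classes & is.na(pair_id)]
  free_gene <- ids[truth$biotype == "protein_coding" & is.na(pair_id)]
  pick_de <- function(pool) {
    k <- ceiling(config$de_fraction * length(pool))
    if (k > 0L) sample(pool)[seq_len(k)] else character(0)
  }
  de_extra <- c(pick_de(free_lnc), pick_de(free_gene))
  l2fc[de_extra] <- config$planted_l2fc *
    rep_len(c(1, -1), length(de_extra))

  mu <- base * 2^(outer(l2fc, as.numeric(is_srjc))) * latent
  counts <- matrix(0L, n, nS, dimnames = list(ids, names(groups)))
  for (f in seq_len(n)) {
    counts[f, ] <- rnb(nS, mu[f, ] * libfac, disp[f])
  }

  # miRNAs
  nm <- config$n_mirnas
  mir_ids <- sprintf("mir_%03d", seq_len(nm))
  mbase <- stats::rlnorm(nm, log(3000), 0.5)
  ml2fc <- rep(0, nm)
  if (config$n_dems > 0L) {
    ml2fc[seq_len(min(config$n_dems, nm))] <-
      config$mirna_l2fc * rep_len(c(1, -1), min(config$n_dems, nm))
  }
  mlib <- config$lib_size_range[1] + stats::runif(nS) * diff(config$lib_size_range)
  mcounts <- matrix(0L, nm, nS, dimnames = list(mir_ids, names(groups)))
  for (f in seq_len(nm)) {
    mcounts[f, ] <- rnb(nS, mbase[f] * 2^(ml2fc[f] * is_srjc) * mlib,
                        config$mirna_dispersion)
  }

  kind_of <- ifelse(truth$biotype == "protein_coding", "mRNA", "lncRNA")
  truth_expression <- rbind(
    data.frame(feature_id = ids, kind = kind_of, base_mean = unname(base),
               l2fc = unname(l2fc), dispersion = unname(disp),
               is_de = unname(l2fc != 0), pair_id = pair_id,
               pair_kind = pair_kind, stringsAsFactors = FALSE),
    data.frame(feature_id = mir_ids, kind = "miRNA", base_mean = mbase,
               l2fc = ml2fc, dispersion = config$mirna_dispersion,
               is_de = ml2fc != 0, pair_id = NA_character_,
               pair_kind = NA_character_, stringsAsFactors = FALSE))

  list(counts = expression_matrix(counts, groups, "count"),
       mirna_counts = expression_matrix(mcounts, groups, "count"),
       truth_expression = truth_expression,
       truth_pairs = truth_pairs)
}
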