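# Orchestration of the full synthetic study with machine-readable truth.

# transcript-coordinate spans of each exon (0-based half-open), in the
# 5'->3' order of the spliced transcript
exon_transcript_spans <- function(ts, tid) {
  e <- ts$exons[ts$exons$transcript_id == tid, ]
  e <- e[order(e$start), , drop = FALSE]
  w <- e$end - e$start
  if (e$strand[1] == "-") { e <- e[rev(seq_len(nrow(e))), ]; w <- rev(w) }
  t_end <- cumsum(w)
  data.frame(genomic_start = e$start, genomic_end = e$end,
             t_start = t_end - w, t_end = t_end)
}

# the largest exon's transcript-coordinate window, shrunk by a small margin
largest_exon_region <- function(ts, tid, margin = 3L) {
  sp <- exon_transcript_spans(ts, tid)
  k <- which.max(sp$t_end - sp$t_start)
  c(sp$t_start[k] + margin, sp$t_end[k] - margin)
}

# transcripts whose genomic interval overlaps no other transcript (either
# strand); only these host planted sequence edits, so an edit can never leak
# into another transcript's sequence
isolated_transcripts <- function(ts) {
  tr <- ts$transcripts
  ok <- vapply(seq_len(nrow(tr)), function(i) {
    other <- tr[-i, ]
    !any(other$chrom == tr$chrom[i] &
           interval_overlaps(other$start, other$end, tr$start[i], tr$end[i]))
  }, TRUE)
  tr$transcript_id[ok]
}

#' Generate the complete synthetic study
#'
#' Runs [simulate_genome], [simulate_mirnas] and [simulate_counts], plants
#' miRNA binding sites and hairpin copies into differential transcripts
#' (writing every edit back into the genome so annotation, genome and
#' transcript FASTA stay consistent), and builds a synthetic gene-term map
#' in which one term collects the planted partner genes. All outputs are
#' deterministic functions of `config$seed`.
#'
#' @param config A [simulation_config].
#' @param out_dir Optional directory; when given, all study files are
#'   written there (genome/annotation/sequence FASTA and GTF, count TSVs,
#'   term map, truth tables, config JSON).
#' @return list with the in-memory study: `annotation`, `genes`,
#'   `candidates`, `genome`, `seqs`, `mirnas`, `hairpins`, `counts`,
#'   `mirna_counts`, `term_map`, and `truth` (features, expression, pairs,
#'   sites, precursors).
#' @export
simulate_study <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  sim <- simulate_genome(config)
  mir <- simulate_mirnas(config)
  cnt <- simulate_counts(sim, config)

  set.seed(config$seed + 3L)
  ts <- sim$annotation
  seqs <- extract_transcript_seqs(ts, sim$genome)
  texpr <- cnt$truth_expression
  isolated <- isolated_transcripts(ts)
  de_lnc <- texpr$feature_id[texpr$kind == "lncRNA" & texpr$is_de]
  de_lnc <- intersect(de_lnc, sim$truth_features$transcript_id[
    sim$truth_features$expected_survivor])
  de_lnc <- intersect(de_lnc, isolated)
  de_mrna <- intersect(texpr$feature_id[texpr$kind == "mRNA" & texpr$is_de],
                       isolated)
  regions <- lapply(stats::setNames(nm = c(de_lnc, de_mrna)),
                    function(tid) largest_exon_region(ts, tid))
  region_width <- vapply(regions, diff, 0)

  lnc_hosts <- de_lnc[region_width[de_lnc] >= 40]
  mrna_hosts <- de_mrna[region_width[de_mrna] >= 40]
  spc <- config$sites_per_class
  lnc_classes <- spc[setdiff(names(spc), "target_mrna")]
  if (length(lnc_hosts) == 0L && sum(lnc_classes) > 0L) {
    stop("no differential lncRNA can host a site")
  }
  if (length(mrna_hosts) == 0L && spc[["target_mrna"]] > 0L) {
    stop("no differential mRNA can host a site")
  }
  p1 <- plant_mirna_sites(seqs, mir$mirnas, lnc_classes, hosts = lnc_hosts,
                          allowed_regions = regions)
  p2 <- plant_mirna_sites(p1$seqs, mir$mirnas,
                          spc["target_mrna"], hosts = mrna_hosts,
                          allowed_regions = regions, occupied = p1$occupied)
  hp_hosts <- de_lnc[region_width[de_lnc] >= max(nchar(mir$hairpins)) + 12]
  if (length(hp_hosts) == 0L &&
      (config$n_precursor_pos + config$n_precursor_neg) > 0L) {
    stop("no differential lncRNA is long enough to host a hairpin copy")
  }
  p3 <- plant_precursors(p2$seqs, mir$hairpins, config$n_precursor_pos,
                         config$n_precursor_neg, hosts = hp_hosts,
                         allowed_regions = regions, occupied = p2$occupied)
  seqs <- p3$seqs

  # write every edit back into the genome so sequence extraction and the
  # planted transcript sequences agree
  genome <- sim$genome
  all_windows <- rbind(
    data.frame(host = c(p1$truth_sites$host_id, p2$truth_sites$host_id),
               start = c(p1$truth_sites$site_start, p2$truth_sites$site_start),
               end = c(p1$truth_sites$site_end, p2$truth_sites$site_end),
               stringsAsFactors = FALSE),
    data.frame(host = p3$truth_precursors$host_id,
               start = p3$truth_precursors$insert_start,
               end = p3$truth_precursors$insert_end,
               stringsAsFactors = FALSE))
  for (i in seq_len(nrow(all_windows))) {
    w <- all_windows[i, ]
    genome <- write_spliced(genome, ts, w$host, w$start,
                            substr(seqs[[w$host]], w$start + 1L, w$end))
  }

  # planted inserts can re-open a long ORF in a noncoding host; break any
  # such ORF with a stop codon placed outside every planted window
  noncoding <- sim$truth_features$transcript_id[
    sim$truth_features$biotype == "candidate" &
      sim$truth_features$planted_class != "coding_decoy"]
  for (host in intersect(unique(all_windows$host), noncoding)) {
    win <- p3$occupied[[host]]
    for (iter in seq_len(20L)) {
      d <- orf_detail(seqs[[host]])
      if (d$codons < config$orf_threshold) break
      codon_starts <- d$start_nt - 1L + 3L * (seq_len(d$codons) - 1L)
      codon_starts <- codon_starts[order(abs(codon_starts - stats::median(codon_starts)))]
      free <- codon_starts[vapply(codon_starts, function(cs)
        is.null(win) || !any(win$start < cs + 3L & cs < win$end), TRUE)]
      if (length(free) == 0L) {
        stop("cannot break a re-opened ORF in ", host,
             " without touching a planted site")
      }
      substr(seqs[[host]], free[1] + 1L, free[1] + 3L) <- "TAA"
      genome <- write_spliced(genome, ts, host, free[1], "TAA")
    }
  }

  check <- extract_transcript_seqs(
    subset_transcripts(ts, unique(all_windows$host)), genome)
  if (!identical(unname(check), unname(seqs[names(check)]))) {
    stop("internal error: genome write-back does not reproduce the edited transcripts")
  }

  truth_sites <- rbind(p1$truth_sites, p2$truth_sites)

  # synthetic term map: one term collects the planted partner genes, the
  # rest are random; every gene gets at least one term
  mrna_ids <- ts$transcripts$transcript_id[ts$transcripts$biotype == "protein_coding"]
  partner_genes <- unique(cnt$truth_pairs$gene_id[
    cnt$truth_pairs$kind %in% c("cis", "trans")])
  terms <- list(T01 = partner_genes)
  for (k in seq_len(max(config$n_terms - 1L, 0L))) {
    terms[[sprintf("T%02d", k + 1L)]] <-
      sample(mrna_ids, rint(1L, 5L, min(12L, length(mrna_ids))))
  }
  unannotated <- setdiff(mrna_ids, unique(unlist(terms)))
  if (length(unannotated)) {
    spread <- sprintf("T%02d", (seq_along(unannotated) %% max(config$n_terms, 1L)) + 1L)
    for (i in seq_along(unannotated)) {
      terms[[spread[i]]] <- c(terms[[spread[i]]], unannotated[i])
    }
  }
  term_map <- do.call(rbind, lapply(names(terms), function(tm) {
    data.frame(gene_id = unique(terms[[tm]]), term_id = tm,
               term_name = paste0("synthetic term ", tm),
               stringsAsFactors = FALSE)
  }))

  study <- list(config = config, annotation = ts, genes = sim$genes,
                candidates = sim$candidates, genome = genome, seqs = seqs,
                mirnas = mir$mirnas, hairpins = mir$hairpins,
                counts = cnt$counts, mirna_counts = cnt$mirna_counts,
                term_map = term_map,
                truth = list(features = sim$truth_features,
                             expression = cnt$truth_expression,
                             pairs = cnt$truth_pairs,
                             sites = truth_sites,
                             precursors = p3$truth_precursors))
  if (!is.null(out_dir)) write_study(study, out_dir)
  study
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

# write all study files; plain-text formats only
write_study <- function(study, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(x) file.path(out_dir, x)
  write_fasta(study$genome, fp("genome.fa"))
  write_annotation(study$annotation, fp("annotation.gtf"))
  write_fasta(study$seqs, fp("transcripts.fa"))
  write_fasta(study$mirnas, fp("mirnas.fa"))
  write_fasta(study$hairpins, fp("hairpins.synthetic.fa"))
  write_counts(study$counts, fp("counts_transcripts.tsv"))
  write_counts(study$mirna_counts, fp("counts_mirnas.tsv"))
  write_tsv(study$term_map, fp("term_map.tsv"))
  write_tsv(study$truth$features, fp("truth_features.tsv"))
  write_tsv(study$truth$expression, fp("truth_expression.tsv"))
  write_tsv(study$truth$pairs, fp("truth_pairs.tsv"))
  write_tsv(study$truth$sites, fp("truth_sites.tsv"))
  write_tsv(study$truth$precursors, fp("truth_precursors.tsv"))
  cfg <- unclass(study$config)
  jsonlite::write_json(cfg, fp("config.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
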