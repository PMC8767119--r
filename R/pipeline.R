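# End-to-end pipeline: simulate -> discover -> de -> targets -> mirna ->
# enrich -> network, with a reproducibility manifest.

#' Run the complete analysis pipeline on a synthetic study
#'
#' Generates (or reuses) a synthetic study, writes its files, reads them back
#' through the package's own format readers, and runs every analysis stage,
#' writing all result tables under `out_dir`. The run is a pure function of
#' the seed: two runs with the same seed produce byte-identical files.
#'
#' @param config A [simulation_config] (its seed drives everything).
#' @param out_dir Output directory; study inputs go to `out_dir/study`,
#'   result tables to `out_dir/results`.
#' @param keep_all_network Disable the miRNA-anchored network filter.
#' @return list with all intermediate objects (invisible file paths in
#'   `$files`).
#' @export
run_pipeline <- function(config, out_dir, keep_all_network = FALSE) {
  stopifnot(inherits(config, "simulation_config"))
  study_dir <- file.path(out_dir, "study")
  res_dir <- file.path(out_dir, "results")
  dir.create(res_dir, recursive = TRUE, showWarnings = FALSE)
  study <- simulate_study(config, out_dir = study_dir)

  # read the study back through the format layer
  ann <- read_annotation(file.path(study_dir, "annotation.gtf"))
  genome <- read_fasta(file.path(study_dir, "genome.fa"))
  seqs <- read_fasta(file.path(study_dir, "transcripts.fa"))
  mirnas <- read_fasta(file.path(study_dir, "mirnas.fa"))
  hairpins <- read_fasta(file.path(study_dir, "hairpins.synthetic.fa"))
  counts <- read_counts(file.path(study_dir, "counts_transcripts.tsv"))
  mir_counts <- read_counts(file.path(study_dir, "counts_mirnas.tsv"))
  term_map <- read_term_map(file.path(study_dir, "term_map.tsv"))

  tr <- ann$transcripts
  coding <- subset_transcripts(ann, tr$transcript_id[tr$biotype == "protein_coding"])
  candidates <- subset_transcripts(ann, tr$transcript_id[tr$biotype == "candidate"])

  # expression + discovery
  lengths <- stats::setNames(tr$length, tr$transcript_id)
  fpkm <- compute_fpkm(counts, lengths, robust = TRUE)
  mir_tpm <- compute_mirna_tpm(mir_counts)
  disc <- discover_lncrnas(candidates, coding,
                           expression_matrix(
                             fpkm$values[candidates$transcripts$transcript_id, ,
                                         drop = FALSE],
                             fpkm$groups, "FPKM"),
                           seqs[candidates$transcripts$transcript_id],
                           orf_threshold = config$orf_threshold)
  write_tsv(disc$records, file.path(res_dir, "lncrna_records.tsv"))
  write_tsv(disc$tally, file.path(res_dir, "filter_tally.tsv"))
  feats <- summarize_features(disc$records)
  write_tsv(feats$length_bins, file.path(res_dir, "length_bins.tsv"))
  write_tsv(feats$classes, file.path(res_dir, "class_proportions.tsv"))

  # differential expression (mRNAs + identified lncRNAs; miRNAs separately)
  mrna_ids <- coding$transcripts$transcript_id
  lnc_ids <- disc$records$transcript_id
  de_tx <- nb_differential_test(
    expression_matrix(counts$values[c(mrna_ids, lnc_ids), , drop = FALSE],
                      counts$groups, "count"),
    feature_kind = c(rep("mRNA", length(mrna_ids)),
                     rep("lncRNA", length(lnc_ids))),
    numerator = "SRJC")
  de_mir <- nb_differential_test(mir_counts, feature_kind = "miRNA",
                                 numerator = "SRJC")
  de <- rbind(de_tx, de_mir)
  write_tsv(de, file.path(res_dir, "differential_expression.tsv"))
  dels <- de$feature_id[de$feature_kind == "lncRNA" & de$call != "not_DE"]
  degs <- de$feature_id[de$feature_kind == "mRNA" & de$call != "not_DE"]
  dems <- de$feature_id[de$feature_kind == "miRNA" & de$call != "not_DE"]

  # cis / trans target assignment on FPKM
  cis <- assign_cis(dels, degs, ann, fpkm)
  trans <- assign_trans(dels, degs, fpkm, cis_pairs = cis)
  write_tsv(cis, file.path(res_dir, "cis_pairs.tsv"))
  write_tsv(trans, file.path(res_dir, "trans_pairs.tsv"))

  # miRNA interactions of differential features
  kinds <- stats::setNames(
    ifelse(c(dels, degs) %in% dels, "lncRNA", "mRNA"), c(dels, degs))
  tg <- call_targets(mirnas[dems], seqs[c(dels, degs)], kinds)
  et <- call_etms(mirnas[dems], seqs[dels])
  pre <- identify_precursors(seqs[dels], hairpins)
  write_tsv(tg$edges, file.path(res_dir, "mirna_targets.tsv"))
  if (!is.null(tg$sites)) write_tsv(tg$sites, file.path(res_dir, "mirna_target_sites.tsv"))
  write_tsv(et$edges, file.path(res_dir, "etm_edges.tsv"))
  if (!is.null(et$sites)) write_tsv(et$sites, file.path(res_dir, "etm_sites.tsv"))
  write_tsv(pre, file.path(res_dir, "precursors.tsv"))

  # enrichment of cis+trans target genes
  targets <- unique(c(cis$gene_id, trans$gene_id))
  enr <- if (length(targets)) {
    hypergeometric_enrichment(targets, term_map)
  } else data.frame()
  write_tsv(enr, file.path(res_dir, "enrichment.tsv"))

  # network assembly
  node_classes <- c(
    stats::setNames(rep("mRNA", length(mrna_ids)), mrna_ids),
    stats::setNames(rep("lncRNA", length(lnc_ids)), lnc_ids),
    stats::setNames(rep("miRNA", length(mirnas)), names(mirnas)),
    stats::setNames(rep("miRNA", length(hairpins)), names(hairpins)))
  net <- build_network(cis = cis, trans = trans, mirna_targets = tg$edges,
                       etms = et$edges, precursors = pre,
                       node_classes = node_classes,
                       keep_all = keep_all_network)
  write_network(net$edges[, c("source", "target", "edge_type", "score")],
                net$nodes[, c("id", "class")],
                file.path(res_dir, "network.tsv"), format = "tsv")
  write_network(net$edges[, c("source", "target", "edge_type", "score")],
                net$nodes[, c("id", "class")],
                file.path(res_dir, "network.graphml"), format = "graphml")
  write_tsv(net$summary$nodes_by_class, file.path(res_dir, "network_nodes_by_class.tsv"))
  write_tsv(net$summary$edges_by_type, file.path(res_dir, "network_edges_by_type.tsv"))

  # reproducibility manifest: parameters, seed, input checksums
  files <- sort(c(list.files(study_dir, full.names = TRUE),
                  list.files(res_dir, full.names = TRUE)))
  manifest <- list(seed = config$seed,
                   parameters = unclass(config),
                   files = lapply(stats::setNames(files, basename(files)),
                                  function(f) unname(tools::md5sum(f))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(study = study, discovery = disc, de = de, cis = cis,
                 trans = trans, mirna_targets = tg, etms = et,
                 precursors = pre, enrichment = enr, network = net,
                 files = files))
}

#' Command-line entry point
#'
#' Subcommands: `all` (full pipeline), `simulate` (study generation only).
#' Usage: `lncnet <subcommand> --seed <int> --out <dir>`.
#'
#' @param args Character vector of command-line arguments.
#' @return Exit status (0 on success), invisibly.
#' @export
lncnet_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) < 1L || !args[1] %in% c("all", "simulate")) {
    message("usage: lncnet <all|simulate> [--seed N] [--out DIR]")
    return(invisible(1L))
  }
  sub <- args[1]
  opt <- list(seed = 1L, out = "lncnet_run")
  rest <- args[-1]
  i <- 1L
  while (i <= length(rest)) {
    key <- sub("^--", "", rest[i])
    if (!key %in% names(opt)) stop("unknown option: ", rest[i])
    opt[[key]] <- rest[i + 1L]
    i <- i + 2L
  }
  cfg <- simulation_config(seed = as.integer(opt$seed))
  if (sub == "all") {
    run_pipeline(cfg, opt$out)
  } else {
    simulate_study(cfg, out_dir = file.path(opt$out, "study"))
  }
  message("done: ", opt$out)
  invisible(0L)
}
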