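# End-to-end orchestration on synthetic inputs: simulate -> consensus ->
# subtract controls -> knockdown-sensitive acetylation -> annotate -> feature
# enrichment -> expression -> motifs -> overlap statistics -> GRN, with a
# JSON run manifest recording counts and checksums of every emitted file.

#' Default pipeline configuration
#'
#' @param seed Master seed for every stochastic stage.
#' @param synthetic Named list of [synthetic_config()] overrides.
#' @param consensus_fdr_max FDR ceiling for factor ChIP consensus (default
#'   0.05).
#' @param acetyl_fdr_max FDR ceiling for the acetylation mark (default 0.2).
#' @param min_support,n_replicates Consensus support parameters (2 of 3).
#' @param gmnn_dependent_fraction Fraction of acetylation true peaks omitted
#'   from the knockdown arm (the planted knockdown-sensitive fraction).
#' @param fold_threshold Expression fold-change threshold (default 2).
#' @param score_fraction PWM hit threshold as a fraction of the maximum
#'   attainable score.
#' @param n_background_per_peak Background regions sampled per peak for
#'   motif enrichment.
#' @param motif_peak_cap Number of peak sequences scanned (keeps runtime
#'   bounded; peaks are taken in coordinate order).
#' @param tf_every Every `tf_every`-th gene id forms the synthetic TF
#'   catalog.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, synthetic = list(),
                            consensus_fdr_max = 0.05, acetyl_fdr_max = 0.2,
                            min_support = 2L, n_replicates = 3L,
                            gmnn_dependent_fraction = 0.3,
                            fold_threshold = 2, score_fraction = 0.8,
                            n_background_per_peak = 2L,
                            motif_peak_cap = 150L, tf_every = 3L) {
  cfg <- as.list(environment())
  synthetic$seed <- NULL    # the pipeline seed governs all stages
  cfg$synthetic <- do.call(synthetic_config,
                           c(list(seed = seed), synthetic))
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipeline_config()]; the `synthetic` mapping
#' holds [synthetic_config()] overrides. Unknown keys raise an error.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ","))
  do.call(pipeline_config, raw)
}

#' Write a pipeline configuration to YAML
#' @param config A `pipeline_config`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_pipeline_config <- function(config, path) {
  flat <- unclass(config)
  flat$synthetic <- unclass(flat$synthetic)
  yaml::write_yaml(flat, path)
  invisible(path)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full pipeline on synthetic data
#'
#' Executes every stage in dependency order inside `outdir`, writing the
#' stage outputs (BED, TSV, FASTA, GraphML/DOT) and a `manifest.json`
#' recording the effective configuration, per-stage record counts, and md5
#' checksums of every emitted file. Rerunning with the same configuration
#' and seed reproduces every checksum.
#'
#' @param config A `pipeline_config` (or path to a YAML config).
#' @param outdir Output directory (created if missing).
#' @return The manifest, invisibly (also written to
#'   `file.path(outdir, "manifest.json")`).
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = tempfile("run")) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  scfg <- config$synthetic
  counts <- list()
  path <- function(...) file.path(outdir, ...)
  write_pipeline_config(config, path("config.yaml"))

  ## stage 1: genome + annotation
  gen <- simulate_genome(scfg)
  ann <- gen$annotation
  writeLines(sprintf("%s\t%d", names(gen$sizes), as.integer(gen$sizes)),
             path("chrom.sizes"))
  write_bed(gen$genes_bed12, path("genes.bed12"), "bed12")
  write_bed(ann$cpg_islands, path("cpg_islands.bed"), "bed3")
  write_bed(ann$enhancers, path("enhancers.bed"), "bed3")
  Biostrings::writeXStringSet(gen$genome, path("genome.fa"))
  counts$genes <- nrow(ann$genes)

  ## stage 2: peak simulation (factor A, co-bound factor B, acetylation arms)
  simA <- simulate_peak_replicates(scfg, ann, factor = "Gmnn",
                                   condition = "NE", stage = 2L)
  simB <- simulate_cobound_factor(scfg, simA, ann, factor = "Zic1",
                                  condition = "NE", stage = 3L)
  ac_true <- .place_true_peaks(scfg, ann, scfg$peaks_per_replicate,
                               .child_seed(scfg, 6L))$gr
  keep_in_dox <- with_seed(.child_seed(scfg, 6L) + 1L,
                           stats::runif(length(ac_true)) >=
                             config$gmnn_dependent_fraction)
  no_dox <- .replicate_wrap(scfg, ann, ac_true, "H3K9ac", "NE",
                            .child_seed(scfg, 6L) + 2L)
  dox <- .replicate_wrap(scfg, ann, ac_true[keep_in_dox], "H3K9ac", "NE+Dox",
                         .child_seed(scfg, 6L) + 3L)
  for (i in seq_along(simA$replicates))
    write_bed(simA$replicates[[i]]$gr, path(sprintf("gmnn_rep%d.bed", i)))
  for (i in seq_along(simB$replicates))
    write_bed(simB$replicates[[i]]$gr, path(sprintf("zic1_rep%d.bed", i)))
  .write_tsv(simA$truth, path("truth_gmnn_peaks.tsv"))
  .write_tsv(simB$truth, path("truth_zic1_peaks.tsv"))
  counts$gmnn_replicate_peaks <- vapply(simA$replicates, length, 1L)

  ## stage 3: consensus + control subtraction + knockdown-sensitive peaks
  cpar <- consensus_params(config$consensus_fdr_max, config$min_support,
                           config$n_replicates)
  apar <- consensus_params(config$acetyl_fdr_max, config$min_support,
                           config$n_replicates)
  consA <- subtract_control(consensus_peaks(simA$replicates, cpar),
                            simA$controls)
  consB <- subtract_control(consensus_peaks(simB$replicates, cpar),
                            simB$controls)
  ac_dep <- gmnn_dependent_acetylation(no_dox$replicates, dox$replicates, apar)
  write_bed(consA$gr, path("gmnn_consensus.bed"))
  write_bed(consB$gr, path("zic1_consensus.bed"))
  write_bed(ac_dep$gr, path("h3k9ac_gmnn_dependent.bed"))
  counts$gmnn_consensus <- length(consA)
  counts$zic1_consensus <- length(consB)
  counts$acetyl_dependent <- length(ac_dep)

  ## stage 4: nearest-TSS annotation, location classes, feature enrichment
  assignA <- nearest_tss(consA$gr, ann)
  assignB <- nearest_tss(consB$gr, ann)
  assignAc <- nearest_tss(ac_dep$gr, ann)
  locA <- classify_genomic_location(consA$gr, ann)
  assignA$category <- as.character(locA)
  assignB$category <- as.character(classify_genomic_location(consB$gr, ann))
  .write_tsv(assignA, path("gmnn_annotation.tsv"))
  .write_tsv(assignB, path("zic1_annotation.tsv"))
  enr <- rbind(
    feature_enrichment(consA$gr, ann$promoters, gen$sizes, "promoter"),
    feature_enrichment(consA$gr, ann$cpg_islands, gen$sizes, "cpg_island"),
    feature_enrichment(consA$gr, ann$enhancers, gen$sizes, "enhancer"))
  .write_tsv(enr, path("gmnn_feature_enrichment.tsv"))
  counts$gmnn_genes <- length(unique(stats::na.omit(assignA$gene_id)))
  counts$zic1_genes <- length(unique(stats::na.omit(assignB$gene_id)))

  ## stage 5: expression
  expr_sim <- simulate_expression(scfg, ann)
  m <- rpkm_normalize(expr_sim$counts, expr_sim$gene_lengths,
                      library_sizes = expr_sim$library_sizes,
                      sample_groups = expr_sim$sample_groups)
  m <- zscore_rows(m)
  labels <- classify_enrichment(m, "embryonic_CNS", "ES",
                                fold_threshold = config$fold_threshold)
  .write_tsv(data.frame(gene_id = rownames(m$rpkm), round(m$rpkm, 4)),
             path("rpkm.tsv"))
  .write_tsv(labels, path("cns_enrichment.tsv"))
  .write_tsv(expr_sim$truth, path("truth_expression.tsv"))
  counts$cns_enriched_genes <- sum(labels$label == "enriched")

  ## stage 6: motif enrichment on factor-B peak sequences
  zic_pwm <- motif_pwm(.zic_like_counts(), name = "Zic_like")
  shuf_pwm <- motif_pwm(.zic_like_counts()[, c(4, 6, 1, 5, 3, 7, 2)],
                        name = "Zic_like_shuffled")
  target_peaks <- utils::head(consB$gr, config$motif_peak_cap)
  target_seqs <- extract_peak_sequences(target_peaks, gen$genome)
  planted <- plant_motif(scfg, target_seqs, zic_pwm)
  bg <- sample_background_regions(target_peaks, gen$sizes,
                                  seed = .child_seed(scfg, 7L),
                                  n_per_peak = config$n_background_per_peak)
  bg_seqs <- extract_peak_sequences(bg, gen$genome)
  motif_tab <- rank_motifs(planted$sequences, bg_seqs,
                           list(zic_pwm, shuf_pwm),
                           score_fraction = config$score_fraction)
  .write_tsv(motif_tab, path("motif_enrichment.tsv"))
  counts$motifs_tested <- nrow(motif_tab)

  ## stage 7: overlap statistics between the two factors' gene sets
  genesA <- sort(unique(stats::na.omit(assignA$gene_id)))
  genesB <- sort(unique(stats::na.omit(assignB$gene_id)))
  universe <- ann$genes$gene_id
  ov <- overlap_test(genesA, genesB, universe)
  vc <- venn_counts(list(Gmnn = genesA, Zic1 = genesB))
  .write_tsv(data.frame(metric = c("chi2_yates", "p_chi2", "p_hypergeom",
                                   "jaccard", names(vc)),
                        value = c(ov$chi2_yates, ov$p_chi2, ov$p_hypergeom,
                                  ov$jaccard, as.numeric(vc))),
             path("overlap_stats.tsv"))
  counts$shared_genes <- ov$table$a

  ## stage 8: GRN
  cob <- cobound_targets(consA, consB, ann)
  tf_list <- universe[seq_along(universe) %% config$tf_every == 0L]
  acetyl_genes <- sort(unique(stats::na.omit(assignAc$gene_id)))
  catalog <- gene_set_catalog(list(Gmnn = genesA, Zic1 = genesB))
  grn <- suppressWarnings(build_grn(catalog, tf_list = tf_list,
                                    enrichment_labels = labels,
                                    acetylation_genes = acetyl_genes,
                                    cobound_genes = cob$genes))
  export_grn(grn, path("grn_edges.tsv"), "edge_tsv")
  export_grn(grn, path("grn.graphml"), "graphml")
  export_grn(grn, path("grn.dot"), "dot")
  counts$cobound_peaks <- length(cob$peaks)
  counts$grn_edges <- nrow(grn$edges)
  counts$grn_nodes <- nrow(grn$nodes)

  ## manifest
  files <- sort(list.files(outdir, recursive = TRUE))
  files <- setdiff(files, "manifest.json")
  checksums <- as.list(tools::md5sum(file.path(outdir, files)))
  names(checksums) <- files
  manifest <- list(tool = "neurogrn",
                   version = as.character(utils::packageVersion("neurogrn")),
                   seed = config$seed,
                   counts = counts,
                   checksums = checksums)
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}

# a Zic-family-like GC-rich consensus count matrix (7 positions)
.zic_like_counts <- function() {
  matrix(c( 2,  1, 90,  2,  1,  2, 10,   # A
           90,  2,  2, 90,  2, 90, 30,   # C
            6, 95,  6,  6, 95,  6, 50,   # G
            2,  2,  2,  2,  2,  2, 10),  # T
         nrow = 4, byrow = TRUE)
}
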