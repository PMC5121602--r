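# Synthetic-data generators with planted ground truth. Defaults emulate the
# assayed study conditions: 3 ChIP replicates with FDR-scored peaks and an
# attainable 2-of-3 consensus, input/untagged control sets, a second factor
# sharing a planted co-binding fraction, a three-tissue expression panel with
# a planted embryonic-CNS-enriched gene subset, and peak sequences with a
# motif planted at a stated rate. Everything is deterministic under the
# master seed; each generator derives a stage-specific child seed so stages
# can be regenerated independently.

#' Synthetic-data configuration
#'
#' @param seed Master integer seed; child seeds per generator stage are
#'   derived from it.
#' @param n_chroms,chrom_length_bp Genome shape.
#' @param n_genes,n_cpg_islands,n_enhancers Annotation feature counts.
#' @param peaks_per_replicate Number of planted true peaks.
#' @param n_replicates Replicates per condition (default 3).
#' @param replicate_reproducibility Probability a true peak appears in a
#'   given replicate.
#' @param promoter_planting_fraction Fraction of true peaks placed inside
#'   promoters (the rest are placed uniformly outside promoters).
#' @param noise_peaks_per_replicate Replicate-specific noise peaks appended.
#' @param control_peak_rate Control set size as a fraction of
#'   `peaks_per_replicate`.
#' @param control_contamination Fraction of control peaks coinciding with
#'   true peaks.
#' @param cobinding_fraction Fraction of factor-A true peaks duplicated
#'   (with jitter) into a second factor's true set.
#' @param fdr_threshold FDR ceiling the analysis will use; true peaks draw
#'   FDR ~ Uniform(0, threshold/2), noise peaks ~ Uniform(0, 1).
#' @param peak_jitter_frac Replicate-to-replicate coordinate jitter as a
#'   fraction of peak width (default 0.1, i.e. edges move by up to 10%).
#' @param peak_width_mean,peak_width_sd,peak_width_min Peak width (bp)
#'   distribution (normal, clipped below).
#' @param n_samples_per_group Samples per tissue group (ES, embryonic_CNS,
#'   adult).
#' @param planted_cns_fraction Fraction of genes flagged CNS-enriched.
#' @param planted_fold Expression fold applied to flagged genes in
#'   embryonic-CNS samples.
#' @param nb_size Negative-binomial size (1/dispersion) for counts.
#' @param base_mean Mean baseline count per gene (log-normal across genes).
#' @param motif_planting_rate Fraction of target sequences receiving a
#'   planted motif site.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1L,
                             n_chroms = 3L, chrom_length_bp = 1e6,
                             n_genes = 300L, n_cpg_islands = 200L,
                             n_enhancers = 300L,
                             peaks_per_replicate = 500L, n_replicates = 3L,
                             replicate_reproducibility = 0.8,
                             promoter_planting_fraction = 0.4,
                             noise_peaks_per_replicate = 100L,
                             control_peak_rate = 0.1,
                             control_contamination = 0.1,
                             cobinding_fraction = 0.3,
                             fdr_threshold = 0.05,
                             peak_jitter_frac = 0.1,
                             peak_width_mean = 300, peak_width_sd = 80,
                             peak_width_min = 50,
                             n_samples_per_group = 3L,
                             planted_cns_fraction = 0.3,
                             planted_fold = 4,
                             nb_size = 10,
                             base_mean = 100,
                             motif_planting_rate = 0.5) {
  cfg <- as.list(environment())
  probs <- c(cfg$replicate_reproducibility, cfg$promoter_planting_fraction,
             cfg$control_peak_rate, cfg$control_contamination,
             cfg$cobinding_fraction, cfg$planted_cns_fraction,
             cfg$motif_planting_rate)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (cfg$planted_fold <= 0) stop("planted_fold must be > 0")
  if (cfg$fdr_threshold <= 0 || cfg$fdr_threshold > 1)
    stop("fdr_threshold must be in (0, 1]")
  structure(cfg, class = "synthetic_config")
}

# deterministic per-stage child seed, kept well below 2^31
.child_seed <- function(cfg, stage) {
  (abs(cfg$seed) %% 100000L) * 10000L + stage
}

.rand_widths <- function(cfg, n) {
  pmax(round(stats::rnorm(n, cfg$peak_width_mean, cfg$peak_width_sd)),
       cfg$peak_width_min)
}

#' Simulate a genome, annotation, and sequence
#'
#' Gene bodies are non-overlapping (slot placement), each with 2-5 exons, a
#' CDS (thick) region, and a uniformly assigned strand. CpG-island and
#' enhancer intervals are placed uniformly within bounds. The sequence is
#' i.i.d. uniform over A/C/G/T.
#'
#' @param cfg A [synthetic_config()].
#' @param with_sequence Generate the nucleotide sequence (default TRUE; the
#'   sequence is drawn after all interval features, so annotations are
#'   identical either way). Skipping it speeds up large peak-only
#'   simulations.
#' @return List with `annotation` (a `genome_annotation`), `genes_bed12` (a
#'   BED12-style `GRanges`, writable with [write_bed()]), `genome` (a named
#'   `DNAStringSet`, or `NULL`), and `sizes` (a `chrom_sizes`).
#' @export
simulate_genome <- function(cfg, with_sequence = TRUE) {
  stopifnot(inherits(cfg, "synthetic_config"))
  with_seed(.child_seed(cfg, 1L), {
    chroms <- sprintf("chr%d", seq_len(cfg$n_chroms))
    sizes <- chrom_sizes(stats::setNames(rep(cfg$chrom_length_bp, cfg$n_chroms),
                                         chroms))
    slot <- 10000L
    slots_per_chrom <- floor(cfg$chrom_length_bp / slot)
    total_slots <- cfg$n_chroms * slots_per_chrom
    if (cfg$n_genes > total_slots)
      stop("capacity error: ", cfg$n_genes, " genes cannot fit in ",
           total_slots, " gene slots")
    if (cfg$n_genes > 0L) {
      chosen <- sort(sample.int(total_slots, cfg$n_genes))
      chrom_idx <- (chosen - 1L) %/% slots_per_chrom + 1L
      slot_off <- ((chosen - 1L) %% slots_per_chrom) * slot
      span <- sample(2000:8000, cfg$n_genes, replace = TRUE)
      gstart <- slot_off + vapply(slot - 1000L - span,
                                  function(r) sample.int(r, 1L), 1L)
      gend <- gstart + span
      strand <- sample(c("+", "-"), cfg$n_genes, replace = TRUE)
      n_ex <- sample(2:5, cfg$n_genes, replace = TRUE)
      bs <- bst <- character(cfg$n_genes)
      for (i in seq_len(cfg$n_genes)) {
        k <- n_ex[i]
        # k exons: cut the span into 2k-1 alternating exon/intron pieces
        cuts <- sort(sample.int(span[i] - 1L, 2L * k - 2L))
        bounds <- c(0L, cuts, span[i])
        starts <- bounds[seq(1, 2 * k - 1, by = 2)]
        ends <- bounds[seq(2, 2 * k, by = 2)]
        keep <- ends > starts
        starts <- starts[keep]; ends <- ends[keep]
        bs[i] <- paste0(paste(ends - starts, collapse = ","), ",")
        bst[i] <- paste0(paste(starts, collapse = ","), ",")
      }
      thick_s <- gstart + round(span * 0.2)
      thick_e <- gstart + round(span * 0.8)
      genes_bed12 <- granges0(chroms[chrom_idx], gstart, gend, strand = strand,
                              name = sprintf("gene%04d", seq_len(cfg$n_genes)),
                              score = rep(0, cfg$n_genes), sizes = sizes)
      ord <- order(chroms[chrom_idx], gstart, gend)
      mcols(genes_bed12)$thick_start0 <- thick_s[ord]
      mcols(genes_bed12)$thick_end0 <- thick_e[ord]
      mcols(genes_bed12)$block_sizes <- bs[ord]
      mcols(genes_bed12)$block_starts <- bst[ord]
    } else {
      genes_bed12 <- granges0(character(0), integer(0), integer(0), sizes = sizes)
    }
    place_uniform <- function(n, width_mean, width_sd, width_min) {
      if (n == 0L)
        return(granges0(character(0), integer(0), integer(0), sizes = sizes))
      w <- pmax(round(stats::rnorm(n, width_mean, width_sd)), width_min)
      ch <- sample(chroms, n, replace = TRUE)
      s0 <- vapply(cfg$chrom_length_bp - w,
                   function(r) sample.int(r, 1L) - 1L, 1L)
      granges0(ch, s0, s0 + w, name = sprintf("f%d", seq_len(n)), sizes = sizes)
    }
    cpg <- place_uniform(cfg$n_cpg_islands, 601, 150, 200)
    enh <- place_uniform(cfg$n_enhancers, 271, 60, 100)
    genome <- NULL
    if (with_sequence) {
      genome <- Biostrings::DNAStringSet(vapply(chroms, function(ch)
        paste(sample(c("A", "C", "G", "T"), cfg$chrom_length_bp, replace = TRUE),
              collapse = ""), ""))
      names(genome) <- chroms
    }
    ann <- build_annotation(genes_bed12, cpg_islands = cpg, enhancers = enh,
                            sizes = sizes)
    list(annotation = ann, genes_bed12 = genes_bed12, genome = genome,
         sizes = sizes)
  })
}

# place n true peaks: frac in promoters (midpoint inside a promoter), rest
# uniform with midpoint outside any promoter
.place_true_peaks <- function(cfg, annotation, n, seed) {
  sizes <- annotation$chrom_sizes
  prom <- annotation$promoters
  with_seed(seed, {
    w <- .rand_widths(cfg, n)
    in_prom <- stats::runif(n) < cfg$promoter_planting_fraction &
      length(prom) > 0L
    chrom <- character(n); mid <- numeric(n)
    chroms <- names(sizes)
    p_chr <- as.numeric(sizes) / genome_length(sizes)
    k <- sum(in_prom)
    if (k > 0L) {
      j <- sample.int(length(prom), k, replace = TRUE)
      chrom[in_prom] <- as.character(seqnames(prom))[j]
      mid[in_prom] <- start0(prom)[j] +
        floor(stats::runif(k) * width(prom)[j])
    }
    todo <- which(!in_prom)
    while (length(todo)) {     # uniform placement, midpoint outside promoters
      ch <- sample(chroms, length(todo), replace = TRUE, prob = p_chr)
      m <- floor(stats::runif(length(todo)) *
                   as.numeric(sizes)[match(ch, chroms)])
      probe <- GenomicRanges::GRanges(ch, IRanges::IRanges(m + 1, m + 1))
      clear <- if (length(prom))
        !IRanges::overlapsAny(probe, prom, ignore.strand = TRUE)
      else rep(TRUE, length(todo))
      chrom[todo[clear]] <- ch[clear]
      mid[todo[clear]] <- m[clear]
      todo <- todo[!clear]
    }
    s0 <- pmax(0, mid - floor(w / 2))
    lim <- as.numeric(sizes)[match(chrom, chroms)]
    s0 <- pmin(s0, lim - w)
    list(gr = granges0(chrom, s0, s0 + w,
                       name = sprintf("true%04d", seq_len(n)), sizes = sizes),
         promoter_planted = stats::setNames(in_prom,
                                            sprintf("true%04d", seq_len(n))))
  })
}

.jitter_peaks <- function(gr, frac = 0.1) {
  if (length(gr) == 0L || frac == 0) return(gr)
  w <- width(gr)
  shift <- round(stats::runif(length(gr), -frac, frac) * w)
  grow <- round(stats::runif(length(gr), -frac, frac) * w)
  s0 <- pmax(start0(gr) + shift, 0)
  e0 <- pmax(end0(gr) + shift + grow, s0 + 1)
  sizes <- seqlengths(gr)
  lim <- sizes[as.character(seqnames(gr))]
  e0 <- pmin(e0, lim)
  s0 <- pmin(s0, e0 - 1)
  nm <- mcols(gr)$name
  granges0(as.character(seqnames(gr)), s0, e0, name = nm,
           sizes = chrom_sizes(sizes))
}

.uniform_peaks <- function(cfg, sizes, n, prefix, avoid = NULL,
                           max_rounds = 200L) {
  if (n == 0L) return(granges0(character(0), integer(0), integer(0), sizes = sizes))
  w <- .rand_widths(cfg, n)
  chroms <- names(sizes)
  ch <- character(n); s0 <- numeric(n)
  todo <- seq_len(n)
  for (round in seq_len(max_rounds)) {
    if (!length(todo)) break
    cand_ch <- sample(chroms, length(todo), replace = TRUE,
                      prob = as.numeric(sizes) / genome_length(sizes))
    cand_s0 <- floor(stats::runif(length(todo)) *
                       (as.numeric(sizes)[match(cand_ch, chroms)] - w[todo]))
    clear <- if (is.null(avoid) || length(avoid) == 0L) rep(TRUE, length(todo))
    else !IRanges::overlapsAny(
      GenomicRanges::GRanges(cand_ch, IRanges::IRanges(cand_s0 + 1,
                                                       cand_s0 + w[todo])),
      avoid, ignore.strand = TRUE)
    ch[todo[clear]] <- cand_ch[clear]
    s0[todo[clear]] <- cand_s0[clear]
    todo <- todo[!clear]
  }
  if (length(todo)) stop("could not place ", length(todo), " peak(s) avoiding ",
                         "the exclusion set")
  granges0(ch, s0, s0 + w, name = sprintf("%s%04d", prefix, seq_len(n)),
           sizes = sizes)
}

# true peaks padded by a bit more than the maximal jitter excursion, so
# intervals placed outside the padded set can never touch a jittered copy
.jitter_pad <- function(gr, frac) {
  if (length(gr) == 0L) return(gr)
  pad <- ceiling(2.5 * frac * width(gr))
  s0 <- pmax(start0(gr) - pad, 0)
  lim <- seqlengths(gr)[as.character(seqnames(gr))]
  e0 <- pmin(end0(gr) + pad, lim)
  granges0(as.character(seqnames(gr)), s0, e0,
           sizes = chrom_sizes(seqlengths(gr)))
}

#' Simulate replicate and control peak sets with planted truth
#'
#' True peaks are placed with `promoter_planting_fraction` of midpoints
#' inside promoters and the rest uniformly outside promoters. Each replicate
#' contains each true peak with probability `replicate_reproducibility`
#' (coordinates jittered by up to 10% of the width) plus replicate-specific
#' noise peaks; true peaks draw FDR ~ Uniform(0, threshold/2) so they pass
#' the configured threshold, noise peaks draw FDR ~ Uniform(0, 1). The
#' control set holds `control_peak_rate * peaks_per_replicate` intervals, a
#' `control_contamination` fraction of which coincide with true peaks.
#'
#' @param cfg A [synthetic_config()].
#' @param annotation A `genome_annotation` from [simulate_genome()].
#' @param factor,condition Labels stamped on the generated `PeakSet`s.
#' @param stage Seed offset; use distinct values for independent factors.
#' @return List with `replicates` (list of `PeakSet`), `controls` (list of
#'   one control `PeakSet`), `true_peaks` (`GRanges`), and `truth` (data
#'   frame: peak_id, promoter_planted, per-replicate presence).
#' @export
simulate_peak_replicates <- function(cfg, annotation, factor = "Gmnn",
                                     condition = "NE", stage = 2L) {
  stopifnot(inherits(cfg, "synthetic_config"))
  placed <- .place_true_peaks(cfg, annotation, cfg$peaks_per_replicate,
                              .child_seed(cfg, stage))
  out <- .replicate_wrap(cfg, annotation, placed$gr, factor, condition,
                         .child_seed(cfg, stage) + 1L)
  out$truth$promoter_planted <-
    unname(placed$promoter_planted[out$truth$peak_id])
  out
}

#' Simulate a co-bound second factor
#'
#' Copies `cobinding_fraction` of the first factor's true peaks (with
#' coordinate jitter) into the new factor's true set; the remainder are
#' placed independently. Replicates and controls are then generated exactly
#' as in [simulate_peak_replicates()].
#'
#' @param cfg A [synthetic_config()].
#' @param factor_a Result of [simulate_peak_replicates()] for the first
#'   factor (its `true_peaks` are used).
#' @param annotation A `genome_annotation`.
#' @param factor,condition Labels for the new factor.
#' @param stage Seed offset (default 3).
#' @return As [simulate_peak_replicates()], with a `cobound` column in
#'   `truth`.
#' @export
simulate_cobound_factor <- function(cfg, factor_a, annotation,
                                    factor = "Zic1", condition = "NE",
                                    stage = 3L) {
  stopifnot(inherits(cfg, "synthetic_config"))
  a_true <- factor_a$true_peaks
  sizes <- annotation$chrom_sizes
  n <- cfg$peaks_per_replicate
  with_seed(.child_seed(cfg, stage), {
    n_co <- round(cfg$cobinding_fraction * n)
    n_co <- min(n_co, length(a_true))
    co_idx <- if (n_co > 0L) sample.int(length(a_true), n_co) else integer(0)
    co <- .jitter_peaks(a_true[co_idx], cfg$peak_jitter_frac)
    placed <- .place_true_peaks(cfg, annotation, n - n_co,
                                .child_seed(cfg, stage) + 7L)
    own <- placed$gr
    true_gr <- c(granges_only(co), granges_only(own))
    nm <- sprintf("true%04d", seq_along(true_gr))
    mcols(true_gr)$name <- nm
    true_gr <- sort_intervals(true_gr)
    cobound_flag <- stats::setNames(c(rep(TRUE, length(co)),
                                      rep(FALSE, length(own))), nm)
    prom_flag <- stats::setNames(c(rep(NA, length(co)),
                                   unname(placed$promoter_planted)), nm)
    out <- .replicate_wrap(cfg, annotation, true_gr, factor, condition,
                           .child_seed(cfg, stage) + 13L)
    out$truth$cobound <- unname(cobound_flag[out$truth$peak_id])
    out$truth$promoter_planted <- unname(prom_flag[out$truth$peak_id])
    out
  })
}

# shared replicate/control machinery given an existing true peak set:
# per-replicate inclusion + jitter + FDR scores, replicate-specific noise,
# and a control set whose contaminated fraction sits on true peaks while the
# rest is placed clear of them (and of any jittered copy)
.replicate_wrap <- function(cfg, annotation, true_gr, factor, condition, seed) {
  sizes <- annotation$chrom_sizes
  with_seed(seed, {
    reps <- vector("list", cfg$n_replicates)
    present <- matrix(FALSE, length(true_gr), cfg$n_replicates,
                      dimnames = list(mcols(true_gr)$name, NULL))
    pad <- .jitter_pad(true_gr, cfg$peak_jitter_frac)
    for (r in seq_len(cfg$n_replicates)) {
      inc <- stats::runif(length(true_gr)) < cfg$replicate_reproducibility
      present[, r] <- inc
      tg <- .jitter_peaks(true_gr[inc], cfg$peak_jitter_frac)
      if (length(tg))
        mcols(tg)$fdr <- stats::runif(length(tg), 0, cfg$fdr_threshold / 2)
      ng <- .uniform_peaks(cfg, sizes, cfg$noise_peaks_per_replicate,
                           sprintf("noise_r%d_", r))
      if (length(ng)) mcols(ng)$fdr <- stats::runif(length(ng), 0, 1)
      reps[[r]] <- peak_set(sort_intervals(c(tg, ng)), factor = factor,
                            condition = condition, replicate = r)
    }
    n_ctl <- round(cfg$control_peak_rate * cfg$peaks_per_replicate)
    n_contam <- min(round(cfg$control_contamination * n_ctl), length(true_gr))
    contam <- if (n_contam > 0L)
      .jitter_peaks(true_gr[sample.int(length(true_gr), n_contam)],
                    cfg$peak_jitter_frac)
    else true_gr[integer(0)]
    ctl_rand <- .uniform_peaks(cfg, sizes, n_ctl - n_contam, "ctl",
                               avoid = pad)
    ctl <- sort_intervals(c(granges_only(contam), granges_only(ctl_rand)))
    if (length(ctl)) {
      mcols(ctl)$name <- sprintf("ctl%04d", seq_along(ctl))
      mcols(ctl)$fdr <- stats::runif(length(ctl), 0, 1)
    }
    controls <- list(peak_set(ctl, factor = factor, condition = "control",
                              replicate = 1L))
    truth <- data.frame(peak_id = mcols(true_gr)$name,
                        stringsAsFactors = FALSE)
    truth <- cbind(truth, stats::setNames(as.data.frame(present),
                                          sprintf("in_rep%d", seq_len(cfg$n_replicates))))
    list(replicates = reps, controls = controls, true_peaks = true_gr,
         truth = truth)
  })
}

#' Simulate an expression counts panel with a planted CNS-enriched subset
#'
#' Counts are negative binomial (mean/size parameterization) with per-sample
#' library-size factors; a `planted_cns_fraction` of genes has its mean
#' multiplied by `planted_fold` in embryonic-CNS samples. Gene lengths come
#' from the annotation (sum of exon lengths).
#'
#' @param cfg A [synthetic_config()].
#' @param annotation A `genome_annotation` with at least one gene.
#' @return List with `counts` (genes x samples matrix), `sample_groups`
#'   (character vector: ES, embryonic_CNS, adult), `library_sizes` (design
#'   sequencing depth per sample, for RPKM), `gene_lengths`, and `truth`
#'   (data frame: gene_id, cns_flag, planted_fold).
#' @export
simulate_expression <- function(cfg, annotation) {
  stopifnot(inherits(cfg, "synthetic_config"))
  genes <- annotation$genes
  if (nrow(genes) == 0L) stop("annotation has no genes")
  with_seed(.child_seed(cfg, 4L), {
    groups <- rep(c("ES", "embryonic_CNS", "adult"),
                  each = cfg$n_samples_per_group)
    samples <- sprintf("%s_%d", groups, sequence(rep(cfg$n_samples_per_group, 3)))
    base <- stats::rlnorm(nrow(genes), log(cfg$base_mean), 1)
    cns_flag <- stats::runif(nrow(genes)) < cfg$planted_cns_fraction
    libfac <- stats::runif(length(samples), 0.8, 1.2)
    mu <- outer(base, libfac)
    mu[cns_flag, groups == "embryonic_CNS"] <-
      mu[cns_flag, groups == "embryonic_CNS"] * cfg$planted_fold
    counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = cfg$nb_size),
                     nrow(mu), ncol(mu),
                     dimnames = list(genes$gene_id, samples))
    # the design depth per sample (baseline expectation, excluding the
    # planted enrichment) is the mapped-read total RPKM should divide by;
    # raw column sums would fold the planted signal back into the
    # normalization
    lib <- stats::setNames(sum(base) * libfac, samples)
    list(counts = counts, sample_groups = groups,
         library_sizes = lib,
         gene_lengths = stats::setNames(genes$length_bp, genes$gene_id),
         truth = data.frame(gene_id = genes$gene_id, cns_flag = cns_flag,
                            planted_fold = ifelse(cns_flag, cfg$planted_fold, 1),
                            stringsAsFactors = FALSE))
  })
}

#' Plant motif sites into a fraction of sequences
#'
#' Writes one site, sampled column-wise from the PWM probabilities, at a
#' uniformly random position into `motif_planting_rate` of the sequences;
#' the rest are untouched.
#'
#' @param cfg A [synthetic_config()].
#' @param sequences Named character vector or `DNAStringSet`.
#' @param pwm A `motif_pwm`.
#' @return List with `sequences` (`DNAStringSet`) and `truth` (data frame:
#'   sequence_id, planted, offset).
#' @export
plant_motif <- function(cfg, sequences, pwm) {
  stopifnot(inherits(cfg, "synthetic_config"))
  seqs <- .as_char_seqs(sequences)
  w <- pwm$length
  if (any(nchar(seqs) < w))
    stop("motif longer than sequence: ",
         names(seqs)[which(nchar(seqs) < w)[1]])
  with_seed(.child_seed(cfg, 5L), {
    plant <- stats::runif(length(seqs)) < cfg$motif_planting_rate
    offset <- rep(NA_integer_, length(seqs))
    for (i in which(plant)) {
      site <- paste(vapply(seq_len(w), function(j)
        sample(.BASES, 1L, prob = pwm$prob[, j]), ""), collapse = "")
      o <- sample.int(nchar(seqs[[i]]) - w + 1L, 1L) - 1L
      substr(seqs[[i]], o + 1L, o + w) <- site
      offset[i] <- o
    }
    out <- Biostrings::DNAStringSet(seqs)
    names(out) <- names(seqs)
    list(sequences = out,
         truth = data.frame(sequence_id = names(seqs), planted = plant,
                            offset = offset, stringsAsFactors = FALSE))
  })
}
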