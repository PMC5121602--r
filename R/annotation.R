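# Gene-model and annotation layer. A genome_annotation bundles gene models
# (one representative, 5'-most isoform per gene_id), CpG islands, enhancers,
# derived promoters, and the chromosome-size table.

.parse_blocks <- function(gene_start0, block_sizes, block_starts) {
  sizes <- as.integer(strsplit(block_sizes, ",", fixed = TRUE)[[1]])
  starts <- as.integer(strsplit(block_starts, ",", fixed = TRUE)[[1]])
  s0 <- gene_start0 + starts
  cbind(start0 = s0, end0 = s0 + sizes)
}

#' Assemble a genome annotation from interval sets
#'
#' Gene models come from BED12 records ([read_bed()] with dialect "bed12").
#' For gene ids with multiple isoform records, the 5'-most isoform (per
#' strand) provides the TSS, exon structure, and gene length. Introns are the
#' gene body minus exons; 5'/3' UTRs are the exonic sequence outside the
#' thick (CDS) region, partitioned by strand. Promoters are derived with
#' [define_promoters()].
#'
#' @param genes A `GRanges` of BED12 gene records (metadata columns `name`,
#'   `thick_start0`, `thick_end0`, `block_sizes`, `block_starts`).
#' @param cpg_islands,enhancers `GRanges` of feature intervals (may be empty).
#' @param sizes A `chrom_sizes` object governing all coordinates.
#' @return A `genome_annotation` object.
#' @export
build_annotation <- function(genes, cpg_islands = GenomicRanges::GRanges(),
                             enhancers = GenomicRanges::GRanges(), sizes) {
  stopifnot(inherits(sizes, "chrom_sizes"))
  if (length(genes) && is.null(mcols(genes)$name))
    stop("gene records need a 'name' metadata column (gene_id)")
  if (length(genes) == 0L) {
    gene_df <- data.frame(gene_id = character(0), chrom = character(0),
                          strand = character(0), start0 = integer(0),
                          end0 = integer(0), tss0 = integer(0),
                          length_bp = integer(0), stringsAsFactors = FALSE)
    feat <- function() granges0(character(0), integer(0), integer(0), sizes = sizes)
    ann <- list(genes = gene_df, exons = feat(), introns = feat(),
                utr5 = feat(), utr3 = feat(), promoters = feat(),
                cpg_islands = cpg_islands, enhancers = enhancers,
                chrom_sizes = sizes)
    class(ann) <- "genome_annotation"
    return(ann)
  }
  df <- data.frame(gene_id = mcols(genes)$name,
                   chrom = as.character(seqnames(genes)),
                   strand = as.character(strand(genes)),
                   start0 = start0(genes), end0 = end0(genes),
                   stringsAsFactors = FALSE)
  df$tss0 <- ifelse(df$strand == "-", df$end0 - 1L, df$start0)
  df$thick_start0 <- if (!is.null(mcols(genes)$thick_start0))
    mcols(genes)$thick_start0 else df$start0
  df$thick_end0 <- if (!is.null(mcols(genes)$thick_end0))
    mcols(genes)$thick_end0 else df$end0
  df$block_sizes <- if (!is.null(mcols(genes)$block_sizes))
    mcols(genes)$block_sizes else paste0(df$end0 - df$start0, ",")
  df$block_starts <- if (!is.null(mcols(genes)$block_starts))
    mcols(genes)$block_starts else "0,"

  # representative isoform per gene_id: the one whose TSS is 5'-most
  pick <- vapply(split(seq_len(nrow(df)), df$gene_id), function(idx) {
    sub <- df[idx, ]
    best <- if (sub$strand[1] == "-") which.max(sub$tss0) else which.min(sub$tss0)
    idx[best]
  }, 1L)
  df <- df[pick[order(names(pick))], , drop = FALSE]
  rownames(df) <- NULL

  ex_list <- in_list <- u5_list <- u3_list <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    ex <- .parse_blocks(df$start0[i], df$block_sizes[i], df$block_starts[i])
    ex_list[[i]] <- ex
    # introns: gaps between consecutive exons
    if (nrow(ex) > 1L) {
      in_list[[i]] <- cbind(start0 = ex[-nrow(ex), "end0"], end0 = ex[-1, "start0"])
      in_list[[i]] <- in_list[[i]][in_list[[i]][, 1] < in_list[[i]][, 2], , drop = FALSE]
    } else in_list[[i]] <- cbind(start0 = integer(0), end0 = integer(0))
    # UTRs: exonic sequence before thick_start0 / after thick_end0
    ts <- df$thick_start0[i]; te <- df$thick_end0[i]
    left <- ex; left[, "end0"] <- pmin(left[, "end0"], ts)
    left <- left[left[, "start0"] < left[, "end0"], , drop = FALSE]
    right <- ex; right[, "start0"] <- pmax(right[, "start0"], te)
    right <- right[right[, "start0"] < right[, "end0"], , drop = FALSE]
    if (df$strand[i] == "-") { u5_list[[i]] <- right; u3_list[[i]] <- left }
    else { u5_list[[i]] <- left; u3_list[[i]] <- right }
  }
  as_feature_gr <- function(lst) {
    n <- vapply(lst, nrow, 1L)
    if (sum(n) == 0L)
      return(granges0(character(0), integer(0), integer(0), sizes = sizes))
    m <- do.call(rbind, lst)
    granges0(rep(df$chrom, n), m[, "start0"], m[, "end0"],
             strand = rep(df$strand, n), name = rep(df$gene_id, n),
             sizes = sizes)
  }
  df$length_bp <- vapply(ex_list, function(m) sum(m[, "end0"] - m[, "start0"]), 1L)
  gene_df <- df[, c("gene_id", "chrom", "strand", "start0", "end0", "tss0", "length_bp")]
  ann <- list(genes = gene_df,
              exons = as_feature_gr(ex_list),
              introns = as_feature_gr(in_list),
              utr5 = as_feature_gr(u5_list),
              utr3 = as_feature_gr(u3_list),
              promoters = NULL,
              cpg_islands = cpg_islands, enhancers = enhancers,
              chrom_sizes = sizes)
  class(ann) <- "genome_annotation"
  ann$promoters <- define_promoters(ann)
  ann
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("genome_annotation:", nrow(x$genes), "genes,",
      length(x$cpg_islands), "CpG islands,",
      length(x$enhancers), "enhancers on",
      length(x$chrom_sizes), "chromosome(s)\n")
  invisible(x)
}

#' Derive promoter intervals
#'
#' A promoter spans 2 kb upstream through 0.5 kb downstream of the TSS
#' (2,500 bp total), strand-aware, in 0-based half-open coordinates:
#' plus strand `[TSS-2000, TSS+500)`, minus strand `[TSS-499, TSS+2001)`.
#' Intervals are clipped to chromosome bounds.
#'
#' @param annotation A `genome_annotation` (or its `genes` data frame plus
#'   `chrom_sizes` via the `sizes` argument).
#' @param upstream,downstream Distances in bp (defaults 2000 and 500).
#' @param sizes Optional `chrom_sizes` when passing a bare gene table.
#' @return A `GRanges` of promoters with a `name` column of gene ids.
#' @export
define_promoters <- function(annotation, upstream = 2000L, downstream = 500L,
                             sizes = NULL) {
  if (inherits(annotation, "genome_annotation")) {
    genes <- annotation$genes
    sizes <- annotation$chrom_sizes
  } else genes <- annotation
  if (nrow(genes) == 0L)
    return(granges0(character(0), integer(0), integer(0), sizes = sizes))
  minus <- genes$strand == "-"
  s0 <- ifelse(minus, genes$tss0 - (downstream - 1L), genes$tss0 - upstream)
  e0 <- ifelse(minus, genes$tss0 + upstream + 1L, genes$tss0 + downstream)
  s0 <- pmax(s0, 0L)
  lim <- as.integer(sizes)[match(genes$chrom, names(sizes))]
  e0 <- pmin(e0, lim)
  granges0(genes$chrom, s0, e0, strand = genes$strand, name = genes$gene_id,
           sizes = sizes)
}

#' Assign peaks to the nearest transcription start site
#'
#' For each peak the gene minimizing the absolute distance between the peak
#' midpoint and the gene TSS, over all genes on the same chromosome,
#' strand-ignored. Ties go to the smaller TSS coordinate, then the
#' lexicographically smaller gene id. Peaks on chromosomes without genes get
#' an `NA` gene and a warning.
#'
#' @param peaks A `GRanges` (or `PeakSet`) of peaks.
#' @param annotation A `genome_annotation`.
#' @return A data frame with columns `peak_name`, `chrom`, `midpoint0`,
#'   `gene_id`, `distance_bp`.
#' @export
nearest_tss <- function(peaks, annotation) {
  gr <- as_peak_granges(peaks)
  genes <- annotation$genes
  nm <- if (!is.null(mcols(gr)$name)) mcols(gr)$name else
    sprintf("peak%d", seq_along(gr))
  out <- data.frame(peak_name = nm, chrom = as.character(seqnames(gr)),
                    midpoint0 = midpoint0(gr), gene_id = NA_character_,
                    distance_bp = NA_real_, stringsAsFactors = FALSE)
  if (length(gr) == 0L) return(out)
  for (ch in unique(out$chrom)) {
    g <- genes[genes$chrom == ch, , drop = FALSE]
    idx <- which(out$chrom == ch)
    if (nrow(g) == 0L) next
    g <- g[order(g$tss0, g$gene_id), , drop = FALSE]
    tss <- g$tss0
    m <- out$midpoint0[idx]
    pos <- findInterval(m, tss)            # last tss <= m (0 if none)
    left <- pmax(pos, 1L)
    right <- pmin(pos + 1L, length(tss))
    dl <- abs(m - tss[left]); dr <- abs(m - tss[right])
    # prefer left on ties: smaller TSS coordinate wins
    use_left <- (pos >= 1L) & (dl <= dr | pos >= length(tss))
    choice <- ifelse(use_left, left, right)
    # same-tss duplicates: g is sorted by (tss0, gene_id); step back to the
    # first gene sharing the chosen TSS
    first_at <- match(tss[choice], tss)
    out$gene_id[idx] <- g$gene_id[first_at]
    out$distance_bp[idx] <- abs(m - tss[choice])
  }
  if (anyNA(out$gene_id))
    warning(sum(is.na(out$gene_id)), " peak(s) on chromosomes without genes; gene_id NA")
  out
}

#' Classify peaks by genomic location
#'
#' Single category per peak from the midpoint position, with priority
#' promoter > 5' UTR > 3' UTR > exon > intron > intergenic, so the category
#' histogram always sums to the number of peaks.
#'
#' @param peaks A `GRanges` or `PeakSet`.
#' @param annotation A `genome_annotation`.
#' @return Factor of categories, one per peak, levels in priority order.
#' @export
classify_genomic_location <- function(peaks, annotation) {
  gr <- as_peak_granges(peaks)
  lev <- c("promoter", "utr5", "utr3", "exon", "intron", "intergenic")
  if (length(gr) == 0L) return(factor(character(0), levels = lev))
  mid <- GenomicRanges::GRanges(seqnames(gr),
                                IRanges::IRanges(midpoint0(gr) + 1L, width = 1L))
  res <- rep("intergenic", length(gr))
  sets <- list(intron = annotation$introns, exon = annotation$exons,
               utr3 = annotation$utr3, utr5 = annotation$utr5,
               promoter = annotation$promoters)
  for (cat in names(sets)) {   # ascending priority: later assignments win
    if (length(sets[[cat]]))
      res[IRanges::overlapsAny(mid, sets[[cat]], ignore.strand = TRUE)] <- cat
  }
  factor(res, levels = lev)
}

# average feature lengths (bp) used for background window counts
.default_avg_lengths <- c(cpg_island = 601, promoter = 2500, enhancer = 271)

#' Genomic-feature fold enrichment of a peak set
#'
#' Computes `(n_feature / n_peak) / (N_feature / N_background)` where
#' `n_feature` is the number of peaks overlapping at least one feature
#' interval, `n_peak` the total number of peaks, `N_feature` the number of
#' annotation features, and `N_background` the number of genome windows,
#' `floor(genome_length / avg_feature_length)`. For feature names
#' "cpg_island", "promoter" and "enhancer" the default average lengths are
#' 601, 2500 and 271 bp; otherwise the empirical mean feature length is used.
#'
#' @param peaks A `GRanges` or `PeakSet`.
#' @param features A `GRanges` of annotation features.
#' @param sizes A `chrom_sizes` (genome length = sum of sizes).
#' @param feature_name Label for the feature class.
#' @param avg_feature_length Average feature length in bp; `NULL` picks the
#'   named default or the empirical mean.
#' @param min_overlap Minimum overlap in bp to count a peak (default 1).
#' @return A one-row data frame of class `feature_enrichment` with fields
#'   `feature_name`, `n_feature`, `n_peak`, `N_feature`, `N_background`,
#'   `avg_feature_length_bp`, `enrichment`.
#' @export
feature_enrichment <- function(peaks, features, sizes, feature_name = "feature",
                               avg_feature_length = NULL, min_overlap = 1L) {
  gr <- as_peak_granges(peaks)
  if (length(gr) == 0L) stop("feature enrichment is undefined for an empty peak set")
  if (is.null(avg_feature_length)) {
    avg_feature_length <- if (feature_name %in% names(.default_avg_lengths))
      .default_avg_lengths[[feature_name]] else mean(width(features))
  }
  if (!isTRUE(avg_feature_length > 0)) stop("avg_feature_length must be > 0")
  n_peak <- length(gr)
  n_feature <- length(intersect_peaks(gr, features, min_overlap = min_overlap))
  N_feature <- length(features)
  N_background <- floor(genome_length(sizes) / avg_feature_length)
  enr <- (n_feature / n_peak) / (N_feature / N_background)
  out <- data.frame(feature_name = feature_name, n_feature = n_feature,
                    n_peak = n_peak, N_feature = N_feature,
                    N_background = N_background,
                    avg_feature_length_bp = avg_feature_length,
                    enrichment = enr, stringsAsFactors = FALSE)
  class(out) <- c("feature_enrichment", "data.frame")
  out
}
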