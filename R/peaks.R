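# PeakSet: a GRanges of scored peaks plus assay metadata. The replicate slot
# is an integer for raw replicates and "consensus" after replicate filtering.

#' Construct a PeakSet
#'
#' @param gr A `GRanges` of peak intervals; a `fdr` metadata column carries
#'   per-peak FDR scores for thresholding.
#' @param factor ChIP'd factor or mark (e.g. "Gmnn", "Zic1", "H3K9ac").
#' @param condition Cell state / treatment (e.g. "ES", "NE", "NE+Dox",
#'   "control").
#' @param replicate Replicate number, or "consensus".
#' @param platform "chip_chip" or "chip_seq".
#' @return A `PeakSet` object.
#' @export
peak_set <- function(gr, factor = "factor", condition = "condition",
                     replicate = 1L, platform = c("chip_seq", "chip_chip")) {
  stopifnot(methods::is(gr, "GRanges"))
  platform <- match.arg(platform)
  structure(list(gr = gr, factor = factor, condition = condition,
                 replicate = replicate, platform = platform),
            class = "PeakSet")
}

#' @export
print.PeakSet <- function(x, ...) {
  cat(sprintf("PeakSet: %s [%s] replicate %s (%s): %d peaks\n",
              x$factor, x$condition, as.character(x$replicate), x$platform,
              length(x$gr)))
  invisible(x)
}

#' @export
length.PeakSet <- function(x) length(x$gr)

#' Extract the GRanges from a PeakSet (or pass a GRanges through)
#' @param x A `PeakSet` or `GRanges`.
#' @return The underlying `GRanges`.
#' @export
as_peak_granges <- function(x) {
  if (inherits(x, "PeakSet")) x$gr
  else if (methods::is(x, "GRanges")) x
  else stop("expected a PeakSet or GRanges, got ", class(x)[1])
}

.peakset_like <- function(template, gr, replicate = template$replicate) {
  peak_set(gr, factor = template$factor, condition = template$condition,
           replicate = replicate, platform = template$platform)
}

#' Consensus-calling parameters
#'
#' Defaults follow the factor-ChIP conventions: FDR < 0.05 (strict
#' inequality), a peak must be present in at least 2 of 3 replicates. For
#' H3K9ac use `fdr_max = 0.2`.
#'
#' @param fdr_max Maximum FDR (exclusive).
#' @param min_support Minimum number of distinct replicates supporting a
#'   region.
#' @param n_replicates Number of replicates in the design.
#' @return A `consensus_params` list.
#' @export
consensus_params <- function(fdr_max = 0.05, min_support = 2L, n_replicates = 3L) {
  stopifnot(fdr_max > 0, fdr_max <= 1,
            min_support >= 1L, min_support <= n_replicates)
  structure(list(fdr_max = fdr_max, min_support = as.integer(min_support),
                 n_replicates = as.integer(n_replicates)),
            class = "consensus_params")
}

#' Filter peaks by FDR
#'
#' Retains peaks with FDR strictly below `fdr_max` (a peak scored exactly at
#' the threshold is dropped).
#'
#' @param peaks A `PeakSet` (or `GRanges` with an `fdr` metadata column).
#' @param fdr_max Exclusive FDR ceiling.
#' @return Filtered object of the same type.
#' @export
threshold_fdr <- function(peaks, fdr_max = 0.05) {
  gr <- as_peak_granges(peaks)
  fdr <- mcols(gr)$fdr
  if (is.null(fdr) || anyNA(fdr))
    stop("every peak needs a non-missing 'fdr' score for thresholding")
  keep <- gr[fdr < fdr_max]
  if (inherits(peaks, "PeakSet")) .peakset_like(peaks, keep) else keep
}

#' Consensus peaks across replicates
#'
#' Each replicate is FDR-thresholded, all surviving peaks are pooled and
#' fused into candidate regions (merged union); a candidate is retained when
#' at least `min_support` distinct replicates contribute >= 1 overlapping
#' peak. Retained candidates are reported as the merged region with the
#' support count in the `support` metadata column and a `fdr` column of 0
#' (by construction every contributing peak already passed the threshold).
#'
#' @param replicates List of `PeakSet`s with identical factor and condition.
#' @param params A [consensus_params()] object.
#' @return A consensus `PeakSet` (replicate = "consensus").
#' @export
consensus_peaks <- function(replicates, params = consensus_params()) {
  stopifnot(length(replicates) >= 1L)
  facs <- unique(vapply(replicates, function(p) p$factor, ""))
  conds <- unique(vapply(replicates, function(p) p$condition, ""))
  if (length(facs) > 1L || length(conds) > 1L)
    stop("replicates mix factors/conditions: ",
         paste(facs, collapse = ","), " / ", paste(conds, collapse = ","))
  if (length(replicates) < params$min_support)
    stop("need at least min_support = ", params$min_support, " replicate sets")
  thr <- lapply(replicates, threshold_fdr, fdr_max = params$fdr_max)
  pooled <- do.call(c, lapply(thr, function(p) {
    g <- p$gr
    mcols(g) <- NULL
    g
  }))
  cand <- merge_peaks(pooled)
  if (length(cand)) {
    support <- Reduce(`+`, lapply(thr, function(p)
      as.integer(IRanges::overlapsAny(cand, p$gr, ignore.strand = TRUE))))
    keep <- cand[support >= params$min_support]
    mcols(keep)$name <- sprintf("%s_%s_consensus_%d", facs, conds, seq_along(keep))
    mcols(keep)$support <- support[support >= params$min_support]
    mcols(keep)$fdr <- rep(0, length(keep))
  } else keep <- cand
  peak_set(keep, factor = facs, condition = conds, replicate = "consensus",
           platform = replicates[[1]]$platform)
}

#' Subtract control peaks
#'
#' Removes every experimental peak that overlaps any peak of any control set
#' (input chromatin, untagged-line ChIP) by >= 1 bp. Intervals are removed
#' whole; the result does not depend on the order of the control sets.
#'
#' @param exp A consensus `PeakSet`.
#' @param controls List of control `PeakSet`s (or `GRanges`).
#' @return The control-subtracted `PeakSet`.
#' @export
subtract_control <- function(exp, controls) {
  gr <- as_peak_granges(exp)
  for (ctl in controls) gr <- subtract_peaks(gr, as_peak_granges(ctl))
  if (inherits(exp, "PeakSet")) .peakset_like(exp, gr) else gr
}

#' Knockdown-sensitive acetylation peaks
#'
#' H3K9ac consensus peaks in the untreated arm minus consensus peaks present
#' after doxycycline-induced knockdown: the surviving peaks mark promoter
#' acetylation that depends on the knocked-down factor. Both arms are
#' consensus-called with the same parameters (default FDR < 0.2, >= 2 of 3
#' replicates) and subtraction removes whole intervals.
#'
#' @param no_dox_reps,dox_reps Lists of replicate `PeakSet`s for the
#'   untreated and knockdown arms.
#' @param params [consensus_params()]; default uses `fdr_max = 0.2`.
#' @return A `PeakSet` of knockdown-sensitive peaks.
#' @export
gmnn_dependent_acetylation <- function(no_dox_reps, dox_reps,
                                       params = consensus_params(fdr_max = 0.2)) {
  ctrl <- consensus_peaks(no_dox_reps, params)
  dox <- consensus_peaks(dox_reps, params)
  .peakset_like(ctrl, subtract_peaks(ctrl$gr, dox$gr))
}

#' Combine peak sets from two platforms
#'
#' Merged union of (for example) ChIP-chip and ChIP-seq peak sets for the
#' same factor and condition. Provenance is retained in the `name` field of
#' each merged region as the platforms of the contributing peaks.
#'
#' @param a,b `PeakSet`s with the same factor and condition.
#' @return A combined `PeakSet` (platform of `a` is kept on the object; the
#'   per-peak `name` records contributing platforms).
#' @export
combine_platforms <- function(a, b) {
  if (a$factor != b$factor)
    stop("factor mismatch: ", a$factor, " vs ", b$factor)
  if (a$condition != b$condition)
    stop("condition mismatch: ", a$condition, " vs ", b$condition)
  pooled <- c(granges_only(a$gr), granges_only(b$gr))
  merged <- merge_peaks(pooled)
  if (length(merged)) {
    from_a <- IRanges::overlapsAny(merged, a$gr, ignore.strand = TRUE)
    from_b <- IRanges::overlapsAny(merged, b$gr, ignore.strand = TRUE)
    prov <- ifelse(from_a & from_b, paste(a$platform, b$platform, sep = "+"),
                   ifelse(from_a, a$platform, b$platform))
    mcols(merged)$name <- sprintf("%s_%s_%s_%d", a$factor, a$condition, prov,
                                  seq_along(merged))
    mcols(merged)$fdr <- rep(0, length(merged))
  }
  peak_set(merged, factor = a$factor, condition = a$condition,
           replicate = "consensus", platform = a$platform)
}

# strip metadata so GRanges concatenate cleanly
granges_only <- function(gr) { mcols(gr) <- NULL; gr }
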