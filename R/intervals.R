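#' @import methods
#' @import GenomicRanges
#' @import IRanges
#' @importFrom S4Vectors queryHits subjectHits mcols mcols<-
#' @importFrom GenomeInfoDb seqlevels seqlevels<- seqlengths seqlengths<- seqnames
NULL

# Coordinate convention: all external files are BED-style 0-based half-open
# [start, end); internally intervals live in GRanges (1-based closed).
# bed start0 == GRanges start - 1 ; bed end0 == GRanges end.

#' Read a chromosome-sizes table
#'
#' Two-column tab-separated file: chromosome name, length in bp.
#'
#' @param path Path to the TSV file.
#' @return A named integer vector of class `chrom_sizes` (names are
#'   chromosomes, values lengths in bp).
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "length"),
                          colClasses = c("character", "numeric"))
  chrom_sizes(stats::setNames(df$length, df$chrom))
}

#' Construct a chromosome-sizes object
#'
#' @param lengths Named numeric vector, chromosome name -> length (bp).
#' @return A `chrom_sizes` object.
#' @export
chrom_sizes <- function(lengths) {
  if (is.null(names(lengths)) || any(!nzchar(names(lengths))))
    stop("chromosome sizes must be a named vector")
  if (any(lengths <= 0)) stop("all chromosome lengths must be > 0")
  x <- as.integer(lengths)
  names(x) <- names(lengths)
  structure(x, class = "chrom_sizes")
}

#' Total genome length of a chromosome-sizes object
#' @param sizes A `chrom_sizes` object.
#' @return Sum of chromosome lengths in bp.
#' @export
genome_length <- function(sizes) sum(as.numeric(sizes))

#' @export
print.chrom_sizes <- function(x, ...) {
  cat("chrom_sizes:", length(x), "chromosomes,",
      format(genome_length(x), big.mark = ","), "bp total\n")
  print(stats::setNames(as.integer(x), names(x)))
  invisible(x)
}

#' Build a GRanges from 0-based half-open coordinates
#'
#' @param chrom Character vector of chromosome names.
#' @param start0 0-based inclusive start positions.
#' @param end0 Exclusive end positions.
#' @param strand Strand vector ("+", "-", or "." for unstranded).
#' @param name Optional interval names.
#' @param score Optional numeric scores (e.g. per-replicate FDR).
#' @param sizes Optional `chrom_sizes`; when supplied, coordinates are
#'   validated against chromosome bounds and seqlengths are set.
#' @return A sorted `GRanges`.
#' @export
granges0 <- function(chrom, start0, end0, strand = ".", name = NULL,
                     score = NULL, sizes = NULL) {
  if (length(chrom) == 0L) {
    gr <- GenomicRanges::GRanges()
  } else {
    n <- max(length(chrom), length(start0))
    chrom <- rep_len(as.character(chrom), n)
    bad <- which(!(start0 >= 0 & start0 < end0))
    if (length(bad))
      stop("invalid interval(s) at index ", paste(utils::head(bad, 5), collapse = ","),
           ": need 0 <= start < end")
    ord <- order(chrom, start0, end0)
    chrom <- chrom[ord]; start0 <- start0[ord]; end0 <- end0[ord]
    strand <- rep_len(strand, length(chrom))[ord]
    strand[strand == "."] <- "*"
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1, end0),
                                 strand = strand)
    if (!is.null(name)) mcols(gr)$name <- name[ord]
    if (!is.null(score)) mcols(gr)$score <- score[ord]
  }
  seqlevels(gr) <- sort(unique(c(seqlevels(gr), if (!is.null(sizes)) names(sizes))))
  if (!is.null(sizes)) {
    missing_chr <- setdiff(as.character(seqnames(gr)), names(sizes))
    if (length(missing_chr))
      stop("chromosome(s) not in the size table: ", paste(missing_chr, collapse = ","))
    if (length(gr)) {    # validate before stamping seqlengths
      over <- end(gr) > as.numeric(sizes)[match(as.character(seqnames(gr)),
                                                names(sizes))]
      if (any(over)) stop("interval(s) exceed chromosome length: index ",
                          paste(utils::head(which(over), 5), collapse = ","))
    }
    seqlengths(gr) <- stats::setNames(as.integer(sizes)[match(seqlevels(gr), names(sizes))],
                                      seqlevels(gr))
  }
  gr
}

#' Sort intervals into canonical order
#'
#' Lexicographic chromosome name, then start, then end; ties keep input order.
#'
#' @param gr A `GRanges`.
#' @return The sorted `GRanges`.
#' @export
sort_intervals <- function(gr) {
  gr[order(as.character(seqnames(gr)), start(gr), end(gr))]
}

#' 0-based start/end accessors
#' @param gr A `GRanges`.
#' @return Integer vector of 0-based inclusive starts (`start0`) or exclusive
#'   ends (`end0`).
#' @export
start0 <- function(gr) start(gr) - 1L

#' @rdname start0
#' @export
end0 <- function(gr) end(gr)

#' Interval midpoints
#'
#' The anchor position used for nearest-TSS distances and genomic-location
#' classification: `floor((start + end) / 2)` in 0-based half-open
#' coordinates.
#'
#' @param gr A `GRanges`.
#' @return Integer vector of 0-based midpoint positions.
#' @export
midpoint0 <- function(gr) as.integer(floor((start0(gr) + end0(gr)) / 2))

.bed_ncols <- c(bed3 = 3L, bed6 = 6L, "bed6+1" = 7L, bed12 = 12L)

#' Read a BED file
#'
#' Supports BED3, BED6, BED6+1 (a seventh numeric column carrying a
#' per-interval FDR, stored in metadata column `fdr`), and BED12 (block
#' structure retained for gene-model construction: metadata columns
#' `thick_start0`, `thick_end0`, `block_sizes`, `block_starts`).
#'
#' @param path File path (tab-separated, no header).
#' @param dialect One of "bed3", "bed6", "bed6+1", "bed12".
#' @param sizes Optional `chrom_sizes` for bounds validation.
#' @return A sorted `GRanges`; empty file yields an empty `GRanges`.
#' @export
read_bed <- function(path, dialect = c("bed6+1", "bed3", "bed6", "bed12"),
                     sizes = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  need <- .bed_ncols[[dialect]]
  if (length(lines) == 0L)
    return(granges0(character(0), integer(0), integer(0), sizes = sizes))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < need))
    stop("malformed BED line ", which(nf < need)[1], " in ", path,
         ": expected >= ", need, " fields, got ", nf[nf < need][1])
  col <- function(i) vapply(fields, `[[`, "", i)
  chrom <- col(1)
  s0 <- suppressWarnings(as.numeric(col(2)))
  e0 <- suppressWarnings(as.numeric(col(3)))
  if (anyNA(s0) || anyNA(e0))
    stop("non-numeric coordinate at line ", which(is.na(s0) | is.na(e0))[1], " in ", path)
  bad <- which(!(s0 >= 0 & s0 < e0))
  if (length(bad))
    stop("invalid interval at line ", bad[1], " in ", path,
         ": start >= end or negative start")
  name <- if (need >= 6L) col(4) else sprintf("iv%d", seq_along(chrom))
  score <- if (need >= 6L) suppressWarnings(as.numeric(col(5))) else NULL
  strand <- if (need >= 6L) col(6) else rep(".", length(chrom))
  gr <- granges0(chrom, s0, e0, strand = strand, name = name, score = score,
                 sizes = sizes)
  if (dialect == "bed6+1") {
    fdr <- suppressWarnings(as.numeric(col(7)))
    if (anyNA(fdr)) stop("non-numeric FDR at line ", which(is.na(fdr))[1], " in ", path)
    ord <- .bed_sort_order(chrom, s0, e0)
    mcols(gr)$fdr <- fdr[ord]
  } else if (dialect == "bed12") {
    ord <- .bed_sort_order(chrom, s0, e0)
    mcols(gr)$thick_start0 <- as.numeric(col(7))[ord]
    mcols(gr)$thick_end0 <- as.numeric(col(8))[ord]
    mcols(gr)$block_sizes <- col(11)[ord]
    mcols(gr)$block_starts <- col(12)[ord]
  }
  gr
}

# order matching GenomicRanges::sort on lexicographic seqlevels
.bed_sort_order <- function(chrom, s0, e0) order(chrom, s0, e0)

#' Write a BED file
#'
#' Inverse of [read_bed()] for each dialect; columns absent from the
#' `GRanges` metadata are filled with BED conventions (name ".", score 0).
#'
#' @param gr A `GRanges` (metadata columns as produced by [read_bed()]).
#' @param path Output path.
#' @param dialect BED dialect to emit.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(gr, path, dialect = c("bed6+1", "bed3", "bed6", "bed12")) {
  dialect <- match.arg(dialect)
  m <- mcols(gr)
  nm <- if (!is.null(m$name)) m$name else rep(".", length(gr))
  sc <- if (!is.null(m$score)) m$score else rep(0, length(gr))
  st <- as.character(strand(gr))
  st[st == "*"] <- "."
  df <- data.frame(chrom = as.character(seqnames(gr)), start = start0(gr),
                   end = end0(gr), stringsAsFactors = FALSE)
  if (dialect != "bed3") {
    df$name <- nm; df$score <- sc; df$strand <- st
  }
  if (dialect == "bed6+1") {
    if (is.null(m$fdr)) stop("bed6+1 output requires an 'fdr' metadata column")
    df$fdr <- m$fdr
  } else if (dialect == "bed12") {
    df$thick_start <- if (!is.null(m$thick_start0)) m$thick_start0 else df$start
    df$thick_end <- if (!is.null(m$thick_end0)) m$thick_end0 else df$end
    df$rgb <- "0"
    df$block_sizes_str <- if (!is.null(m$block_sizes)) m$block_sizes else
      paste0(df$end - df$start, ",")
    df$block_count <- vapply(strsplit(df$block_sizes_str, ","), length, 1L)
    df$block_starts <- if (!is.null(m$block_starts)) m$block_starts else "0,"
    df <- df[, c("chrom", "start", "end", "name", "score", "strand",
                 "thick_start", "thick_end", "rgb", "block_count",
                 "block_sizes_str", "block_starts")]
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Intervals of one set overlapping another
#'
#' Returns the intervals of `a` that overlap at least one interval of `b` by
#' at least `min_overlap` bp. Output is a subset of `a` (coordinates are not
#' modified); the operation is idempotent.
#'
#' @param a,b `GRanges` inputs (strand is ignored).
#' @param min_overlap Minimum shared bases (default 1).
#' @return The overlapping subset of `a`.
#' @export
intersect_peaks <- function(a, b, min_overlap = 1L) {
  stopifnot(min_overlap >= 1L)
  if (length(a) == 0L || length(b) == 0L) return(a[integer(0)])
  hits <- GenomicRanges::findOverlaps(a, b, minoverlap = min_overlap,
                                      ignore.strand = TRUE)
  a[sort(unique(S4Vectors::queryHits(hits)))]
}

#' Whole-interval subtraction
#'
#' Removes every interval of `a` that shares at least one base with any
#' interval of `b`. Intervals are removed whole, never trimmed: the operation
#' subtracts peaks, not base pairs.
#'
#' @param a,b `GRanges` inputs (strand ignored).
#' @return The intervals of `a` untouched by `b`.
#' @export
subtract_peaks <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) return(a)
  a[!IRanges::overlapsAny(a, b, ignore.strand = TRUE)]
}

#' Merge overlapping or bookended intervals
#'
#' Fuses overlapping and directly adjacent (bookended) intervals into maximal
#' intervals; total covered bp is preserved.
#'
#' @param a A `GRanges`.
#' @return The merged `GRanges`.
#' @export
merge_peaks <- function(a) {
  GenomicRanges::reduce(a, ignore.strand = TRUE)
}

#' Total covered base pairs of an interval set
#' @param a A `GRanges`.
#' @return Number of distinct genomic bases covered.
#' @export
covered_bp <- function(a) sum(width(merge_peaks(a)))
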