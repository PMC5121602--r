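# Shared fixtures and brute-force oracles, all built in code.

SIZES1 <- chrom_sizes(c(chr1 = 50000L))

# random interval set on a single chromosome
rand_ivs <- function(n, L = 10000L, max_w = 120L, sizes = NULL) {
  s0 <- sample.int(L - max_w, n, replace = TRUE) - 1L
  w <- sample.int(max_w, n, replace = TRUE)
  granges0(rep("chr1", n), s0, s0 + w, name = sprintf("p%d", seq_len(n)),
           sizes = sizes)
}

# per-base coverage oracle (single chromosome, 0-based positions 0..L-1)
cover_vec <- function(gr, L) {
  v <- logical(L)
  for (i in seq_along(gr)) v[(start0(gr)[i] + 1L):end0(gr)[i]] <- TRUE
  v
}

# brute-force oracles over per-interval overlap
oracle_intersect <- function(a, b, min_overlap = 1L) {
  keep <- vapply(seq_along(a), function(i) {
    ov <- pmin(end0(a)[i], end0(b)) - pmax(start0(a)[i], start0(b))
    any(ov >= min_overlap)
  }, TRUE)
  a[keep]
}

oracle_subtract <- function(a, b) {
  keep <- vapply(seq_along(a), function(i) {
    ov <- pmin(end0(a)[i], end0(b)) - pmax(start0(a)[i], start0(b))
    !any(ov >= 1L)
  }, TRUE)
  a[keep]
}

# a small deterministic annotation: genes on two chromosomes with known
# structure, plus CpG islands and enhancers
tiny_annotation <- function() {
  sizes <- chrom_sizes(c(chr1 = 100000L, chr2 = 100000L))
  genes <- granges0(
    chrom = c("chr1", "chr1", "chr2"),
    start0 = c(10000, 40000, 20000),
    end0 = c(16000, 46000, 26000),
    strand = c("+", "-", "+"),
    name = c("geneA", "geneB", "geneC"),
    score = c(0, 0, 0),
    sizes = sizes)
  # two exons each: [0,1000) and [5000,6000) relative to gene start
  mcols(genes)$thick_start0 <- start0(genes) + 500
  mcols(genes)$thick_end0 <- start0(genes) + 5500
  mcols(genes)$block_sizes <- rep("1000,1000,", 3)
  mcols(genes)$block_starts <- rep("0,5000,", 3)
  cpg <- granges0(c("chr1", "chr2"), c(9500, 19500), c(10100, 20100),
                  name = c("cpg1", "cpg2"), sizes = sizes)
  enh <- granges0("chr1", 70000, 70271, name = "enh1", sizes = sizes)
  build_annotation(genes, cpg_islands = cpg, enhancers = enh, sizes = sizes)
}

# scored PeakSet from bare coordinate vectors
mk_peaks <- function(s0, e0, fdr = rep(0.01, length(s0)), chrom = "chr1",
                     factor = "Gmnn", condition = "NE", replicate = 1L,
                     sizes = NULL) {
  gr <- granges0(rep(chrom, length(s0)), s0, e0,
                 name = sprintf("pk%d", seq_along(s0)), sizes = sizes)
  mcols(gr)$fdr <- fdr
  peak_set(gr, factor = factor, condition = condition, replicate = replicate)
}

# deterministic PWM recognising exactly `motif` (probability-1 columns)
exact_pwm <- function(motif, name = motif) {
  bases <- strsplit(motif, "")[[1]]
  mat <- vapply(bases, function(b) as.numeric(c("A", "C", "G", "T") == b),
                numeric(4))
  motif_pwm(mat, name = name, pseudocount = 0)
}

random_seqs <- function(n, len, prefix = "s") {
  s <- vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""), "")
  names(s) <- sprintf("%s%d", prefix, seq_len(n))
  s
}
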