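# PWM motif scanning and hypergeometric enrichment. Scores are log2 odds
# against a base-frequency background; a sequence "has" a motif when any
# offset on either strand reaches score_fraction of the maximum attainable
# score (sequence-level occurrence counting).

.BASES <- c("A", "C", "G", "T")

#' Construct a position weight matrix
#'
#' @param mat 4 x L numeric matrix of per-position base counts or
#'   probabilities, rows A, C, G, T.
#' @param name Motif name.
#' @param pseudocount Added to every cell (after scaling probabilities to a
#'   unit column) before renormalization; default 0.01.
#' @param background Background base frequencies (A, C, G, T); default
#'   uniform.
#' @return A `motif_pwm` object: probability matrix (columns sum to 1),
#'   name, background, and the log2-odds matrix.
#' @export
motif_pwm <- function(mat, name = "motif", pseudocount = 0.01,
                      background = rep(0.25, 4)) {
  mat <- as.matrix(mat)
  if (nrow(mat) != 4L) stop("PWM needs 4 rows (A, C, G, T)")
  if (ncol(mat) < 1L) stop("PWM needs at least one column")
  if (any(mat < 0)) stop("PWM entries must be non-negative")
  cs <- colSums(mat)
  if (any(cs == 0)) stop("PWM column with zero total")
  prob <- sweep(mat, 2, cs, "/") + pseudocount
  prob <- sweep(prob, 2, colSums(prob), "/")
  rownames(prob) <- .BASES
  logodds <- log2(prob / background)
  structure(list(name = name, prob = prob, background = background,
                 logodds = logodds, length = ncol(prob)),
            class = "motif_pwm")
}

#' @export
print.motif_pwm <- function(x, ...) {
  cat(sprintf("motif_pwm '%s': length %d, max score %.2f bits\n",
              x$name, x$length, pwm_max_score(x)))
  invisible(x)
}

#' Maximum attainable log-odds score of a PWM
#' @param pwm A `motif_pwm`.
#' @return Score in bits of the optimal sequence.
#' @export
pwm_max_score <- function(pwm) sum(apply(pwm$logodds, 2, max))

#' Read motifs from a JASPAR text file
#'
#' Accepts the JASPAR matrix format: a `>ID name` header followed by four
#' rows `A [ n1 n2 ... ]` (brackets optional).
#'
#' @param path File path.
#' @param pseudocount,background Passed to [motif_pwm()].
#' @return Named list of `motif_pwm` objects.
#' @export
read_jaspar <- function(path, pseudocount = 0.01, background = rep(0.25, 4)) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  heads <- grep("^>", lines)
  if (length(heads) == 0L) stop("no JASPAR records ('>' headers) in ", path)
  out <- list()
  for (i in seq_along(heads)) {
    from <- heads[i] + 1L
    to <- if (i < length(heads)) heads[i + 1L] - 1L else length(lines)
    block <- lines[from:to]
    if (length(block) < 4L) stop("JASPAR record with fewer than 4 matrix rows")
    hdr <- sub("^>\\s*", "", lines[heads[i]])
    name <- paste(strsplit(hdr, "\\s+")[[1]], collapse = "_")
    rows <- lapply(block[1:4], function(l) {
      l <- gsub("\\[|\\]", " ", l)
      parts <- strsplit(trimws(l), "\\s+")[[1]]
      if (toupper(parts[1]) %in% .BASES) parts <- parts[-1]
      as.numeric(parts)
    })
    base_order <- toupper(substr(block[1:4], 1, 1))
    mat <- do.call(rbind, rows)
    if (all(sort(base_order) == .BASES)) mat <- mat[match(.BASES, base_order), ]
    out[[name]] <- motif_pwm(mat, name = name, pseudocount = pseudocount,
                             background = background)
  }
  out
}

#' Write motifs to a JASPAR text file
#' @param pwms List of `motif_pwm` objects (probability matrices written).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_jaspar <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(paste0(">", p$name), con)
    for (b in .BASES)
      writeLines(sprintf("%s [ %s ]", b,
                         paste(format(p$prob[b, ], digits = 6), collapse = " ")),
                 con)
  }
  invisible(path)
}

.seq_to_index <- function(s) {
  idx <- match(strsplit(toupper(s), "")[[1]], .BASES)
  idx[is.na(idx)] <- 0L   # N and other ambiguity codes: log-odds contribution 0
  idx
}

.revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

.scan_one_strand <- function(idx, lo) {
  w <- ncol(lo)
  n <- length(idx)
  if (n < w) return(numeric(0))
  lo0 <- rbind(rep(0, w), lo)   # row 1 scores unknown bases as 0
  n_off <- n - w + 1L
  s <- numeric(n_off)
  for (j in seq_len(w))         # one vectorized sweep per motif column
    s <- s + lo0[idx[j:(j + n_off - 1L)] + 1L, j]
  s
}

#' Scan sequences with a PWM
#'
#' Both strands are scanned at every offset; the log-odds score at an offset
#' is the sum of per-position `log2(p / background)` terms (unknown bases
#' contribute 0). A hit is any offset whose score reaches
#' `score_fraction * pwm_max_score(pwm)`. Reverse-strand hits are reported
#' at their forward-strand offset.
#'
#' @param sequences Named character vector or `DNAStringSet`.
#' @param pwm A `motif_pwm`.
#' @param score_fraction Fraction of the maximum attainable score required
#'   for a hit (default 0.8).
#' @return Data frame with `sequence_id`, `offset` (0-based), `strand`,
#'   `score` (bits).
#' @export
scan_pwm <- function(sequences, pwm, score_fraction = 0.8) {
  stopifnot(score_fraction > 0, score_fraction <= 1)
  seqs <- .as_char_seqs(sequences)
  w <- pwm$length
  thr <- score_fraction * pwm_max_score(pwm)
  if (all(nchar(seqs) < w)) {
    warning("motif longer than every sequence; no hits possible")
    return(data.frame(sequence_id = character(0), offset = integer(0),
                      strand = character(0), score = numeric(0)))
  }
  res <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    n <- nchar(s)
    fw <- .scan_one_strand(.seq_to_index(s), pwm$logodds)
    rv <- if (n >= w) .scan_one_strand(.seq_to_index(.revcomp(s)), pwm$logodds)
          else numeric(0)
    hit_f <- which(fw >= thr) - 1L
    hit_r <- which(rv >= thr) - 1L
    res[[i]] <- data.frame(
      sequence_id = rep(names(seqs)[i], length(hit_f) + length(hit_r)),
      offset = c(hit_f, n - hit_r - w),
      strand = c(rep("+", length(hit_f)), rep("-", length(hit_r))),
      score = c(fw[hit_f + 1L], rv[hit_r + 1L]),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

.as_char_seqs <- function(sequences) {
  nm <- names(sequences)
  s <- as.character(sequences)   # base as.character drops names
  names(s) <- nm
  if (is.null(names(s)) || any(!nzchar(names(s))))
    names(s) <- sprintf("seq%d", seq_along(s))
  toupper(s)
}

#' Hypergeometric motif enrichment in targets vs background
#'
#' A sequence "has" the motif when [scan_pwm()] reports >= 1 hit. With the
#' pooled population of N target + background sequences, K of which have the
#' motif, drawing the n targets and observing k motif-positive targets, the
#' enrichment P-value is the hypergeometric upper tail `P(X >= k)`.
#'
#' @param targets,backgrounds Named sequence sets (ids must not overlap).
#' @param pwm A `motif_pwm`.
#' @param score_fraction Passed to [scan_pwm()].
#' @return One-row data frame: `motif`, `n_target_with`, `n_target`,
#'   `n_background_with`, `n_background`, `p_value`, `q_value` (NA until
#'   [rank_motifs()] adjusts across a library).
#' @export
motif_enrichment_test <- function(targets, backgrounds, pwm,
                                  score_fraction = 0.8) {
  tg <- .as_char_seqs(targets)
  bg <- .as_char_seqs(backgrounds)
  if (length(tg) == 0L || length(bg) == 0L)
    stop("both target and background sets must be non-empty")
  if (length(intersect(names(tg), names(bg))))
    stop("target and background sequence ids overlap")
  has_hit <- function(seqs) {
    hits <- suppressWarnings(scan_pwm(seqs, pwm, score_fraction))
    names(seqs) %in% hits$sequence_id
  }
  k <- sum(has_hit(tg))
  kb <- sum(has_hit(bg))
  n <- length(tg); N <- n + length(bg); K <- k + kb
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  data.frame(motif = pwm$name, n_target_with = k, n_target = n,
             n_background_with = kb, n_background = length(bg),
             p_value = p, q_value = NA_real_, stringsAsFactors = FALSE)
}

#' Rank a motif library by enrichment
#'
#' Runs [motif_enrichment_test()] for every PWM, adjusts P-values across the
#' library by Benjamini-Hochberg, and sorts ascending by P.
#'
#' @param targets,backgrounds Named sequence sets.
#' @param pwm_library List of `motif_pwm` objects.
#' @param score_fraction Passed to [scan_pwm()].
#' @return Data frame of per-motif results sorted by `p_value`.
#' @export
rank_motifs <- function(targets, backgrounds, pwm_library,
                        score_fraction = 0.8) {
  stopifnot(length(pwm_library) >= 1L)
  rows <- lapply(pwm_library, function(p)
    motif_enrichment_test(targets, backgrounds, p, score_fraction))
  out <- do.call(rbind, rows)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, out$motif), ]
  rownames(out) <- NULL
  out
}

#' Extract peak sequences from a genome
#'
#' @param peaks A `GRanges` or `PeakSet`; interval names become sequence ids.
#' @param genome A named `DNAStringSet` (one entry per chromosome) or a
#'   FASTA file path.
#' @return An upper-cased `DNAStringSet`, one sequence per peak.
#' @export
extract_peak_sequences <- function(peaks, genome) {
  gr <- as_peak_granges(peaks)
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  chroms <- as.character(seqnames(gr))
  missing_chr <- setdiff(chroms, names(genome))
  if (length(missing_chr))
    stop("chromosome(s) absent from genome: ", paste(missing_chr, collapse = ","))
  lens <- Biostrings::width(genome)[match(chroms, names(genome))]
  bad <- which(end(gr) > lens)
  if (length(bad)) {
    nm <- mcols(gr)$name
    stop("peak out of genome bounds: ",
         if (!is.null(nm)) nm[bad[1]] else paste0("index ", bad[1]))
  }
  seqs <- Biostrings::DNAStringSet(vapply(seq_along(gr), function(i)
    toupper(as.character(Biostrings::subseq(genome[[chroms[i]]],
                                            start(gr)[i], end(gr)[i]))), ""))
  names(seqs) <- if (!is.null(mcols(gr)$name)) mcols(gr)$name else
    sprintf("peak%d", seq_along(gr))
  seqs
}

#' Sample length-matched background regions
#'
#' Draws `n_per_peak` regions per peak, each with that peak's length, at
#' uniformly random positions (chromosomes weighted by length), rejecting
#' positions that overlap any peak. Deterministic for a given seed.
#'
#' @param peaks A `GRanges` or `PeakSet`.
#' @param sizes A `chrom_sizes`.
#' @param seed Integer seed.
#' @param n_per_peak Regions per peak (default 2).
#' @param max_tries Rejection-sampling retries per region before erroring.
#' @return A `GRanges` of background regions (names `bg_<i>`).
#' @export
sample_background_regions <- function(peaks, sizes, seed, n_per_peak = 2L,
                                      max_tries = 1000L) {
  gr <- as_peak_granges(peaks)
  widths <- rep(width(gr), n_per_peak)
  n <- length(widths)
  with_seed(seed, {
    chrom <- character(n); s0 <- numeric(n)
    p_chr <- as.numeric(sizes) / genome_length(sizes)
    todo <- seq_len(n)
    for (round in seq_len(max_tries)) {
      if (!length(todo)) break
      ch <- sample(names(sizes), length(todo), replace = TRUE, prob = p_chr)
      room <- as.numeric(sizes)[match(ch, names(sizes))] - widths[todo]
      cand_s0 <- floor(stats::runif(length(todo)) * (room + 1))
      ok <- room >= 0
      cand <- GenomicRanges::GRanges(ch[ok],
                                     IRanges::IRanges(cand_s0[ok] + 1,
                                                      cand_s0[ok] + widths[todo][ok]))
      clear <- !IRanges::overlapsAny(cand, gr, ignore.strand = TRUE)
      hit <- todo[ok][clear]
      chrom[hit] <- ch[ok][clear]
      s0[hit] <- cand_s0[ok][clear]
      todo <- setdiff(todo, hit)
    }
    if (length(todo)) stop("could not place ", length(todo),
                           " background region(s) after ", max_tries, " rounds")
    granges0(chrom, s0, s0 + widths, name = sprintf("bg_%d", seq_len(n)),
             sizes = sizes)
  })
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global RNG state so seeded helpers do not disturb
#' the caller's random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}
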