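# Expression layer: counts -> RPKM -> per-gene z-scores across a tissue
# panel, tissue-enrichment classification, and hierarchical ordering.

#' Normalize counts to RPKM
#'
#' `rpkm[g,s] = counts[g,s] / (gene_length_kb[g] * library_size_millions[s])`.
#' Library sizes default to the column sums of the counts matrix.
#'
#' @param counts Non-negative genes x samples matrix (rownames = gene ids,
#'   colnames = sample ids).
#' @param gene_lengths Positive gene lengths in bp, named by gene id or in
#'   row order.
#' @param library_sizes Positive per-sample mapped-read totals; default
#'   `colSums(counts)`.
#' @param sample_groups Optional character vector of tissue-group labels per
#'   sample (e.g. "ES", "embryonic_CNS", "adult_CNS").
#' @return An `expr_matrix` object with elements `rpkm`, `gene_length_bp`,
#'   `library_size`, `sample_groups`, and (after [zscore_rows()]) `zscore`.
#' @export
rpkm_normalize <- function(counts, gene_lengths, library_sizes = colSums(counts),
                           sample_groups = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (!is.null(names(gene_lengths)) && !is.null(rownames(counts)))
    gene_lengths <- gene_lengths[rownames(counts)]
  if (length(gene_lengths) != nrow(counts))
    stop("gene_lengths must cover every gene")
  if (any(!is.finite(gene_lengths)) || any(gene_lengths <= 0))
    stop("gene lengths must be positive")
  if (any(library_sizes <= 0)) stop("library sizes must be positive")
  rpkm <- counts / (gene_lengths / 1000) /
    matrix(library_sizes / 1e6, nrow(counts), ncol(counts), byrow = TRUE)
  if (!is.null(sample_groups)) {
    if (length(sample_groups) != ncol(counts))
      stop("one group label per sample required")
  }
  structure(list(rpkm = rpkm, zscore = NULL,
                 gene_length_bp = gene_lengths, library_size = library_sizes,
                 sample_groups = sample_groups),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples (z-scores %s)\n",
              nrow(x$rpkm), ncol(x$rpkm),
              if (is.null(x$zscore)) "not computed" else "computed"))
  if (!is.null(x$sample_groups))
    print(table(x$sample_groups))
  invisible(x)
}

#' Per-gene z-scores across samples
#'
#' `z[g,s] = (rpkm[g,s] - mean_g) / sd_g` with the sample (n-1) standard
#' deviation across samples. Constant rows (sd = 0) are set to all zeros
#' with a warning rather than NaN.
#'
#' @param m An `expr_matrix` (or bare matrix).
#' @param log2_transform Optionally z-score `log2(rpkm + 1)` instead of raw
#'   RPKM (off by default).
#' @return The `expr_matrix` with the `zscore` element filled (or the
#'   z-score matrix when a bare matrix was given).
#' @export
zscore_rows <- function(m, log2_transform = FALSE) {
  x <- if (inherits(m, "expr_matrix")) m$rpkm else as.matrix(m)
  if (ncol(x) < 2L) stop("z-scores need at least 2 samples")
  if (log2_transform) x <- log2(x + 1)
  mu <- rowMeans(x)
  sdv <- apply(x, 1, stats::sd)
  z <- (x - mu) / sdv
  const <- sdv == 0
  if (any(const)) {
    warning(sum(const), " constant row(s) set to all-zero z-scores")
    z[const, ] <- 0
  }
  if (inherits(m, "expr_matrix")) { m$zscore <- z; m } else z
}

#' Classify genes by between-group fold change
#'
#' Fold change of mean RPKM between two tissue groups with a pseudocount:
#' `fold = (mean_A + eps) / (mean_B + eps)`. Genes at or above the threshold
#' are "enriched", at or below its reciprocal "depleted", otherwise
#' "unchanged" (the threshold is inclusive: "at least `fold_threshold`-fold").
#'
#' @param m An `expr_matrix` with `sample_groups`.
#' @param group_a,group_b Group labels (e.g. "embryonic_CNS" vs "ES").
#' @param fold_threshold Inclusive fold-change threshold (default 2).
#' @param eps Pseudocount in RPKM units (default 0.1).
#' @return Data frame with `gene_id`, `fold_change`, `label`.
#' @export
classify_enrichment <- function(m, group_a, group_b, fold_threshold = 2,
                                eps = 0.1) {
  stopifnot(inherits(m, "expr_matrix"), !is.null(m$sample_groups))
  for (g in c(group_a, group_b))
    if (!g %in% m$sample_groups) stop("unknown group label: ", g)
  ma <- rowMeans(m$rpkm[, m$sample_groups == group_a, drop = FALSE])
  mb <- rowMeans(m$rpkm[, m$sample_groups == group_b, drop = FALSE])
  fold <- (ma + eps) / (mb + eps)
  label <- ifelse(fold >= fold_threshold, "enriched",
                  ifelse(fold <= 1 / fold_threshold, "depleted", "unchanged"))
  data.frame(gene_id = rownames(m$rpkm), fold_change = fold, label = label,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Hierarchical ordering of genes by expression pattern
#'
#' Agglomerative clustering of per-gene z-score rows (Euclidean distance,
#' average linkage). Deterministic given the input order.
#'
#' @param m An `expr_matrix` with z-scores (computed on the fly if absent).
#' @param gene_subset Optional character vector of gene ids to cluster.
#' @return List with `order` (gene ids in leaf order) and `tree` (the
#'   `hclust` object).
#' @export
hierarchical_order <- function(m, gene_subset = NULL) {
  mm <- if (is.null(m$zscore)) zscore_rows(m) else m
  z <- mm$zscore
  if (!is.null(gene_subset)) z <- z[gene_subset, , drop = FALSE]
  if (nrow(z) < 2L) stop("need at least 2 genes to cluster")
  tree <- stats::hclust(stats::dist(z, method = "euclidean"), method = "average")
  list(order = rownames(z)[tree$order], tree = tree)
}
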