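# Gene regulatory network construction: directed regulator -> target edges
# from chromatin-association gene sets, filtered by default to targets that
# are themselves transcription factors with embryonic-CNS-enriched
# expression, with co-binding and acetylation-dependence evidence carried as
# attributes.

#' Construct a gene-set catalog
#'
#' Maps factor names to their associated gene sets (from [nearest_tss()]
#' runs, or imported published gene lists for external factors), with
#' provenance recorded per set.
#'
#' @param sets Named list of character vectors (factor -> gene ids).
#' @param provenance Character vector, one per set: "chip" for internally
#'   processed ChIP runs, "imported" for external gene lists. Recycled.
#' @return A `gene_set_catalog` object.
#' @export
gene_set_catalog <- function(sets, provenance = "chip") {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("every gene set must be named by its factor")
  provenance <- rep_len(provenance, length(sets))
  structure(list(sets = lapply(sets, unique),
                 provenance = stats::setNames(provenance, names(sets))),
            class = "gene_set_catalog")
}

#' @export
print.gene_set_catalog <- function(x, ...) {
  for (f in names(x$sets))
    cat(sprintf("%s: %d genes (%s)\n", f, length(x$sets[[f]]),
                x$provenance[[f]]))
  invisible(x)
}

#' Build a gene regulatory network
#'
#' One directed edge regulator -> target for every gene in each factor's
#' associated set that passes the target filters. The default filters mirror
#' an association-derived network of transcriptional regulators: a target
#' must itself encode a transcription factor (be in `tf_list`) and carry an
#' "enriched" expression label (embryonic-CNS-enriched). Candidates without
#' an expression label are skipped with a warning. Node attributes record TF
#' status, enrichment label, and acetylation dependence; duplicate
#' (regulator, target) pairs cannot arise, and evidence for co-binding is
#' merged onto edges via `cobound_genes`.
#'
#' @param catalog A [gene_set_catalog()].
#' @param tf_list Character vector of transcription-factor gene ids.
#' @param enrichment_labels Data frame from [classify_enrichment()]
#'   (`gene_id`, `label`), or `NULL` to skip the expression filter.
#' @param acetylation_genes Gene ids with knockdown-sensitive promoter
#'   acetylation (node annotation).
#' @param cobound_genes Gene ids bound by multiple factors at intersecting
#'   peaks (edge annotation `co_bound`).
#' @param require_tf,require_enriched Toggle the two default target filters.
#' @return A `grn` object with `nodes` and `edges` data frames.
#' @export
build_grn <- function(catalog, tf_list = character(0),
                      enrichment_labels = NULL,
                      acetylation_genes = character(0),
                      cobound_genes = character(0),
                      require_tf = TRUE, require_enriched = TRUE) {
  stopifnot(inherits(catalog, "gene_set_catalog"), length(catalog$sets) >= 1L)
  lab <- if (!is.null(enrichment_labels))
    stats::setNames(enrichment_labels$label, enrichment_labels$gene_id)
  edges <- list()
  skipped <- 0L
  for (f in names(catalog$sets)) {
    for (g in sort(catalog$sets[[f]])) {
      if (require_tf && !(g %in% tf_list)) next
      if (require_enriched) {
        if (is.null(lab) || is.na(lab[g])) { skipped <- skipped + 1L; next }
        if (lab[[g]] != "enriched") next
      }
      edges[[length(edges) + 1L]] <- data.frame(
        regulator = f, target = g, co_bound = g %in% cobound_genes,
        provenance = catalog$provenance[[f]], stringsAsFactors = FALSE)
    }
  }
  if (skipped) warning(skipped, " candidate target(s) skipped: no expression label")
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(regulator = character(0), target = character(0),
               co_bound = logical(0), provenance = character(0),
               stringsAsFactors = FALSE)
  edges <- edges[order(edges$regulator, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  node_ids <- sort(unique(c(names(catalog$sets), edges$target)))
  nodes <- data.frame(
    gene_id = node_ids,
    is_regulator = node_ids %in% names(catalog$sets),
    is_tf = node_ids %in% tf_list,
    cns_label = if (is.null(lab)) NA_character_ else
      unname(lab[node_ids]),
    gmnn_dependent_acetylation = node_ids %in% acetylation_genes,
    stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges), class = "grn")
}

#' @export
print.grn <- function(x, ...) {
  cat(sprintf("grn: %d nodes, %d edges (%d co-bound)\n",
              nrow(x$nodes), nrow(x$edges), sum(x$edges$co_bound)))
  invisible(x)
}

#' Genes bound by two factors at intersecting peaks
#'
#' Peak-level intersection (>= 1 bp) of the two factors' peak sets, followed
#' by nearest-TSS assignment of the intersecting peaks.
#'
#' @param peaks_a,peaks_b `PeakSet`s (or `GRanges`) for the two factors in
#'   the same condition.
#' @param annotation A `genome_annotation`.
#' @param min_overlap Minimum shared bases for a peak-level intersection.
#' @return List with `genes` (character vector) and `peaks` (the
#'   intersecting subset of `peaks_a`).
#' @export
cobound_targets <- function(peaks_a, peaks_b, annotation, min_overlap = 1L) {
  inter <- intersect_peaks(as_peak_granges(peaks_a), as_peak_granges(peaks_b),
                           min_overlap = min_overlap)
  if (length(inter) == 0L)
    return(list(genes = character(0), peaks = inter))
  assign <- nearest_tss(inter, annotation)
  list(genes = sort(unique(assign$gene_id[!is.na(assign$gene_id)])),
       peaks = inter)
}

#' Per-gene factor-combination summary
#'
#' For every gene in the union of the catalog's sets, the combination of
#' factors associating with it, plus counts per combination (consistent with
#' [venn_counts()] on the same sets).
#'
#' @param catalog A [gene_set_catalog()] with >= 2 factors.
#' @return List with `genes` (data frame gene_id, one logical column per
#'   factor, `combination`) and `counts` (table of combination sizes).
#' @export
shared_target_summary <- function(catalog) {
  stopifnot(inherits(catalog, "gene_set_catalog"))
  if (length(catalog$sets) < 2L) stop("need at least 2 factors")
  universe <- sort(unique(unlist(catalog$sets)))
  member <- vapply(catalog$sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1,
                                               dimnames = list(NULL, names(catalog$sets)))
  combination <- apply(member, 1, function(row)
    paste(names(catalog$sets)[row], collapse = "+"))
  genes <- data.frame(gene_id = universe, member, combination,
                      stringsAsFactors = FALSE, check.names = FALSE)
  rownames(genes) <- NULL
  list(genes = genes, counts = table(combination))
}

#' Convert a GRN to an igraph object
#' @param grn A `grn`.
#' @return An `igraph` directed graph with node/edge attributes.
#' @export
grn_to_igraph <- function(grn) {
  nodes <- grn$nodes
  nodes$cns_label[is.na(nodes$cns_label)] <- "unknown"
  igraph::graph_from_data_frame(grn$edges, directed = TRUE, vertices = nodes)
}

#' Export a GRN
#'
#' Formats: `edge_tsv` (header + one row per edge: regulator, target,
#' co_bound, provenance, target_cns_label, target_acetylation_flag; a
#' re-import with [import_grn_edges()] reproduces the edge set),
#' `graphml`, and `dot` (via igraph, with node and edge attributes).
#'
#' @param grn A `grn`.
#' @param path Output file path.
#' @param format One of "edge_tsv", "graphml", "dot".
#' @return Invisibly, `path`.
#' @export
export_grn <- function(grn, path, format = c("edge_tsv", "graphml", "dot")) {
  format <- match.arg(format)
  if (format == "edge_tsv") {
    e <- grn$edges
    idx <- match(e$target, grn$nodes$gene_id)
    e$target_cns_label <- grn$nodes$cns_label[idx]
    e$target_acetylation_flag <- grn$nodes$gmnn_dependent_acetylation[idx]
    utils::write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    g <- grn_to_igraph(grn)
    # igraph coerces logical attributes to numeric for DOT; that is fine
    suppressWarnings(
      igraph::write_graph(g, path, format = if (format == "dot") "dot" else "graphml"))
  }
  invisible(path)
}

#' Import a GRN from an edge TSV
#'
#' @param path File written by [export_grn()] with format "edge_tsv".
#' @return A `grn` object (node attributes reconstructed from edge columns).
#' @export
import_grn_edges <- function(path) {
  e <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  node_ids <- sort(unique(c(e$regulator, e$target)))
  lab <- stats::setNames(rep(NA_character_, length(node_ids)), node_ids)
  ac <- stats::setNames(rep(FALSE, length(node_ids)), node_ids)
  lab[e$target] <- e$target_cns_label
  ac[e$target] <- e$target_acetylation_flag
  nodes <- data.frame(gene_id = node_ids,
                      is_regulator = node_ids %in% e$regulator,
                      is_tf = node_ids %in% e$target |
                        node_ids %in% e$regulator,
                      cns_label = unname(lab),
                      gmnn_dependent_acetylation = unname(ac),
                      stringsAsFactors = FALSE)
  edges <- e[, c("regulator", "target", "co_bound", "provenance")]
  edges <- edges[order(edges$regulator, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "grn")
}
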