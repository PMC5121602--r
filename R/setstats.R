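# Overlap statistics for gene/peak sets: 2x2 contingency construction,
# chi-square with Yates' continuity correction, exact hypergeometric
# overlap, and 2-3 way Venn region counts.

#' Build a 2x2 contingency table from two sets and a universe
#'
#' Cells: `a` = in both, `b` = A only, `c` = B only, `d` = neither.
#' Both sets must be subsets of the universe; the universe is a required
#' argument because overlap P-values depend on it directly.
#'
#' @param set_a,set_b Character vectors of element ids.
#' @param universe Character vector containing every element of both sets.
#' @return A `contingency2x2` object (named list a, b, c, d, N).
#' @export
build_contingency <- function(set_a, set_b, universe) {
  set_a <- unique(set_a); set_b <- unique(set_b); universe <- unique(universe)
  out_a <- setdiff(set_a, universe); out_b <- setdiff(set_b, universe)
  if (length(out_a) || length(out_b))
    stop("element(s) outside the universe: ",
         paste(utils::head(c(out_a, out_b), 5), collapse = ","))
  a <- length(intersect(set_a, set_b))
  b <- length(setdiff(set_a, set_b))
  c <- length(setdiff(set_b, set_a))
  d <- length(universe) - a - b - c
  contingency2x2(a, b, c, d)
}

#' Construct a 2x2 contingency table from counts
#' @param a,b,c,d Non-negative counts: in-both, A-only, B-only, neither.
#' @return A `contingency2x2` object.
#' @export
contingency2x2 <- function(a, b, c, d) {
  counts <- as.numeric(c(a = a, b = b, c = c, d = d))  # doubles: the margin
  if (any(counts < 0)) stop("contingency counts must be non-negative")
  N <- sum(counts)                                     # products overflow int
  if (N <= 0) stop("empty contingency table")
  structure(list(a = counts[[1]], b = counts[[2]], c = counts[[3]],
                 d = counts[[4]], N = N),
            class = "contingency2x2")
}

#' @export
print.contingency2x2 <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(c("in A", "not A"), c("in B", "not B")))
  print(m)
  invisible(x)
}

#' Chi-square test with Yates' continuity correction
#'
#' Shortcut formula for a 2x2 table:
#' `chi2 = N * (max(|ad - bc| - N/2, 0))^2 / ((a+b)(c+d)(a+c)(b+d))`,
#' P-value from the upper tail of the chi-square distribution with 1 df.
#' The continuity term is floored at zero. Any zero margin leaves the
#' statistic undefined and raises an error.
#'
#' @param t A `contingency2x2`.
#' @return List with `statistic` and `p_value`.
#' @export
chisq_yates <- function(t) {
  stopifnot(inherits(t, "contingency2x2"))
  m1 <- t$a + t$b; m2 <- t$c + t$d; m3 <- t$a + t$c; m4 <- t$b + t$d
  if (min(m1, m2, m3, m4) == 0)
    stop("chi-square statistic undefined: zero margin")
  num <- max(abs(t$a * t$d - t$b * t$c) - t$N / 2, 0)
  stat <- t$N * num^2 / (m1 * m2 * m3 * m4)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Exact hypergeometric overlap P-value
#'
#' Upper-tail probability `P(X >= a)` of observing at least the seen overlap
#' when drawing `a + c` elements from a universe of `N` containing `a + b`
#' marked elements.
#'
#' @param t A `contingency2x2`.
#' @return The P-value.
#' @export
hypergeom_overlap <- function(t) {
  stopifnot(inherits(t, "contingency2x2"))
  stats::phyper(t$a - 1, t$a + t$b, t$c + t$d, t$a + t$c, lower.tail = FALSE)
}

#' Jaccard index of a 2x2 overlap
#' @param t A `contingency2x2`.
#' @return `a / (a + b + c)`, or `NA` when both sets are empty.
#' @export
jaccard_index <- function(t) {
  denom <- t$a + t$b + t$c
  if (denom == 0) NA_real_ else t$a / denom
}

#' Full overlap summary for two sets
#'
#' @param set_a,set_b,universe As in [build_contingency()].
#' @return List with the table, `chi2_yates`, `p_chi2`, `p_hypergeom`, and
#'   `jaccard`.
#' @export
overlap_test <- function(set_a, set_b, universe) {
  t <- build_contingency(set_a, set_b, universe)
  chi <- tryCatch(chisq_yates(t),
                  error = function(e) list(statistic = NA_real_,
                                           p_value = NA_real_))
  list(table = t, chi2_yates = chi$statistic, p_chi2 = chi$p_value,
       p_hypergeom = hypergeom_overlap(t), jaccard = jaccard_index(t))
}

#' Disjoint-region counts for 2 or 3 named sets
#'
#' @param named_sets Named list of 2 or 3 character vectors.
#' @return Named integer vector of disjoint region counts; for sets A, B
#'   (and C) the names are combinations like "A_only", "A_B", "A_B_C".
#'   Region counts sum to the size of the union.
#' @export
venn_counts <- function(named_sets) {
  k <- length(named_sets)
  if (k < 2L || k > 3L) stop("venn_counts supports 2 or 3 sets, got ", k)
  if (is.null(names(named_sets)) || any(!nzchar(names(named_sets))))
    stop("sets must be named")
  sets <- lapply(named_sets, unique)
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1)
  combo <- apply(member, 1, function(row) {
    inset <- names(sets)[row]
    if (length(inset) == 1L) paste0(inset, "_only") else
      paste(inset, collapse = "_")
  })
  all_regions <- unlist(lapply(seq_len(k), function(m)
    utils::combn(names(sets), m, function(x)
      if (length(x) == 1L) paste0(x, "_only") else paste(x, collapse = "_"),
      simplify = TRUE)))
  counts <- table(factor(combo, levels = all_regions))
  stats::setNames(as.integer(counts), names(counts))
}

#' Format a P-value with the conventional reporting floor
#'
#' Values below 2.2e-16 are reported as the string "< 2.2e-16".
#'
#' @param p Numeric P-value(s).
#' @return Character vector.
#' @export
format_pvalue <- function(p) {
  ifelse(p < 2.2e-16, "< 2.2e-16", format(p, digits = 4))
}
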