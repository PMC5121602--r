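---
title: "From scored ChIP peaks to a gene regulatory network: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From scored ChIP peaks to a gene regulatory network: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurogrn)
```

# The analysis

neurogrn reimplements, as a tested pipeline, the integration analysis used
to map chromatin association of neural transcription factors (Geminin,
Zic1) and knockdown-sensitive histone acetylation (H3K9ac) onto gene sets,
expression specificity, sequence motifs, and finally a directed gene
regulatory network. The pipeline consumes *scored peak intervals* — the
output of an upstream peak caller or tiling-array scorer, carried as BED6+1
with a per-peak FDR in column 7 — never raw reads. Every stage is a pure
function of its inputs, and a synthetic-data module with planted ground
truth exercises all of them without downloads.

## Coordinates and interval algebra

All file formats are BED-convention 0-based half-open; internally intervals
live in `GRanges` (1-based closed) with conversion confined to the readers
and writers. Three primitive operations carry the peak algebra:

- `intersect_peaks(a, b, min_overlap)` keeps the intervals of `a` that share
  at least `min_overlap` bp with *some single* interval of `b` (default
  1 bp; the threshold is configurable because no canonical value exists).
- `subtract_peaks(a, b)` removes every interval of `a` that touches `b` by
  one or more bases, whole — subtraction operates on peaks, not base pairs,
  because control subtraction and knockdown contrasts are statements about
  peak presence, not about coverage.
- `merge_peaks(a)` fuses overlapping and bookended intervals, preserving
  covered bases.

These are thin wrappers over `findOverlaps`/`overlapsAny`/`reduce`; the test
suite nevertheless checks each against an independent per-base brute-force
oracle on thousands of random instances, because the rest of the pipeline
rests on their exact semantics (half-open boundaries, whole-interval
subtraction, bookended fusion).

## Consensus peaks and subtraction

A replicate peak passes thresholding when its FDR is *strictly* below the
ceiling (0.05 for factor ChIP, 0.2 for the broader H3K9ac mark — acetylation
domains are wider and noisier, so the conventional ceiling is laxer).
Surviving peaks from all replicates are pooled and merged into candidate
regions; a candidate is retained when at least `min_support` (default 2 of
3) distinct replicates contribute an overlapping peak. Consensus regions
are reported as the *merged union* rather than one replicate's coordinates:
unions are reproducible, conservative, and independent of replicate
ordering. "Present in a replicate" means ≥ 1 bp overlap with the candidate.

Control subtraction removes every consensus region touching any control
interval (input chromatin, untagged-line ChIP), in any control order.
The knockdown contrast runs the same consensus machinery on both arms and
subtracts: acetylation peaks present without knockdown but absent after
knockdown are the knockdown-sensitive set. Platform combining
(tiling-array + sequencing peak sets for the same factor and condition) is
a merged union with per-region provenance retained in the name field.

For replicate reproducibility $r$ and three replicates, the expected
fraction of true peaks surviving 2-of-3 consensus is
$r^3 + 3r^2(1-r)$; the acceptance suite verifies the recovered fraction
against this closed form within a 99% binomial band at $n = 1000$ planted
peaks.

## Annotation and the feature-enrichment statistic

Promoters span 2 kb upstream through 0.5 kb downstream of the TSS
(2,500 bp), strand-aware; the TSS of a minus-strand gene is its 3′-most
coordinate minus one in 0-based space, and for genes with multiple isoform
records the 5′-most TSS is used. Peaks are anchored at their midpoint
(`floor((start+end)/2)`) for both nearest-TSS distance and location
classification — summit positions are unavailable in BED input, and the
midpoint is the only anchor that needs no extra data. Nearest-TSS ties are
broken deterministically: smaller TSS coordinate, then lexicographic gene
id. Location classes are assigned with priority promoter > 5′ UTR > 3′ UTR
> exon > intron > intergenic, so the class histogram always partitions the
peak set.

Feature enrichment is the windowed fold-over-background
$$E = \frac{n_\text{feature}/n_\text{peak}}{N_\text{feature}/N_\text{background}},
\qquad N_\text{background} = \left\lfloor \frac{G}{\bar\ell} \right\rfloor,$$
with $G$ the genome length (the sum of the supplied chromosome sizes, so
synthetic genomes work unchanged) and $\bar\ell$ the averaged feature
length — 601 bp for CpG islands, 2,500 bp for promoters, 271 bp for
enhancers when those names are used, otherwise the empirical mean. A peak
counts toward $n_\text{feature}$ when it overlaps a feature by ≥ 1 bp.
Because overlap is interval-against-interval, wide peaks inflate $E$
relative to a point-anchor null: a random 300 bp peak grazes a 601 bp
island more often than a random point does. The null-calibration test
therefore uses peaks much narrower than the features (20 bp against 601 bp
islands, $|E - 1| < 0.1$ at $n = 10{,}000$); for real peak widths the
statistic should be read as a descriptive fold, which is how its worked
example ($E = 25.0$) is also validated.

## Expression

RPKM is the plain formula
$\mathrm{rpkm} = c / (\ell_\text{kb} \cdot L_\text{M})$ with $\ell$ the
gene length (sum of exon lengths of the 5′-most isoform) and $L$ the
mapped-read total. Per-gene z-scores across the tissue panel use the sample
(n−1) standard deviation; constant rows become all-zero with a warning
rather than NaN. The z-score is computed on raw RPKM by default — a
`log2_transform` option exists because either convention is common, and the
choice is not recoverable from the style of figure the analysis emulates.

Tissue-enrichment classification compares group means with a pseudocount:
$f = (\bar x_A + \epsilon)/(\bar x_B + \epsilon)$, $\epsilon = 0.1$ RPKM,
label "enriched" when $f \ge 2$ (the threshold is inclusive — "at least
two-fold"), "depleted" below 1/2. The pseudocount guards division by zero
for silent genes; it is configurable and the boundary-semantics tests set
it to zero so the inclusive threshold is tested in isolation. Hierarchical
ordering is `hclust` on z-score rows, Euclidean distance, average linkage.

## Motif enrichment

PWMs are read from JASPAR text matrices, smoothed with pseudocount 0.01 and
column-normalized; scanning scores both strands at every offset with
log2-odds against a uniform background (ambiguous bases contribute 0). A
hit requires the score to reach a *fraction* of the maximum attainable
score (default 0.8) — an absolute bit threshold would not transfer across
motif lengths, and the upstream tools this emulates publish no threshold.
Enrichment is sequence-level (a sequence either has the motif or not):
with $N$ pooled target+background sequences, $K$ motif-positive, $n$
targets and $k$ motif-positive targets, $p = P(X \ge k)$ hypergeometric.
Background sets are length-matched regions sampled uniformly away from the
peaks, seeded; BH adjustment runs across the motif library. Site-level
counting and non-uniform backgrounds are deliberately out of scope.

## Overlap statistics

Gene-set overlaps are judged against an *explicit* universe — the universe
term dominates the p-value and silently defaulting it would make results
incomparable, so it is a required argument. The chi-square statistic uses
the 2×2 shortcut form with Yates' correction, continuity term floored at
zero, margins of zero rejected; `stats::chisq.test(correct = TRUE)` serves
as an independent oracle in the tests (to 1e-9 over random tables), never
as the implementation. An exact hypergeometric upper tail and the Jaccard
index accompany it. Printed p-values floor at the conventional
`< 2.2e-16`.

## The GRN

Edges are binary regulatory-potential links: factor → gene for every gene
in the factor's nearest-TSS set that passes the target filters. The
default filters — target must itself encode a transcription factor and
carry embryonic-CNS-enriched expression — mirror a network whose purpose is
to connect early fate regulators to the later neurodevelopmental program;
both filters can be switched off. Co-binding (peak-level intersection of
two factors mapped back to genes) and knockdown-sensitive acetylation are
carried as edge/node evidence, not as edge signs: chromatin association
alone cannot establish activation versus repression, and cooperative
activation is an experimental observation, not an inference this artifact
can make. External factors enter as imported gene lists with provenance
"imported". Exports: edge TSV (round-trips through `import_grn_edges`),
GraphML and DOT via igraph.

# The synthetic-data generator

The generator *defines the study conditions* for every test; its defaults
are fixed once:

| parameter | default | rationale |
|---|---|---|
| genome | 3 × 1 Mb chromosomes | smallest size holding 300 gene slots |
| genes | 300, 2–8 kb, 2–5 exons | non-overlapping slot placement |
| true peaks per factor | 500, widths ~N(300, 80²) bp, min 50 | typical TF peak scale |
| replicates | 3, reproducibility 0.8 | matches a 2-of-3 consensus design |
| coordinate jitter | ±10% of width per replicate | replicate-to-replicate boundary wobble |
| promoter planting | 0.4 of true peaks | strong but not dominant promoter preference |
| FDR scores | true ~ U(0, threshold/2); noise ~ U(0, 1) | makes strict thresholding meaningful without read-level modelling |
| noise peaks | 100 per replicate | replicate-specific, rarely reach consensus |
| controls | 10% of peak count, 10% contaminated | contaminated controls sit on true peaks; the rest are placed clear of them |
| co-binding | 0.3 of factor-A peaks copied with jitter | shared-target structure between two factors |
| expression | NB (size 10), 3 tissue groups × 3 samples, lognormal baselines | standard RNA-seq emulation |
| planted CNS fold | 4× in 30% of genes | comfortably above the 2× classification threshold |
| motif planting | rate 0.5, consensus-sampled site at a uniform position | recoverable but not saturated |

Seeding: one master integer seed; each generator stage derives a child seed
(`(seed mod 1e5) × 1e4 + stage`), so stages regenerate independently and
every derived seed stays far below 2³¹. All generators are byte-identical
under a fixed seed; `with_seed()` isolates them from the caller's RNG
state.

Two generator choices deserve justification. First, expression library
sizes: the generator returns the *design* sequencing depth (baseline
expectation per sample) rather than realized column sums, because planting
a fold-change into half the genes inflates the realized totals of the
affected samples and a column-sum normalization would fold the planted
signal back into itself — with known depths, RPKM recovers the planted fold
directly, which is what a recovery test must isolate. Second,
uncontaminated control peaks are sampled away from the (jitter-padded) true
peaks, so that a zero-contamination configuration provably subtracts
nothing; the contaminated fraction is placed on true peaks.

What the generator does **not** emulate: read-level statistics (FDRs are
drawn, not computed), sequence composition (uniform i.i.d. bases, no CpG
structure, so planted motifs sit in a flat background), fragment-size
effects, overdispersed peak-width distributions, and correlated biological
replicates. Passing tests therefore demonstrate algorithmic correctness
and parameter identifiability under the declared noise model — not
performance on real chromatin data.

# Numerical and degenerate-input decisions

- Strict inequality at FDR thresholds; a peak scored exactly at the ceiling
  is dropped.
- Sorting is lexicographic (chromosome, start, end) with stable ties,
  enforced by the package itself rather than GRanges' strand-aware order.
- `N_background` uses floor division; enrichment is an error (not NaN) on an
  empty peak set.
- Constant expression rows z-score to zero with a warning; a single sample
  is an error.
- The continuity correction in Yates' chi-square floors at zero; any zero
  margin is an error rather than a 0/0.
- Hypergeometric tails come from `stats::phyper`; the full support sums to
  1 within 1e-12.
- Empty interval sets flow through every operation (subtracting nothing,
  merging nothing, thresholding nothing) and return empty results.
- Nearest-TSS on a gene-free chromosome yields an `NA` assignment with a
  warning instead of dropping the peak.

# Problem sizes

The default test run uses genomes of 0.3–30 Mb, 50–400 genes, and
80–5,000 planted peaks per configuration; the interval-algebra oracle runs
1,000 random instances of up to 200 intervals on a 10 kb chromosome, and
the acceptance script's recoveries use n = 1,000 planted peaks (binomial
bands), n = 5,000 for promoter enrichment, n = 10,000 for the null
calibration, and 200 sequences of 200 bp for motif recovery. These sizes
put every stochastic check comfortably inside its stated tolerance while
keeping a full suite run in minutes on one CPU.

# Known limitations

- The pipeline never touches raw reads; peak quality is whatever the
  upstream scorer produced, and only the FDR column is consulted.
- Nearest-TSS assignment is deliberately naive (no enhancer–gene linking,
  no isoform-level assignment); distal peaks map to the nearest gene even
  when implausible.
- The feature-enrichment statistic carries the interval-overlap bias
  discussed above; compare values only between peak sets of similar width.
- Published headline counts from the study this emulates require
  reprocessing the deposited raw data and are out of reach of a
  desk-scale, offline build; the package validates the *operations* those
  counts compose, on synthetic data with known truth.
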