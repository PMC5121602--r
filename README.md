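# neurogrn

Integration of transcription-factor chromatin association with histone
acetylation and tissue-resolved expression, ending in a directed gene
regulatory network (GRN) — the analysis style used to map how neural
transcription factors such as Geminin (Gmnn) and Zic1 select their target
genes as embryonic stem (ES) cells acquire a neuroectodermal (NE) fate.

The package is aimed at epigenomics analysts who have *scored peak files*
(ChIP-chip or ChIP-seq intervals with per-peak FDRs) rather than raw reads,
and who need the downstream integration to be reproducible and testable:

- **Peak processing** — per-replicate FDR thresholding (strict `fdr < 0.05`
  for factor ChIP, `fdr < 0.2` for H3K9ac), replicate consensus ("present in
  at least 2 of 3 replicates", reported as merged regions with support
  counts), whole-interval subtraction of input/untagged controls, and the
  knockdown contrast: H3K9ac consensus without knockdown minus consensus
  after doxycycline-induced knockdown = knockdown-sensitive acetylation.
- **Annotation** — strand-aware promoters (2 kb upstream to 0.5 kb
  downstream of the most 5′ TSS), nearest-TSS gene assignment by peak
  midpoint, genomic-location classification (promoter > 5′ UTR > 3′ UTR >
  exon > intron > intergenic), and the genomic-feature fold-enrichment
  statistic
  `E = (n_feature / n_peak) / (N_feature / N_background)`,
  where `N_background = floor(genome_length / avg_feature_length)` with the
  conventional averaged feature lengths (CpG island 601 bp, promoter
  2500 bp, enhancer 271 bp).
- **Expression** — RPKM normalization, per-gene z-scores across a tissue
  panel (sample sd), inclusive two-fold enrichment classification
  (embryonic CNS vs ES), and hierarchical gene ordering (Euclidean,
  average linkage).
- **Motifs** — JASPAR-format PWMs, two-strand log2-odds scanning with a
  score threshold expressed as a fraction of the maximum attainable score,
  and sequence-level hypergeometric enrichment of targets against
  length-matched sampled background regions, BH-adjusted across a library.
- **Set statistics** — 2×2 contingency tables over an explicit gene
  universe, chi-square with Yates' continuity correction
  `χ² = N (|ad − bc| − N/2)² / ((a+b)(c+d)(a+c)(b+d))`,
  exact hypergeometric overlap, and 2–3-way Venn region counts.
- **GRN construction** — directed regulator → target edges from
  per-factor gene sets, filtered by default to targets that are themselves
  transcription factors with embryonic-CNS-enriched expression; co-bound
  peaks and acetylation dependence ride along as evidence attributes;
  export to edge TSV / GraphML / DOT.
- **Synthetic data** — a first-class generator that plants every parameter
  the pipeline is supposed to recover (replicate reproducibility, promoter
  planting fraction, co-binding fraction, CNS expression fold, motif
  planting rate) so the entire analysis is exercised end to end with known
  ground truth and no downloads.

## Worked example

```r
library(neurogrn)
man <- run_pipeline(pipeline_config(seed = 1), outdir = "run1")
str(man$counts)
```

```
List of 13
 $ genes               : int 300
 $ gmnn_replicate_peaks: int [1:3] 500 498 500
 $ gmnn_consensus      : int 419
 $ zic1_consensus      : int 400
 $ acetyl_dependent    : int 143
 $ gmnn_genes          : int 231
 $ zic1_genes          : int 228
 $ cns_enriched_genes  : int 87
 $ motifs_tested       : int 2
 $ shared_genes        : num 186
 $ cobound_peaks       : int 133
 $ grn_edges           : int 32
 $ grn_nodes           : int 22
```

Reading the run: from 500 planted peaks per factor at replicate
reproducibility 0.8, the 2-of-3 consensus retains 419 control-subtracted
Gmnn regions (the closed-form survival is r³ + 3r²(1−r) = 0.896). Nearest-TSS
assignment maps them to 231 genes, 186 of which are shared with Zic1 — the
planted 30% co-binding plus nearest-gene convergence. The feature-enrichment
table in `run1/gmnn_feature_enrichment.tsv` shows promoter enrichment ≈ 1.8
(planted fraction 0.4 against a promoter background fraction of 0.25):

```
feature_name n_feature n_peak N_feature N_background avg_len enrichment
promoter           187    419       300         1200    2500   1.785
cpg_island          30    419       200         4991     601   1.787
enhancer            28    419       300        11070     271   2.466
```

The motif stage plants a GC-rich Zic-like site into half of the scanned peak
sequences; the planted PWM is recovered at p = 3.7e-09 while its
column-shuffled control stays at q = 0.58. The final GRN has 32 edges over
22 nodes, each target a CNS-enriched transcription factor, with co-binding
and acetylation-dependence flags on every edge
(`run1/grn_edges.tsv`, `run1/grn.graphml`, `run1/grn.dot`).

A thin command-line wrapper is installed at
`inst/scripts/neurogrn.R` (`Rscript neurogrn.R --config run.yaml --out dir`).

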