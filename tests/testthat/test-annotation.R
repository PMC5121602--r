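test_that("promoters span 2 kb upstream to 0.5 kb downstream, strand-aware", {
  sizes <- chrom_sizes(c(chr1 = 100000L))
  genes <- data.frame(gene_id = c("plus", "minus", "edge"),
                      chrom = "chr1", strand = c("+", "-", "+"),
                      start0 = c(10000, 5000, 1000),
                      end0 = c(15000, 10001, 3000),
                      tss0 = c(10000, 10000, 1000),
                      length_bp = c(5000, 5001, 2000))
  prom <- define_promoters(genes, sizes = sizes)
  i <- match(c("plus", "minus", "edge"), mcols(prom)$name)
  expect_equal(start0(prom)[i[1]], 8000)
  expect_equal(end0(prom)[i[1]], 10500)
  # minus strand mirrors around the TSS with the same 2500 bp length
  expect_equal(start0(prom)[i[2]], 9501)
  expect_equal(end0(prom)[i[2]], 12001)
  expect_equal(width(prom)[i[2]], 2500)
  # clipped at the chromosome start
  expect_equal(start0(prom)[i[3]], 0)
  expect_equal(end0(prom)[i[3]], 1500)
})

test_that("gene models derive TSS, exons, introns and UTRs from BED12 blocks", {
  ann <- tiny_annotation()
  g <- ann$genes
  expect_equal(g$tss0[g$gene_id == "geneA"], 10000)
  expect_equal(g$tss0[g$gene_id == "geneB"], 45999)   # minus strand: end - 1
  expect_equal(g$length_bp, rep(2000, 3))             # two 1 kb exons each
  exA <- ann$exons[mcols(ann$exons)$name == "geneA"]
  expect_equal(start0(exA), c(10000, 15000))
  expect_equal(end0(exA), c(11000, 16000))
  inA <- ann$introns[mcols(ann$introns)$name == "geneA"]
  expect_equal(start0(inA), 11000)
  expect_equal(end0(inA), 15000)
  # geneA: thick region [10500, 15500) -> 5' UTR is the exonic [10000,10500)
  u5A <- ann$utr5[mcols(ann$utr5)$name == "geneA"]
  expect_equal(start0(u5A), 10000)
  expect_equal(end0(u5A), 10500)
  u3A <- ann$utr3[mcols(ann$utr3)$name == "geneA"]
  expect_equal(start0(u3A), 15500)
  expect_equal(end0(u3A), 16000)
  # minus-strand gene swaps UTR sides
  u5B <- ann$utr5[mcols(ann$utr5)$name == "geneB"]
  expect_equal(start0(u5B), 45500)
})

test_that("multi-isoform genes use the 5'-most TSS", {
  sizes <- chrom_sizes(c(chr1 = 100000L))
  iso <- granges0(c("chr1", "chr1"), c(10000, 12000), c(20000, 20000),
                  strand = "+", name = c("g1", "g1"), score = c(0, 0),
                  sizes = sizes)
  ann <- build_annotation(iso, sizes = sizes)
  expect_equal(nrow(ann$genes), 1)
  expect_equal(ann$genes$tss0, 10000)
})

test_that("nearest TSS picks the minimal-distance gene with documented ties", {
  sizes <- chrom_sizes(c(chr1 = 100000L))
  genes <- granges0(c("chr1", "chr1"), c(1000, 5000), c(3000, 8000),
                    strand = "+", name = c("near", "far"), score = c(0, 0),
                    sizes = sizes)
  ann <- build_annotation(genes, sizes = sizes)
  hit <- nearest_tss(granges0("chr1", 2400, 2600, name = "pk"), ann)
  expect_equal(hit$gene_id, "near")       # 1500 < 2500
  expect_equal(hit$distance_bp, 1500)
  # exactly equidistant midpoint 3000: distances 2000/2000, smaller TSS wins
  tie <- nearest_tss(granges0("chr1", 2950, 3051), ann)
  expect_equal(tie$midpoint0, 3000)
  expect_equal(tie$gene_id, "near")
})

test_that("nearest TSS flags peaks on chromosomes without genes", {
  ann <- tiny_annotation()
  sizes3 <- chrom_sizes(c(chr1 = 100000L, chr2 = 100000L, chr3 = 100000L))
  pk <- granges0("chr3", 100, 200, name = "lost", sizes = sizes3)
  expect_warning(res <- nearest_tss(pk, ann), "without genes")
  expect_true(is.na(res$gene_id))
})

test_that("nearest TSS matches the exhaustive all-pairs oracle", {
  ann <- tiny_annotation()
  set.seed(101)
  n <- 500
  chrom <- sample(c("chr1", "chr2"), n, replace = TRUE)
  s0 <- sample.int(99000, n) - 1L
  peaks <- granges0(chrom, s0, s0 + 150, name = sprintf("p%d", 1:n))
  res <- nearest_tss(peaks, ann)
  for (i in seq_len(nrow(res))) {
    g <- ann$genes[ann$genes$chrom == res$chrom[i], ]
    d <- abs(res$midpoint0[i] - g$tss0)
    best <- g[d == min(d), ]
    best <- best[order(best$tss0, best$gene_id), ][1, ]
    expect_equal(res$gene_id[i], best$gene_id)
    expect_equal(res$distance_bp[i], min(d))
  }
})

test_that("genomic-location classes follow the priority rule and conserve counts", {
  ann <- tiny_annotation()
  # midpoint in geneA promoter region (upstream of TSS 10000)
  expect_equal(as.character(classify_genomic_location(
    granges0("chr1", 9000, 9100), ann)), "promoter")
  # promoter beats any other feature: downstream promoter region overlaps
  # the 5' UTR of geneA
  expect_equal(as.character(classify_genomic_location(
    granges0("chr1", 10100, 10200), ann)), "promoter")
  # inside the intron of geneA, outside the promoter
  expect_equal(as.character(classify_genomic_location(
    granges0("chr1", 12000, 12100), ann)), "intron")
  # far from every feature
  expect_equal(as.character(classify_genomic_location(
    granges0("chr1", 80000, 80100), ann)), "intergenic")
  set.seed(31)
  s0 <- sample.int(99000, 1000) - 1L
  many <- granges0(sample(c("chr1", "chr2"), 1000, TRUE), s0, s0 + 200)
  h <- table(classify_genomic_location(many, ann))
  expect_equal(sum(h), 1000)
})

test_that("feature enrichment reproduces the worked example exactly", {
  # 10 chromosomes of 2.5e8 bp = 2.5e9 bp genome; 20,000 features; 100 peaks
  # of which 50 overlap features; averaged feature length 2500 ->
  # N_background = 1e6 and enrichment = (50/100) / (20000/1e6) = 25.0
  sizes <- chrom_sizes(stats::setNames(rep(2.5e8, 10), paste0("chr", 1:10)))
  fs <- seq(0, by = 12500, length.out = 20000)
  feats <- granges0(rep("chr1", 20000), fs, fs + 100, sizes = sizes)
  hit_s <- fs[1:50] + 10
  miss_s <- fs[51:100] + 5000          # in the gaps between features
  peaks <- granges0(rep("chr1", 100), c(hit_s, miss_s),
                    c(hit_s, miss_s) + 50, sizes = sizes)
  fe <- feature_enrichment(peaks, feats, sizes, feature_name = "promoter")
  expect_equal(fe$n_feature, 50)
  expect_equal(fe$N_background, 1e6)
  expect_equal(fe$enrichment, 25.0)
  expect_error(feature_enrichment(peaks[integer(0)], feats, sizes), "empty")
})

test_that("feature enrichment is ~1 for uniformly placed narrow peaks", {
  set.seed(77)
  sizes <- chrom_sizes(c(chr1 = 3e6))
  fs <- sort(sample.int(3e6 - 601, 500)) - 1L
  feats <- granges0(rep("chr1", 500), fs, fs + 601, sizes = sizes)
  s0 <- sample.int(3e6 - 20, 10000) - 1L
  peaks <- granges0(rep("chr1", 10000), s0, s0 + 20)
  fe <- feature_enrichment(peaks, feats, sizes, feature_name = "cpg_island")
  expect_lt(abs(fe$enrichment - 1), 0.1)
})
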