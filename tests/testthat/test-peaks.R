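test_that("FDR thresholding is strict and validates scores", {
  ps <- mk_peaks(c(0, 300, 600), c(100, 400, 700), fdr = c(0.01, 0.05, 0.049))
  kept <- threshold_fdr(ps, 0.05)
  expect_equal(length(kept), 2)           # 0.05 excluded by strict inequality
  expect_equal(length(threshold_fdr(ps, 1.0)), 3)
  bare <- granges0("chr1", 0, 10)
  expect_error(threshold_fdr(bare), "fdr")
})

test_that("consensus merges supported candidates and drops unsupported ones", {
  rep1 <- mk_peaks(c(100, 5000), c(200, 5100), replicate = 1)
  rep2 <- mk_peaks(150, 250, replicate = 2)
  rep3 <- mk_peaks(9000, 9100, replicate = 3)
  cons <- consensus_peaks(list(rep1, rep2, rep3), consensus_params())
  expect_equal(start0(cons$gr), 100)      # [100,200) u [150,250) -> [100,250)
  expect_equal(end0(cons$gr), 250)
  expect_equal(mcols(cons$gr)$support, 2)
  expect_equal(cons$replicate, "consensus")
  # peaks seen in a single replicate ([5000,5100) and rep3's) are dropped
  expect_length(cons$gr, 1)
})

test_that("min_support = 1 reduces consensus to the merged union", {
  set.seed(11)
  reps <- lapply(1:3, function(r) {
    gr <- rand_ivs(80)
    mcols(gr)$fdr <- runif(80, 0, 0.04)
    peak_set(gr, "Gmnn", "NE", r)
  })
  cons1 <- consensus_peaks(reps, consensus_params(min_support = 1))
  pooled <- merge_peaks(do.call(c, lapply(reps, function(p) {
    g <- p$gr; mcols(g) <- NULL; g
  })))
  expect_equal(start0(cons1$gr), start0(pooled))
  expect_equal(end0(cons1$gr), end0(pooled))
})

test_that("consensus rejects mixed factors and too few replicates", {
  a <- mk_peaks(0, 100, factor = "Gmnn")
  b <- mk_peaks(0, 100, factor = "Zic1")
  expect_error(consensus_peaks(list(a, b)), "mix")
  expect_error(consensus_peaks(list(a), consensus_params(min_support = 2)),
               "min_support")
})

test_that("consensus is monotone in min_support and fdr_max", {
  set.seed(3)
  reps <- lapply(1:3, function(r) {
    gr <- rand_ivs(120)
    mcols(gr)$fdr <- runif(120)
    peak_set(gr, "Gmnn", "NE", r)
  })
  n_by_support <- vapply(1:3, function(ms)
    length(consensus_peaks(reps, consensus_params(fdr_max = 0.5,
                                                  min_support = ms))), 1L)
  expect_true(all(diff(n_by_support) <= 0))
  n_by_fdr <- vapply(c(0.1, 0.3, 0.6, 1.0), function(fm)
    length(consensus_peaks(reps, consensus_params(fdr_max = fm))), 1L)
  expect_true(all(diff(n_by_fdr) >= 0))
})

test_that("every consensus region traces back to supporting replicate peaks", {
  set.seed(19)
  reps <- lapply(1:3, function(r) {
    gr <- rand_ivs(100)
    mcols(gr)$fdr <- runif(100, 0, 0.04)
    peak_set(gr, "Gmnn", "NE", r)
  })
  cons <- consensus_peaks(reps, consensus_params())
  support <- Reduce(`+`, lapply(reps, function(p)
    as.integer(IRanges::overlapsAny(cons$gr, p$gr))))
  expect_true(all(support >= 2))
})

test_that("control subtraction is order-invariant and removes whole peaks", {
  exp <- mk_peaks(c(0, 1000, 2000), c(100, 1100, 2100))
  expect_equal(length(subtract_control(exp, list())), 3)
  blanket <- mk_peaks(0, 3000, condition = "control")
  expect_length(subtract_control(exp, list(blanket))$gr, 0)
  set.seed(5)
  ctls <- lapply(1:3, function(i) peak_set(rand_ivs(40), "Gmnn", "control", i))
  exp_gr <- peak_set(rand_ivs(100), "Gmnn", "NE")
  for (perm in list(c(2, 1, 3), c(3, 2, 1))) {
    ra <- subtract_control(exp_gr, ctls)
    rb <- subtract_control(exp_gr, ctls[perm])
    expect_equal(start0(ra$gr), start0(rb$gr))
    expect_equal(end0(ra$gr), end0(rb$gr))
  }
})

test_that("knockdown-sensitive acetylation is the consensus difference", {
  mk_rep <- function(s0, e0, r, cond) {
    ps <- mk_peaks(s0, e0, fdr = rep(0.1, length(s0)), factor = "H3K9ac",
                   condition = cond, replicate = r)
    ps
  }
  arm <- function(cond) lapply(1:3, function(r)
    mk_rep(c(100, 1000, 5000), c(300, 1200, 5200), r, cond))
  # identical arms annihilate
  dep <- gmnn_dependent_acetylation(arm("NE"), arm("NE+Dox"))
  expect_length(dep$gr, 0)
  # empty knockdown arm: everything is knockdown-sensitive
  empty_arm <- lapply(1:3, function(r)
    mk_rep(numeric(0), numeric(0), r, "NE+Dox"))
  dep2 <- gmnn_dependent_acetylation(arm("NE"), empty_arm)
  cons <- consensus_peaks(arm("NE"), consensus_params(fdr_max = 0.2))
  expect_equal(start0(dep2$gr), start0(cons$gr))
})

test_that("platform combining unions peaks and tracks provenance", {
  a <- mk_peaks(c(0, 1000, 2000), c(100, 1100, 2100))
  a$platform <- "chip_chip"
  b <- peak_set(granges0("chr1", c(5000, 6000, 7000, 8000),
                         c(5100, 6100, 7100, 8100)), "Gmnn", "NE",
                platform = "chip_seq")
  comb <- combine_platforms(a, b)
  expect_length(comb$gr, 7)
  expect_true(any(grepl("chip_chip", mcols(comb$gr)$name)))
  expect_true(any(grepl("chip_seq", mcols(comb$gr)$name)))
  # idempotence on identical sets
  same <- combine_platforms(a, a)
  expect_length(same$gr, 3)
  expect_error(combine_platforms(a, peak_set(b$gr, "Zic1", "NE")), "factor")
  # union coverage matches the per-base oracle
  set.seed(23)
  x <- peak_set(rand_ivs(150), "Gmnn", "NE")
  y <- peak_set(rand_ivs(150), "Gmnn", "NE")
  u <- combine_platforms(x, y)
  expect_identical(cover_vec(u$gr, 10000L),
                   cover_vec(x$gr, 10000L) | cover_vec(y$gr, 10000L))
})

test_that("the planted knockdown-sensitive acetylation fraction is recovered", {
  cfg <- synthetic_config(seed = 303, n_chroms = 3, chrom_length_bp = 5e6,
                          n_genes = 200, peaks_per_replicate = 1000,
                          replicate_reproducibility = 0.95,
                          promoter_planting_fraction = 0,
                          noise_peaks_per_replicate = 30,
                          fdr_threshold = 0.2)
  gen <- simulate_genome(cfg, with_sequence = FALSE)
  no_dox <- simulate_peak_replicates(cfg, gen$annotation, factor = "H3K9ac",
                                     condition = "NE", stage = 8L)
  # knockdown arm: 30% of the true acetylation peaks are lost
  keep <- with_seed(4242, runif(1000) >= 0.3)
  dox <- neurogrn:::.replicate_wrap(cfg, gen$annotation,
                                    no_dox$true_peaks[keep], "H3K9ac",
                                    "NE+Dox", 9999L)
  dep <- gmnn_dependent_acetylation(no_dox$replicates, dox$replicates,
                                    consensus_params(fdr_max = 0.2))
  recovered <- sum(IRanges::overlapsAny(no_dox$true_peaks, dep$gr))
  band <- qbinom(c(0.005, 0.995), 1000, 0.3)
  expect_gte(recovered, band[1])
  expect_lte(recovered, band[2])
})
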