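test_that("PWM columns normalize to unit sums and max score is attainable", {
  set.seed(2)
  mat <- matrix(runif(28), 4, 7)
  p <- motif_pwm(mat, "rand")
  expect_true(all(abs(colSums(p$prob) - 1) < 1e-6))
  expect_equal(pwm_max_score(p), sum(apply(p$logodds, 2, max)))
  expect_error(motif_pwm(matrix(1, 3, 5)), "4 rows")
})

test_that("log-odds scanning finds hand-scored hits on both strands", {
  ac <- exact_pwm("AC")
  hits <- scan_pwm(c(s1 = "TTACG"), ac, score_fraction = 1)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$offset, 2)
  expect_equal(hits$strand, "+")
  expect_equal(hits$score, 2 * log2(1 / 0.25))   # 4 bits
  # reverse strand: "GT" at offset 0 is the reverse complement of "AC"
  rc <- scan_pwm(c(s1 = "GTTTT"), ac, score_fraction = 1)
  expect_equal(rc$strand, "-")
  expect_equal(rc$offset, 0)
  # a fully degenerate column ties the maximum at every offset
  unif <- motif_pwm(matrix(0.25, 4, 1), "unif", pseudocount = 0)
  all_hits <- scan_pwm(c(s = "ACGT"), unif, score_fraction = 1)
  expect_equal(sum(all_hits$strand == "+"), 4)
  expect_warning(scan_pwm(c(s = "ACG"), exact_pwm("ACGTA"), 0.8), "longer")
})

test_that("scanning agrees with brute-force enumeration on random sequences", {
  set.seed(17)
  pwm <- motif_pwm(matrix(runif(20, 0.05, 1), 4, 5), "rnd")
  lo <- pwm$logodds
  seqs <- random_seqs(15, 80)
  thr <- 0.6 * pwm_max_score(pwm)
  hits <- scan_pwm(seqs, pwm, score_fraction = 0.6)
  base_idx <- function(s) match(strsplit(s, "")[[1]], c("A", "C", "G", "T"))
  rc <- function(s) chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]),
                                                 collapse = ""))
  for (id in names(seqs)) {
    s <- seqs[[id]]
    expected <- list()
    for (o in 0:(nchar(s) - 5)) {
      for (st in c("+", "-")) {
        word <- substr(s, o + 1, o + 5)
        if (st == "-") word <- rc(word)
        sc <- sum(lo[cbind(base_idx(word), 1:5)])
        if (sc >= thr) expected[[length(expected) + 1]] <-
            data.frame(offset = o, strand = st, score = sc)
      }
    }
    got <- hits[hits$sequence_id == id, ]
    exp_df <- if (length(expected)) do.call(rbind, expected) else
      data.frame(offset = integer(0), strand = character(0), score = numeric(0))
    got <- got[order(got$offset, got$strand), ]
    exp_df <- exp_df[order(exp_df$offset, exp_df$strand), ]
    expect_equal(got$offset, exp_df$offset, info = id)
    expect_equal(got$strand, exp_df$strand, info = id)
    expect_equal(got$score, exp_df$score, info = id)
  }
})

test_that("hypergeometric enrichment matches the exact combinatorial value", {
  pwm <- exact_pwm("ACGTAC")
  with_site <- function(n, prefix) {
    s <- random_seqs(n, 40, prefix)
    vapply(s, function(x) { substr(x, 10, 15) <- "ACGTAC"; x }, "")
  }
  set.seed(4)
  targets <- with_site(5, "t")
  bg <- stats::setNames(rep(strrep("A", 40), 5), sprintf("b%d", 1:5))
  res <- motif_enrichment_test(targets, bg, pwm, score_fraction = 1)
  expect_equal(res$n_target_with, 5)
  expect_equal(res$p_value, 1 / choose(10, 5))
  # k = 0 gives p = 1
  res0 <- motif_enrichment_test(bg, targets, pwm, score_fraction = 1)
  expect_equal(res0$n_target_with, 0)
  expect_equal(res0$p_value, 1)
  names(bg)[1] <- names(targets)[1]
  expect_error(motif_enrichment_test(targets, bg, pwm), "overlap")
})

test_that("hypergeometric closed form agrees with resampling", {
  N <- 60; K <- 25; n <- 20; k <- 12
  p_exact <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  set.seed(8)
  draws <- rhyper(1e5, K, N - K, n)
  p_mc <- mean(draws >= k)
  se <- sqrt(p_mc * (1 - p_mc) / 1e5)
  expect_lt(abs(p_exact - p_mc), 3 * se)
  # full support sums to one
  expect_lt(abs(sum(dhyper(0:n, K, N - K, n)) - 1), 1e-12)
})

test_that("motif ranking adjusts with BH and keeps q monotone", {
  set.seed(21)
  cfg <- synthetic_config(seed = 21, motif_planting_rate = 0.5)
  pwm <- exact_pwm("ACGTACGT")
  targets <- random_seqs(60, 120, "t")
  planted <- plant_motif(cfg, targets, pwm)
  bg <- random_seqs(60, 120, "b")
  shuffled <- motif_pwm(pwm$prob[, c(3, 1, 4, 2, 8, 6, 7, 5)], "shuffled",
                        pseudocount = 0)
  other <- exact_pwm("TTTTGGGG", name = "other")
  tab <- rank_motifs(planted$sequences, bg, list(pwm, shuffled, other),
                     score_fraction = 1)
  expect_equal(tab$motif[1], "ACGTACGT")
  expect_lt(tab$p_value[1], 1e-6)
  expect_gt(tab$q_value[tab$motif == "shuffled"], 0.05)
  expect_true(all(diff(tab$q_value) >= -1e-12))
  single <- rank_motifs(planted$sequences, bg, list(pwm), score_fraction = 1)
  expect_equal(single$q_value, single$p_value)
})

test_that("peak sequence extraction matches coordinates and round-trips", {
  genome <- Biostrings::DNAStringSet(c(chr1 = "ACGTACGTGG", chr2 = "TTTTCCCC"))
  peaks <- granges0(c("chr1", "chr2"), c(0, 4), c(5, 8),
                    name = c("p1", "p2"))
  seqs <- extract_peak_sequences(peaks, genome)
  expect_equal(as.character(seqs[["p1"]]), "ACGTA")
  expect_equal(as.character(seqs[["p2"]]), "CCCC")
  expect_equal(Biostrings::width(seqs), width(peaks))
  bad <- granges0("chr1", 5, 20, name = "oob")
  expect_error(extract_peak_sequences(bad, genome), "oob")
  # write-then-extract identity on a synthetic genome
  cfg <- synthetic_config(seed = 3, n_chroms = 1, chrom_length_bp = 60000,
                          n_genes = 4, n_cpg_islands = 2, n_enhancers = 2)
  gen <- simulate_genome(cfg)
  fa <- withr::local_tempfile(fileext = ".fa")
  Biostrings::writeXStringSet(gen$genome, fa)
  pk <- granges0("chr1", c(100, 5000), c(400, 5300), name = c("a", "b"))
  expect_equal(as.character(extract_peak_sequences(pk, fa)),
               as.character(extract_peak_sequences(pk, gen$genome)))
})

test_that("background sampling is length-matched, peak-free and seeded", {
  set.seed(99)
  sizes <- chrom_sizes(c(chr1 = 200000L, chr2 = 200000L))
  pk <- rand_ivs(50, L = 150000L, sizes = NULL)
  bg1 <- sample_background_regions(pk, sizes, seed = 42, n_per_peak = 2)
  bg2 <- sample_background_regions(pk, sizes, seed = 42, n_per_peak = 2)
  expect_length(bg1, 100)
  expect_false(any(IRanges::overlapsAny(bg1, pk)))
  expect_equal(sort(width(bg1)), sort(rep(width(pk), 2)))
  expect_equal(start0(bg1), start0(bg2))
  bg3 <- sample_background_regions(pk, sizes, seed = 43, n_per_peak = 2)
  expect_false(identical(start0(bg1), start0(bg3)))
})

test_that("JASPAR text round-trips through read and write", {
  pwms <- list(motif_pwm(matrix(c(10, 2, 1, 1,
                                  1, 12, 1, 3,
                                  2, 2, 9, 1,
                                  1, 1, 2, 8), 4, 4, byrow = TRUE), "M1"),
               exact_pwm("ACG"))
  f <- withr::local_tempfile(fileext = ".jaspar")
  write_jaspar(pwms, f)
  back <- read_jaspar(f, pseudocount = 0)
  expect_equal(names(back), c("M1", "ACG"))
  expect_equal(back$M1$prob, pwms[[1]]$prob, tolerance = 1e-5)
})
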