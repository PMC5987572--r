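test_that("build_pwm follows the log-odds formula and its symmetries", {
  # uniform column has zero log-odds regardless of pseudocount
  m <- build_pwm(matrix(2, 3, 4), pseudocount = 0.7)
  expect_equal(unname(m$pwm), matrix(0, 3, 4))
  # direct formula evaluation for a skewed column
  m2 <- build_pwm(matrix(c(8, 0, 0, 0), 1, 4), pseudocount = 1)
  expect_equal(unname(m2$pwm[1, "A"]), log2((8 + 0.25) / 9 / 0.25))
  expect_equal(unname(m2$pwm[1, "C"]), log2(0.25 / 9 / 0.25))
  # reverse-complemented PWM scores the reverse complement of any k-mer
  # identically to the original PWM on that k-mer
  set.seed(1)
  for (i in 1:5) {
    pfm <- random_pfm(6)
    mod <- build_pwm(pfm)
    rc <- ocregnet:::revcomp_model(mod)
    kmer <- sample(1:4, 6, replace = TRUE)
    kmer_rc <- rev(5 - kmer)
    expect_equal(sum(mod$pwm[cbind(1:6, kmer)]),
                 sum(rc$pwm[cbind(1:6, kmer_rc)]))
  }
})

test_that("build_pwm rejects degenerate input", {
  expect_error(build_pwm(matrix(0, 2, 4), pseudocount = 0), "degenerate")
  expect_error(build_pwm(matrix(1, 2, 4), background = c(0.5, 0.5, 0, 0)),
               "background")
  expect_error(build_pwm(matrix(-1, 2, 4)), "non-negative")
})

test_that("DP null score distribution matches exhaustive enumeration", {
  # single position, uniform background: 0.25 mass per base score
  m1 <- build_pwm(matrix(c(9, 3, 1, 1), 1, 4))
  d1 <- null_score_distribution(m1)
  expect_equal(sum(d1$pmf), 1, tolerance = 1e-9)
  expect_true(all(abs(d1$pmf[d1$pmf > 0] - 0.25) < 1e-12 |
                    abs(d1$pmf[d1$pmf > 0] - 0.5) < 1e-12))
  set.seed(42)
  for (i in 1:12) {
    L <- sample(2:6, 1)
    bg <- if (i %% 2) rep(0.25, 4) else { b <- runif(4, 0.1, 1); b / sum(b) }
    mod <- build_pwm(random_pfm(L), background = bg)
    d <- null_score_distribution(mod)
    # survival function is non-increasing, starts at 1, ends at pmf max
    expect_true(all(diff(d$sf) <= 1e-15))
    expect_equal(d$sf[1], 1, tolerance = 1e-12)
    probe <- d$scores[sample(length(d$scores), min(8, length(d$scores)))]
    expect_equal(ocregnet:::sf_at(d, round(probe / d$granularity)),
                 sf_by_enumeration(mod, probe), tolerance = 1e-12)
  }
})

test_that("p-value threshold lookup follows the survival table", {
  toy <- structure(list(granularity = 1, int_scores = c(5L, 7L, 9L),
                        scores = c(5, 7, 9), pmf = c(0.8, 0.15, 0.05),
                        sf = c(0.2, 0.05, 0.01)),
                   class = "score_distribution")
  expect_equal(pvalue_threshold_score(toy, 0.05), 7)
  expect_equal(pvalue_threshold_score(toy, 1), 5)
  expect_equal(pvalue_threshold_score(toy, 0.005), Inf)
  expect_error(pvalue_threshold_score(toy, 0), "p_threshold")
  # a sharp L=6 motif under uniform background cannot reach p = 1e-4
  # (minimum attainable p-value is 4^-6 ~ 2.4e-4)
  sharp <- build_pwm(matrix(c(rep(100, 6), rep(0, 18)), 6, 4), pseudocount = 0.4)
  d6 <- null_score_distribution(sharp)
  expect_identical(pvalue_threshold_score(d6, 1e-4), Inf)
  expect_lt(pvalue_threshold_score(d6, 3e-4), Inf)
})

test_that("promoter scanning finds planted sites on both strands", {
  pfm <- matrix(1, 8, 4); pfm[, 1] <- 60  # near-consensus AAAAAAAA
  model <- build_pwm(pfm, tf_id = "tf1")
  set.seed(7)
  bg <- random_dna(2500)
  site <- paste(rep("A", 8), collapse = "")
  # plant forward at TSS-relative +100 (TSS at 0-based index 1000)
  seq_fwd <- paste0(substr(bg, 1, 1100), site, substr(bg, 1109, 2500))
  hits <- scan_promoter(model, promoter_record("g1", seq_fwd, 1000), 1e-4)
  expect_true(any(hits$offset == 100 & hits$match_strand == "+"))
  expect_true(all(hits$pvalue <= 1e-4))
  # plant the reverse complement: hit reported at same offset, strand '-'
  seq_rev <- paste0(substr(bg, 1, 1100), rc_string(site), substr(bg, 1109, 2500))
  hits_rev <- scan_promoter(model, promoter_record("g2", seq_rev, 1000), 1e-4)
  expect_true(any(hits_rev$offset == 100 & hits_rev$match_strand == "-"))
  # all-N sequence and too-short sequence scan to nothing
  expect_equal(nrow(scan_promoter(model,
    promoter_record("g3", strrep("N", 300), 100), 1e-4)), 0)
  expect_equal(nrow(scan_promoter(model,
    promoter_record("g4", "ACGT", 1), 1e-4)), 0)
})

test_that("scanning agrees with a pure-R reference scanner", {
  set.seed(11)
  model <- build_pwm(random_pfm(7), tf_id = "t")
  d <- null_score_distribution(model)
  thr <- pvalue_threshold_score(d, 0.01)
  s <- random_dna(1500)
  hits <- scan_promoter(model, promoter_record("g", s, 700), 0.01)
  fwd <- sort(hits$offset[hits$match_strand == "+"]) + 700
  expect_equal(fwd, scan_by_loop(model, s, thr) - 1)
  # strand closure: '-' hits are '+' hits of the reverse-complement model
  rc_hits <- sort(hits$offset[hits$match_strand == "-"]) + 700
  expect_equal(rc_hits,
               scan_by_loop(ocregnet:::revcomp_model(model), s, thr) - 1)
})

test_that("observed background hit counts match the calibrated rate", {
  # across seeded replicates the two-strand hit count stays within four
  # binomial standard deviations of 2 * n_windows * S(threshold)
  set.seed(13)
  model <- build_pwm(random_pfm(6), tf_id = "t")
  d <- null_score_distribution(model)
  p_thr <- 0.002
  thr <- pvalue_threshold_score(d, p_thr)
  p_hit <- ocregnet:::sf_at(d, round(thr / d$granularity))
  n <- 4000; reps <- 20
  counts <- vapply(seq_len(reps), function(i) {
    nrow(scan_promoter(model, promoter_record("g", random_dna(n), n / 2), p_thr))
  }, numeric(1))
  n_trials <- 2 * (n - 5) * reps
  expected <- n_trials * p_hit
  expect_lt(abs(sum(counts) - expected), 4 * sqrt(expected * (1 - p_hit)))
})

test_that("hits are binned into the 12 disjoint strand x distance windows", {
  expect_equal(sum(bin_hits(data.frame(offset = integer(),
                                       match_strand = character()))), 0)
  one <- data.frame(offset = -600, match_strand = "+")
  b <- bin_hits(one)
  expect_equal(unname(b["plus_up2k"]), 1L)
  expect_equal(sum(b), 1L)
  # boundary conventions: offset 0 is downstream; -500 belongs to up500
  expect_equal(unname(bin_hits(data.frame(offset = 0, match_strand = "-"))["minus_down500"]), 1L)
  expect_equal(unname(bin_hits(data.frame(offset = -500, match_strand = "+"))["plus_up500"]), 1L)
  expect_error(bin_hits(data.frame(offset = 10001, match_strand = "+")),
               "outside promoter")
  # 1000 random offsets: totals equal a direct histogram, count conserved
  set.seed(3)
  h <- data.frame(offset = sample(-10000:10000, 1000, replace = TRUE),
                  match_strand = sample(c("+", "-"), 1000, replace = TRUE))
  b2 <- bin_hits(h)
  expect_equal(sum(b2), 1000L)
  breaks <- c(-10000, -2000, -500, 0, 500, 2000, 10001)
  for (s in c("+", "-")) {
    ref <- hist(h$offset[h$match_strand == s], breaks = c(breaks[1:6], 10000.5),
                plot = FALSE, right = FALSE)$counts
    got <- b2[paste0(if (s == "+") "plus" else "minus",
                     c("_up10k", "_up2k", "_up500", "_down500", "_down2k", "_down10k"))]
    expect_equal(unname(got), ref)
  }
})

test_that("motif feature table matches per-promoter scanning and binning", {
  set.seed(9)
  models <- list(build_pwm(random_pfm(6), tf_id = "tfA"),
                 build_pwm(random_pfm(8), tf_id = "tfB"))
  proms <- lapply(1:4, function(i)
    promoter_record(paste0("g", i), random_dna(3000), 1500))
  tab <- motif_feature_table(models, proms, p_threshold = 0.001)
  expect_equal(dim(tab), c(4, 24))
  for (m in models) for (p in proms) {
    h <- scan_promoter(m, p, p_threshold = 0.001)
    expect_equal(unname(tab[p$gene_id, paste(m$tf_id, ocregnet:::MOTIF_BIN_NAMES,
                                             sep = ".")]),
                 unname(bin_hits(h)))
  }
})

test_that("JASPAR and minimal MEME motif files are parsed", {
  jaspar <- tempfile(fileext = ".pfm")
  writeLines(c(">MA0001.1 TFX",
               "A [ 3 10  2 ]", "C [ 1  0  2 ]",
               "G [ 5  0  2 ]", "T [ 1  0  4 ]",
               ">MA0002.1 TFY",
               "A 1 1", "C 1 1", "G 1 1", "T 7 7"), jaspar)
  ms <- read_jaspar_pfm(jaspar)
  expect_named(ms, c("TFX", "TFY"))
  expect_equal(unname(ms$TFX$pfm[2, ]), c(10, 0, 0, 0))
  expect_equal(nrow(ms$TFY$pwm), 2)
  # duplicate TF id: first kept with a warning
  writeLines(c(">M1 TFZ", "A 1", "C 1", "G 1", "T 1",
               ">M2 TFZ", "A 9", "C 0", "G 0", "T 0"), jaspar)
  expect_warning(dup <- read_jaspar_pfm(jaspar), "keeping the first")
  expect_equal(unname(dup$TFZ$pfm[1, 1]), 1)
  meme <- tempfile(fileext = ".meme")
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "MOTIF M1 TFM",
               "letter-probability matrix: alength= 4 w= 2 nsites= 10",
               " 0.7 0.1 0.1 0.1", " 0.25 0.25 0.25 0.25"), meme)
  mm <- read_meme_motifs(meme)
  expect_equal(unname(mm$TFM$pfm[1, ]), c(7, 1, 1, 1))
})
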