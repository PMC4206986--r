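test_that("log-odds scoring follows the definition", {
  # a PWM equal to the background is uninformative: score 0 everywhere
  bg <- c(0.3, 0.2, 0.2, 0.3)
  flat <- pwm("flat", matrix(bg, 4, 5))
  withr::local_seed(2)
  for (i in 1:5) {
    w <- random_dna(5)
    expect_equal(log_odds_score(flat, w, background = bg, pseudocount = 0), 0)
  }

  # hand computation: consensus "AC" under a uniform background, no
  # pseudocount: log2(1/0.25) + log2(1/0.25) = 4 bits
  ac <- pwm("ac", matrix(c(1, 0, 0, 0, 0, 1, 0, 0), 4, 2))
  expect_equal(log_odds_score(ac, "AC", pseudocount = 0), 4.0)

  # N positions are score-neutral
  expect_equal(log_odds_score(ac, "NN", pseudocount = 0), 0)
  expect_equal(log_odds_score(ac, "AN", pseudocount = 0), 2.0)

  expect_error(log_odds_score(ac, "ACG"), "length")

  # agreement with the naive per-window oracle under pseudocounts
  x <- random_pwm("r", L = 6)
  for (i in 1:10) {
    w <- random_dna(6)
    expect_equal(log_odds_score(x, w, bg, 0.01),
                 naive_window_score(x, w, bg, 0.01))
  }
})

test_that("scan_promoter finds the planted consensus and respects the
          threshold ceiling", {
  x <- generate_pwms(1, pwm_length = 8, info_bits = 2, seed = 3)[[1]]
  cons <- pwm_consensus(x)
  prom <- mk_promoter(paste0("AATTAATTAA", cons, "AATTAATTAA"), tss = 10L)
  hits <- scan_promoter(x, prom, threshold = 1.0)  # only the max score
  expect_gte(nrow(hits), 1)
  expect_true(any(hits$start == 0 & hits$strand == "+"))

  # a threshold above the maximum attainable score yields nothing
  none <- scan_promoter(x, prom, pwm_max_score(x) + 1, "bits")
  expect_identical(nrow(none), 0L)

  # promoter shorter than the motif: empty result, not an error
  expect_identical(nrow(scan_promoter(x, mk_promoter("ACGT"), 0.5)), 0L)
})

test_that("scanner equals the exhaustive both-strand oracle with pruning", {
  withr::local_seed(31)
  bg <- rep(0.25, 4)
  for (i in 1:12) {
    L <- sample(5:9, 1)
    x <- random_pwm(sprintf("t%d", i), L = L, conc = 0.4)
    prom <- mk_promoter(random_dna(sample(80:250, 1), gc = 0.5),
                        tss = sample(0:50, 1))
    thr <- stats::runif(1, 0.5, 0.9) * pwm_max_score(x, bg, 0.01)
    got <- scan_promoter(x, prom, thr, "bits", bg, 0.01)
    want <- naive_scan(x, prom, thr, bg, 0.01)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("raising the threshold never adds hits", {
  withr::local_seed(17)
  x <- random_pwm("m", L = 7, conc = 0.4)
  prom <- mk_promoter(random_dna(600), tss = 300L)
  lo <- scan_promoter(x, prom, 0.6)
  hi <- scan_promoter(x, prom, 0.8)
  expect_lte(nrow(hi), nrow(lo))
  # every retained high-threshold site also passes the low threshold
  expect_true(all(hi$score %in% lo$score | hi$score >= 0.8 * pwm_max_score(x)))
})

test_that("scanning the reverse complement mirrors the hit set with
          strands flipped", {
  withr::local_seed(23)
  x <- random_pwm("s", L = 6, conc = 0.4)
  seq <- random_dna(400)
  n <- nchar(seq)
  fwd <- scan_promoter(x, mk_promoter(seq, tss = 0L), 0.7)
  rev <- scan_promoter(x, mk_promoter(naive_revcomp(seq), tss = 0L), 0.7)
  # map reverse-promoter hits back to forward coordinates
  mapped <- data.frame(start = n - rev$end, end = n - rev$start,
                       strand = ifelse(rev$strand == "+", "-", "+"),
                       score = rev$score)
  ord <- function(d) d[order(d$start, d$strand), c("start", "end", "strand", "score")]
  expect_equal(ord(mapped), ord(fwd[, c("start", "end", "strand", "score")]),
               ignore_attr = TRUE)
})

test_that("Poisson enrichment matches direct mass summation", {
  # no hits: certain under the null
  none <- dataset_enrichment("t", c(0, 0), c(1000, 1000), 1)
  expect_equal(none$p_value, 1.0)
  expect_equal(none$enrichment_ratio, 0)

  # observation equal to expectation: ratio exactly 1
  at <- dataset_enrichment("t", c(3, 2), promoter_lengths = c(2500, 2500), 1)
  expect_equal(at$enrichment_ratio, 1.0)

  # 20 hits at expectation 5: upper tail by explicit series
  enr <- dataset_enrichment("t", 20, 5000, 1)
  direct <- 1 - sum(exp(-5) * 5^(0:19) / factorial(0:19))
  expect_equal(enr$p_value, direct, tolerance = 1e-8)

  expect_error(dataset_enrichment("t", -1, 1000, 1), "negative")
  expect_error(dataset_enrichment("t", 1, 1000, 0), "expected_rate")
})

test_that("exact background rate matches brute-force window enumeration", {
  bg <- c(0.3, 0.2, 0.2, 0.3)
  x <- random_pwm("b", L = 5, conc = 0.6)
  thr <- 0.6 * pwm_max_score(x, bg, 0.01)
  # enumerate all 4^5 windows on both strands
  grid <- expand.grid(rep(list(BASES), 5), stringsAsFactors = FALSE)
  probs <- apply(grid, 1, function(w) prod(bg[match(w, BASES)]))
  wins <- apply(grid, 1, paste, collapse = "")
  p_fwd <- sum(probs[vapply(wins, function(w)
    naive_window_score(x, w, bg, 0.01), 0) >= thr])
  p_rev <- sum(probs[vapply(wins, function(w)
    naive_window_score(x, naive_revcomp(w), bg, 0.01), 0) >= thr])
  expect_equal(pwm_background_rate(x, thr, bg, 0.01),
               1000 * (p_fwd + p_rev), tolerance = 1e-3)
})

test_that("virtual supportive tools call planted, not background, TFs", {
  withr::local_seed(41)
  pws <- generate_pwms(4, pwm_length = 8, info_bits = 1.8, seed = 12)
  # plant many copies of TF01 only
  cons <- pwm_consensus(pws[[1]])
  proms <- lapply(1:6, function(i) {
    seq <- random_dna(900)
    for (at in c(100, 300, 500, 700)) {
      substr(seq, at, at + 7) <- cons
    }
    mk_promoter(seq, tss = 0L, gene_id = sprintf("g%d", i))
  })
  reps <- virtual_supportive_reports(proms, pws, thresholds = 0.9,
                                     alpha = 0.01)
  expect_length(reps, 1)
  expect_true("TF01" %in% reps[[1]]$reported_tfs)
  expect_false(any(c("TF03", "TF04") %in% reps[[1]]$reported_tfs) &&
                 "TF02" %in% reps[[1]]$reported_tfs)
})
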