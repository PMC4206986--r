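#' Log-odds scoring matrix for a PWM
#'
#' Cell (b, j) holds `log2(p'_j(b) / background(b))`, where `p'` is the
#' pseudocount-regularized column (`pseudocount` added per cell, column
#' renormalized). A fifth row for N is fixed at 0, so ambiguous bases are
#' score-neutral.
#'
#' @param x a `pwm`.
#' @param background strictly positive 4-vector over (A,C,G,T) summing to 1.
#' @param pseudocount per-cell regularizer added before renormalization
#'   (default 0.01).
#' @return 5 x L numeric matrix (rows A, C, G, T, N).
#' @export
scoring_matrix <- function(x, background = rep(0.25, 4), pseudocount = 0.01) {
  check_background(background)
  p <- x$probabilities + pseudocount
  p <- sweep(p, 2, colSums(p), "/")
  m <- log2(sweep(p, 1, background, "/"))
  rbind(m, N = 0)
}

## scoring matrix for hits on the minus strand: position j of the window
## pairs with PWM position L+1-j on the complementary base
rc_scoring_matrix <- function(m) {
  L <- ncol(m)
  out <- m[c(4:1, 5), L:1, drop = FALSE]
  rownames(out) <- DNA_ALPHABET
  out
}

#' Log-odds score of one window
#'
#' `sum_j log2(p'_j(w_j) / background(w_j))` in bits; N positions contribute
#' 0. A PWM whose columns all equal the background scores 0 on every window.
#'
#' @param x a `pwm`.
#' @param window DNA string of length `pwm_length(x)`.
#' @inheritParams scoring_matrix
#' @return score in bits.
#' @export
log_odds_score <- function(x, window, background = rep(0.25, 4),
                           pseudocount = 0.01) {
  L <- pwm_length(x)
  if (nchar(window) != L) {
    stop("window length ", nchar(window), " != PWM length ", L)
  }
  m <- scoring_matrix(x, background, pseudocount)
  codes <- encode_dna(window)
  sum(m[cbind(codes, seq_len(L))])
}

#' Maximal attainable log-odds score of a PWM
#'
#' @inheritParams scoring_matrix
#' @return best possible window score, in bits.
#' @export
pwm_max_score <- function(x, background = rep(0.25, 4), pseudocount = 0.01) {
  m <- scoring_matrix(x, background, pseudocount)
  sum(apply(m[1:4, , drop = FALSE], 2, max))
}

## all window scores on one strand; codes: encoded promoter, m: 5 x L matrix.
## Returns numeric(0) when the sequence is shorter than the motif.
strand_scores <- function(codes, m) {
  L <- ncol(m)
  n <- length(codes)
  if (n < L) return(numeric(0))
  k <- n - L + 1L
  sc <- numeric(k)
  for (j in seq_len(L)) {
    sc <- sc + m[cbind(codes[j:(k + j - 1L)], j)]
  }
  sc
}

#' Greedy de-overlapping of same-TF hits
#'
#' Keeps the higher-scoring hit among overlapping ones (ties broken by
#' smaller start, then + strand). Overlap is >= 1 shared bp between the
#' half-open intervals `[start, end)`, regardless of strand. Applied per
#' (gene, tf): occurrences are counted as discrete, disjoint sites.
#'
#' @param hits data.frame with columns start, end, strand, score (and any
#'   others, carried through).
#' @return the retained rows, sorted by start then strand.
#' @export
prune_hits <- function(hits) {
  if (nrow(hits) <= 1) return(hits)
  ord <- order(-hits$score, hits$start, match(hits$strand, c("+", "-")))
  hits <- hits[ord, , drop = FALSE]
  keep <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    kept <- which(keep)
    if (!any(hits$start[kept] < hits$end[i] & hits$end[kept] > hits$start[i])) {
      keep[i] <- TRUE
    }
  }
  out <- hits[keep, , drop = FALSE]
  out[order(out$start, match(out$strand, c("+", "-"))), , drop = FALSE]
}

empty_hits <- function() {
  data.frame(gene_id = character(), tf_id = character(),
             start = integer(), end = integer(), strand = character(),
             score = numeric(), stringsAsFactors = FALSE)
}

#' Scan a promoter with a PWM on both strands
#'
#' Scores every window on both strands against the pseudocount-regularized
#' log-odds model, keeps windows scoring at or above the threshold, then
#' greedily removes overlapping hits (see [prune_hits()]). Positions are
#' reported TSS-relative (negative = upstream), half-open `[start, end)`.
#'
#' @param x a `pwm`.
#' @param promoter a `promoter_record`.
#' @param threshold numeric; absolute bits when `threshold_type = "bits"`,
#'   or a fraction of the PWM's maximal score when `"relative"` (default).
#' @inheritParams scoring_matrix
#' @param threshold_type `"relative"` or `"bits"`.
#' @return data.frame of hits (gene_id, tf_id, start, end, strand, score);
#'   empty when the promoter is shorter than the motif.
#' @export
scan_promoter <- function(x, promoter, threshold = 0.8,
                          threshold_type = c("relative", "bits"),
                          background = rep(0.25, 4), pseudocount = 0.01) {
  threshold_type <- match.arg(threshold_type)
  m <- scoring_matrix(x, background, pseudocount)
  thr <- if (threshold_type == "relative") {
    threshold * pwm_max_score(x, background, pseudocount)
  } else {
    threshold
  }
  codes <- encode_dna(promoter$sequence)
  L <- ncol(m)
  fwd <- strand_scores(codes, m)
  rev <- strand_scores(codes, rc_scoring_matrix(m))
  rows <- list(empty_hits())
  for (s in c("+", "-")) {
    sc <- if (s == "+") fwd else rev
    at <- which(sc >= thr)
    if (length(at)) {
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = promoter$gene_id, tf_id = x$tf_id,
        start = at - 1L - promoter$tss_offset,
        end = at - 1L - promoter$tss_offset + L,
        strand = s, score = sc[at], stringsAsFactors = FALSE
      )
    }
  }
  hits <- do.call(rbind, rows)
  prune_hits(hits)
}

#' Scan a whole promoter set with a panel of PWMs
#'
#' @param promoters list of `promoter_record`.
#' @param pwms list of `pwm`.
#' @inheritParams scan_promoter
#' @return one data.frame of hits across all genes and TFs.
#' @export
scan_dataset <- function(promoters, pwms, threshold = 0.8,
                         threshold_type = c("relative", "bits"),
                         background = rep(0.25, 4), pseudocount = 0.01) {
  threshold_type <- match.arg(threshold_type)
  out <- lapply(promoters, function(pr) {
    do.call(rbind, lapply(pwms, scan_promoter, promoter = pr,
                          threshold = threshold,
                          threshold_type = threshold_type,
                          background = background, pseudocount = pseudocount))
  })
  res <- do.call(rbind, out)
  if (is.null(res)) empty_hits() else res
}

#' Dataset-level Poisson enrichment of a TF's hits
#'
#' Upper-tail Poisson test of the dataset-wide hit total against the
#' expected background rate: `p = P(X >= total)` with
#' `X ~ Poisson(expected_rate * total_kb)`. The enrichment ratio is
#' observed / expected (0 when no hits).
#'
#' @param tf_id TF identifier (carried into the result).
#' @param hit_counts per-gene hit counts for this TF.
#' @param promoter_lengths per-gene promoter lengths in bp.
#' @param expected_rate expected background hits per kb (> 0).
#' @return list with tf_id, total, expected, enrichment_ratio, p_value.
#' @export
dataset_enrichment <- function(tf_id, hit_counts, promoter_lengths,
                               expected_rate) {
  if (expected_rate <= 0) stop("expected_rate must be > 0")
  if (any(hit_counts < 0)) stop("negative hit counts")
  total <- sum(hit_counts)
  lambda <- expected_rate * sum(promoter_lengths) / 1000
  p <- stats::ppois(total - 1, lambda, lower.tail = FALSE)
  list(tf_id = tf_id, total = total, expected = lambda,
       enrichment_ratio = if (total == 0) 0 else total / lambda,
       p_value = p)
}

#' Exact background hit rate of a PWM at a threshold
#'
#' Probability per window that an i.i.d. background sequence scores at or
#' above `threshold_bits`, computed exactly by dynamic-programming
#' convolution of the per-column score distribution (scores discretized to
#' 1e-3 bits), summed over both strands and expressed per kb (1000 windows
#' per strand per kb).
#'
#' @param x a `pwm`.
#' @param threshold_bits absolute score threshold in bits.
#' @inheritParams scoring_matrix
#' @return expected background hits per kb.
#' @export
pwm_background_rate <- function(x, threshold_bits,
                                background = rep(0.25, 4), pseudocount = 0.01) {
  m <- scoring_matrix(x, background, pseudocount)
  tail_prob <- function(mat) {
    vals <- 0
    probs <- 1
    for (j in seq_len(ncol(mat))) {
      v <- round(outer(vals, mat[1:4, j], "+"), 3)
      p <- outer(probs, background)
      agg <- rowsum(as.vector(p), group = as.vector(v))
      vals <- as.numeric(rownames(agg))
      probs <- agg[, 1]
    }
    # discretization guard: admit scores within half a grid step
    sum(probs[vals >= threshold_bits - 5e-4])
  }
  1000 * (tail_prob(m) + tail_prob(rc_scoring_matrix(m)))
}

#' Virtual main tools: the scanner at a ladder of thresholds
#'
#' Stand-ins for an ensemble of per-sequence motif-discovery programs: the
#' same log-odds scanner run at several relative-score thresholds, one tool
#' per threshold. These emulate the report *structure* of independent
#' per-sequence tools; they are not reproductions of any published program.
#'
#' @param promoters list of `promoter_record` (one species' dataset).
#' @param pwms list of `pwm`.
#' @param thresholds relative-score thresholds, one virtual tool each
#'   (default 0.75, 0.80, 0.85, 0.90, 0.95).
#' @inheritParams scoring_matrix
#' @param species species label carried on the reports.
#' @return list of main-class `tool_report` objects.
#' @export
virtual_main_reports <- function(promoters, pwms,
                                 thresholds = c(0.75, 0.80, 0.85, 0.90, 0.95),
                                 background = rep(0.25, 4), pseudocount = 0.01,
                                 species = "human") {
  lapply(seq_along(thresholds), function(i) {
    hits <- scan_dataset(promoters, pwms, thresholds[i], "relative",
                         background, pseudocount)
    tool_report(sprintf("scan%02.0f", 100 * thresholds[i]), "main",
                species = species, hits = hits)
  })
}

#' Virtual supportive tools: dataset-wide Poisson enrichment callers
#'
#' Stand-ins for programs that report enriched TFs over a whole dataset:
#' each virtual tool scans at its own relative threshold, compares every
#' TF's dataset-wide hit total against the exact background expectation
#' ([pwm_background_rate()]), and reports the TFs with Poisson upper-tail
#' p-value at or below `alpha`.
#'
#' @inheritParams virtual_main_reports
#' @param thresholds one relative threshold per virtual supportive tool
#'   (default 0.75, 0.80, 0.85, 0.90).
#' @param alpha enrichment significance level (default 0.05).
#' @return list of supportive-class `tool_report` objects.
#' @export
virtual_supportive_reports <- function(promoters, pwms,
                                       thresholds = c(0.75, 0.80, 0.85, 0.90),
                                       alpha = 0.05,
                                       background = rep(0.25, 4),
                                       pseudocount = 0.01,
                                       species = "human") {
  lens <- vapply(promoters, function(p) nchar(p$sequence), 0L)
  lapply(seq_along(thresholds), function(i) {
    hits <- scan_dataset(promoters, pwms, thresholds[i], "relative",
                         background, pseudocount)
    reported <- vapply(pwms, function(x) {
      thr_bits <- thresholds[i] * pwm_max_score(x, background, pseudocount)
      rate <- pwm_background_rate(x, thr_bits, background, pseudocount)
      cnt <- sum(hits$tf_id == x$tf_id)
      # a motif never seen in background (rate 0) is enriched iff seen at all
      if (rate <= 0) return(cnt > 0)
      enr <- dataset_enrichment(x$tf_id, cnt, lens, rate)
      enr$p_value <= alpha
    }, logical(1))
    tool_report(sprintf("enrich%02.0f", 100 * thresholds[i]), "supportive",
                species = species,
                reported_tfs = vapply(pwms, `[[`, "", "tf_id")[reported])
  })
}
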