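# Independent brute-force oracles used across the suite. These deliberately
# share no code with the package implementation: per-window loops, naive
# quadratic pruning, and direct rule evaluation.

BASES <- c("A", "C", "G", "T")

random_dna <- function(n, gc = 0.5) {
  paste(sample(BASES, n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

random_pwm <- function(tf_id, L = 8, conc = 0.5) {
  m <- matrix(stats::rgamma(4 * L, shape = conc), nrow = 4)
  m <- sweep(m, 2, colSums(m), "/")
  pwm(tf_id, m)
}

naive_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# per-window score, computed directly from the definition
naive_window_score <- function(x, window, background, pseudocount) {
  p <- x$probabilities + pseudocount
  p <- sweep(p, 2, colSums(p), "/")
  chars <- strsplit(window, "")[[1]]
  s <- 0
  for (j in seq_along(chars)) {
    if (chars[j] == "N") next
    s <- s + log2(p[chars[j], j] / background[match(chars[j], BASES)])
  }
  unname(s)
}

# quadratic greedy de-overlap under the stated priority
naive_prune <- function(hits) {
  kept <- hits[0, , drop = FALSE]
  pool <- hits
  while (nrow(pool) > 0) {
    pri <- order(-pool$score, pool$start, ifelse(pool$strand == "+", 0, 1))
    best <- pool[pri[1], , drop = FALSE]
    overlap <- pool$start < best$end & pool$end > best$start
    kept <- rbind(kept, best)
    pool <- pool[!overlap, , drop = FALSE]
  }
  kept[order(kept$start, ifelse(kept$strand == "+", 0, 1)), , drop = FALSE]
}

# exhaustive both-strand enumeration at an absolute bit threshold, followed
# by the same greedy rule; minus-strand windows are scored on their reverse
# complement read against the forward model (per-window loops, no shared
# code with the vectorized scanner)
naive_scan <- function(x, promoter, thr_bits, background, pseudocount) {
  p <- x$probabilities + pseudocount
  p <- sweep(p, 2, colSums(p), "/")
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  chars <- strsplit(promoter$sequence, "")[[1]]
  L <- pwm_length(x)
  n <- length(chars)
  rows <- list()
  if (n >= L) {
    for (s0 in 0:(n - L)) {
      w <- chars[(s0 + 1):(s0 + L)]
      for (strand in c("+", "-")) {
        ww <- if (strand == "+") w else rev(unname(comp[w]))
        keep <- ww != "N"
        ri <- match(ww[keep], BASES)
        sc <- sum(log2(p[cbind(ri, which(keep))] / background[ri]))
        if (sc >= thr_bits) {
          rows[[length(rows) + 1]] <- data.frame(
            gene_id = promoter$gene_id, tf_id = x$tf_id,
            start = s0 - promoter$tss_offset,
            end = s0 - promoter$tss_offset + L,
            strand = strand, score = sc, stringsAsFactors = FALSE)
        }
      }
    }
  }
  hits <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(), tf_id = character(), start = integer(),
               end = integer(), strand = character(), score = numeric())
  naive_prune(hits)
}

# direct evaluation of the two-condition collection rule for one pair
naive_accept <- function(gene, tf, reports, min_main, min_supportive) {
  n_main <- 0
  n_supp <- 0
  for (r in reports) {
    if (r$tool_class == "main") {
      found <- FALSE
      for (i in seq_len(nrow(r$hits))) {
        if (r$hits$gene_id[i] == gene && r$hits$tf_id[i] == tf) found <- TRUE
      }
      if (found) n_main <- n_main + 1
    } else {
      if (tf %in% r$reported_tfs) n_supp <- n_supp + 1
    }
  }
  n_main >= min_main && n_supp >= min_supportive
}

# a small randomized report panel over given genes/tfs
random_reports <- function(genes, tfs, n_main = 5, n_supportive = 4,
                           p_hit = 0.5, p_supp = 0.5) {
  mains <- lapply(seq_len(n_main), function(i) {
    grid <- expand.grid(gene_id = genes, tf_id = tfs,
                        stringsAsFactors = FALSE)
    grid <- grid[stats::runif(nrow(grid)) < p_hit, , drop = FALSE]
    k <- nrow(grid)
    tool_report(sprintf("m%d", i), "main", hits = data.frame(
      gene_id = grid$gene_id, tf_id = grid$tf_id,
      start = sample(-50:50, k, replace = TRUE), end = 0L,
      strand = sample(c("+", "-"), k, replace = TRUE),
      score = round(stats::runif(k, 5, 15), 2), stringsAsFactors = FALSE
    ) |> transform(end = start + 8L))
  })
  supps <- lapply(seq_len(n_supportive), function(i) {
    tool_report(sprintf("s%d", i), "supportive",
                reported_tfs = tfs[stats::runif(length(tfs)) < p_supp])
  })
  c(mains, supps)
}

# smallest promoter record wrapper for scanner tests
mk_promoter <- function(seq, tss = 0L, gene_id = "g1") {
  promoter_record(gene_id, "human", seq, tss, "+")
}
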