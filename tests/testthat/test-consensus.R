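test_that("the two-condition rule accepts and rejects as stated", {
  genes <- "g1"
  tf <- "tfA"
  mk_main <- function(id, has) {
    tool_report(id, "main", hits = if (has) {
      data.frame(gene_id = "g1", tf_id = "tfA", start = 0L, end = 8L,
                 strand = "+", score = 10, stringsAsFactors = FALSE)
    } else {
      data.frame(gene_id = character(), tf_id = character(),
                 start = integer(), end = integer(), strand = character(),
                 score = numeric())
    })
  }
  mk_supp <- function(id, has) {
    tool_report(id, "supportive", reported_tfs = if (has) "tfA" else character())
  }

  # 5/5 main + 2/4 supportive: accepted
  reps <- c(lapply(1:5, function(i) mk_main(paste0("m", i), TRUE)),
            lapply(1:4, function(i) mk_supp(paste0("s", i), i <= 2)))
  expect_true(accept_motif("g1", "tfA", reps))

  # 4/5 main fails unanimity
  reps2 <- c(lapply(1:5, function(i) mk_main(paste0("m", i), i <= 4)),
             lapply(1:4, function(i) mk_supp(paste0("s", i), TRUE)))
  expect_false(accept_motif("g1", "tfA", reps2))
  expect_true(accept_motif("g1", "tfA", reps2, min_main = 4))

  # 5/5 main but no supportive corroboration fails
  reps3 <- c(lapply(1:5, function(i) mk_main(paste0("m", i), TRUE)),
             lapply(1:4, function(i) mk_supp(paste0("s", i), FALSE)))
  expect_false(accept_motif("g1", "tfA", reps3))
  expect_true(accept_motif("g1", "tfA", reps3, min_supportive = 0))

  expect_error(accept_motif("gX", "tfA", reps, genes = genes), "unknown gene")
  expect_error(accept_motif("g1", "tfB", reps, tfs = tf), "unknown TF")
})

test_that("accepted_pairs equals brute-force rule evaluation and is
          monotone in both thresholds", {
  withr::local_seed(71)
  genes <- sprintf("g%d", 1:4)
  tfs <- sprintf("tf%d", 1:3)
  for (rep_i in 1:5) {
    reports <- random_reports(genes, tfs, p_hit = 0.6, p_supp = 0.4)
    for (mm in c(3, 5)) {
      for (ms in 0:2) {
        got <- accepted_pairs(reports, mm, ms)
        want <- expand.grid(gene_id = genes, tf_id = tfs,
                            stringsAsFactors = FALSE)
        ok <- mapply(function(g, t) naive_accept(g, t, reports, mm, ms),
                     want$gene_id, want$tf_id)
        want <- want[ok, ]
        expect_setequal(paste(got$gene_id, got$tf_id),
                        paste(want$gene_id, want$tf_id))
      }
    }
    # relaxing either condition never shrinks the accepted set
    strict <- accepted_pairs(reports, 5, 2)
    loose_main <- accepted_pairs(reports, 4, 2)
    loose_supp <- accepted_pairs(reports, 5, 1)
    key <- function(d) paste(d$gene_id, d$tf_id)
    expect_true(all(key(strict) %in% key(loose_main)))
    expect_true(all(key(strict) %in% key(loose_supp)))
  }
})

test_that("pooled and consensus-site counting differ exactly as defined", {
  # five tools all reporting the same single site
  site <- data.frame(gene_id = "g1", tf_id = "tfA", start = -100L,
                     end = -92L, strand = "+", score = 10,
                     stringsAsFactors = FALSE)
  reports <- c(lapply(1:5, function(i)
    tool_report(paste0("m", i), "main", hits = site)),
    list(tool_report("s1", "supportive", reported_tfs = "tfA")))
  acc <- accepted_pairs(reports)
  pooled <- build_count_matrix(reports, acc, "pooled")
  sites <- build_count_matrix(reports, acc, "consensus_sites")
  expect_identical(pooled["g1", "tfA"], 5L)
  expect_identical(sites["g1", "tfA"], 1L)
  expect_identical(attr(pooled, "provenance"), "pooled")

  # no accepted pairs: an all-zero matrix over the observed ids
  zero <- build_count_matrix(reports, acc[0, ], "pooled")
  expect_true(all(zero == 0))
  expect_error(build_count_matrix(list(), acc, "pooled"), "empty report")
})

test_that("pooled counts equal an independent recount from the raw table", {
  withr::local_seed(83)
  genes <- sprintf("g%d", 1:3)
  tfs <- c("tfA", "tfB")
  reports <- random_reports(genes, tfs, p_hit = 0.7, p_supp = 0.6)
  acc <- accepted_pairs(reports, min_main = 3, min_supportive = 1)
  m <- build_count_matrix(reports, acc, "pooled", min_main = 3)

  # recount from the serialized TSV rows, de-overlapping per tool by hand
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_tool_reports(reports, tsv)
  raw <- read.table(tsv, sep = "\t", header = TRUE,
                    colClasses = "character")
  raw <- raw[raw$tool_class == "main", ]
  key <- paste(acc$gene_id, acc$tf_id)
  for (g in rownames(m)) {
    for (tf in colnames(m)) {
      if (!paste(g, tf) %in% key) {
        expect_identical(m[g, tf], 0L)
        next
      }
      total <- 0
      for (tool in unique(raw$tool)) {
        sub <- raw[raw$tool == tool & raw$gene == g & raw$tf == tf, ]
        if (nrow(sub) == 0) next
        d <- data.frame(start = as.integer(sub$start),
                        end = as.integer(sub$end), strand = sub$strand,
                        score = as.numeric(sub$score))
        total <- total + nrow(naive_prune(d))
      }
      expect_identical(m[g, tf], as.integer(total))
    }
  }
})

test_that("a single main tool with min_main 1 reproduces its own counts", {
  hits <- data.frame(gene_id = c("g1", "g1", "g2"),
                     tf_id = c("tfA", "tfA", "tfA"),
                     start = c(0L, 20L, 5L), end = c(8L, 28L, 13L),
                     strand = "+", score = c(9, 8, 7),
                     stringsAsFactors = FALSE)
  reports <- list(tool_report("solo", "main", hits = hits))
  acc <- accepted_pairs(reports, min_main = 1, min_supportive = 0)
  m <- build_count_matrix(reports, acc, "pooled", min_main = 1)
  expect_identical(m["g1", "tfA"], 2L)
  expect_identical(m["g2", "tfA"], 1L)
})

test_that("tool reports round-trip through the TSV interchange", {
  withr::local_seed(97)
  reports <- random_reports(c("g1", "g2"), c("tfA", "tfB"), n_main = 2,
                            n_supportive = 2, p_hit = 0.8, p_supp = 0.9)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_tool_reports(reports, tsv)
  back <- read_tool_reports(tsv)
  nonempty <- Filter(function(r) {
    (r$tool_class == "main" && nrow(r$hits) > 0) ||
      (r$tool_class == "supportive" && length(r$reported_tfs) > 0)
  }, reports)
  expect_length(back, length(nonempty))
  for (i in seq_along(back)) {
    expect_identical(back[[i]]$tool_id, nonempty[[i]]$tool_id)
    if (back[[i]]$tool_class == "main") {
      a <- back[[i]]$hits
      b <- nonempty[[i]]$hits
      rownames(a) <- rownames(b) <- NULL
      expect_equal(a, b)
    } else {
      expect_setequal(back[[i]]$reported_tfs, nonempty[[i]]$reported_tfs)
    }
  }
})
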