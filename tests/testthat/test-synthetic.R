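small_config <- function(...) {
  defaults <- list(n_genes = 6, promoter_up = 300, promoter_down = 50,
                   n_tfs = 4, pwm_length = 8, pwm_info_bits = 1.8,
                   ortholog_fraction = 0.5, substitution_rate = 0.1,
                   tool_sensitivities = rep(0.9, 5), tool_fp_rate = 0.2)
  args <- utils::modifyList(defaults, list(...))
  do.call(simulation_config, args)
}

test_that("promoter generation honours the planting table exactly", {
  # empty planting: pure background, empty truth
  cfg0 <- small_config(planting_table = NULL, seed = 5)
  out0 <- generate_promoter_set(cfg0)
  expect_identical(nrow(out0$truth), 0L)
  expect_length(out0$promoters, 6 + 3)  # 6 human + 3 orthologs
  expect_true(all(vapply(out0$promoters, function(p)
    nchar(p$sequence), 0L) == 350L))

  # seven copies of one TF in one gene, recorded one row per copy
  cfg7 <- small_config(planting_table = list(G01 = c(TF01 = 7L)), seed = 5)
  out7 <- generate_promoter_set(cfg7)
  human_truth <- out7$truth[out7$truth$gene_id == "G01", ]
  expect_identical(nrow(human_truth), 7L)
  expect_identical(unique(human_truth$tf_id), "TF01")
  # planted intervals lie inside the promoter and do not overlap
  expect_true(all(human_truth$start >= -300 & human_truth$start + 8 <= 50))
  s <- sort(human_truth$start)
  expect_true(all(diff(s) >= 8))

  # total plantings equal the planting-table sum (human side)
  cfg <- small_config(planting_table = list(G01 = c(TF01 = 2L, TF02 = 1L),
                                            G03 = c(TF02 = 3L)), seed = 2)
  out <- generate_promoter_set(cfg)
  hum <- out$truth[!grepl("m$", out$truth$gene_id), ]
  expect_identical(nrow(hum), 6L)
  expect_identical(sum(hum$tf_id == "TF02"), 4L)

  expect_error(generate_promoter_set(
    small_config(planting_table = list(G99 = c(TF01 = 1L)), seed = 1)),
    "unknown genes")
  expect_error(generate_promoter_set(
    small_config(planting_table = list(G01 = c(TF99 = 1L)), seed = 1)),
    "unknown TFs")
})

test_that("mouse orthologs diverge by substitution but conserve the sites", {
  # zero substitution: mouse sequence identical to the human partner
  cfg <- small_config(planting_table = list(G01 = c(TF01 = 3L)),
                      substitution_rate = 0, seed = 9)
  out <- generate_promoter_set(cfg)
  by_id <- setNames(out$promoters,
                    vapply(out$promoters, `[[`, "", "gene_id"))
  expect_identical(by_id$G01m$sequence, by_id$G01$sequence)
  expect_identical(by_id$G01m$ortholog_id, "G01")
  expect_identical(by_id$G01$ortholog_id, "G01m")
  expect_identical(by_id$G01m$module_label, by_id$G01$module_label)

  # positive substitution: background diverges, planted windows do not
  cfg2 <- small_config(planting_table = list(G01 = c(TF01 = 3L)),
                       substitution_rate = 0.3, seed = 9)
  out2 <- generate_promoter_set(cfg2)
  by_id2 <- setNames(out2$promoters,
                     vapply(out2$promoters, `[[`, "", "gene_id"))
  h <- strsplit(by_id2$G01$sequence, "")[[1]]
  m <- strsplit(by_id2$G01m$sequence, "")[[1]]
  expect_gt(sum(h != m), 20)  # ~0.3 * 350 background positions differ
  gt <- out2$truth[out2$truth$gene_id == "G01", ]
  for (i in seq_len(nrow(gt))) {
    at <- gt$start[i] + 300  # back to 0-based promoter coordinates
    expect_identical(m[(at + 1):(at + 8)], h[(at + 1):(at + 8)])
  }
  # mouse truth mirrors the human plantings
  expect_identical(nrow(out2$truth[out2$truth$gene_id == "G01m", ]), 3L)
})

test_that("generators are bit-identical under a fixed seed", {
  cfg <- small_config(planting_table = list(G02 = c(TF03 = 2L)), seed = 123)
  a <- generate_promoter_set(cfg)
  b <- generate_promoter_set(cfg)
  expect_identical(a, b)
  ra <- simulate_tool_reports(a$promoters, a$truth, cfg)
  rb <- simulate_tool_reports(b$promoters, b$truth, cfg)
  expect_identical(ra, rb)
})

test_that("the noiseless channel reproduces ground truth exactly", {
  cfg <- small_config(planting_table = list(G01 = c(TF01 = 2L),
                                            G02 = c(TF02 = 1L)),
                      tool_sensitivities = rep(1, 5), tool_fp_rate = 0,
                      supportive_fp_prob = 0, seed = 21)
  out <- generate_promoter_set(cfg)
  reports <- simulate_tool_reports(out$promoters, out$truth, cfg)
  mains <- Filter(function(r) r$tool_class == "main", reports)
  expect_length(mains, 10)  # 5 per species
  for (r in mains) {
    sp_truth <- out$truth[grepl("m$", out$truth$gene_id) ==
                            (r$species == "mouse"), ]
    expect_setequal(paste(r$hits$gene_id, r$hits$tf_id, r$hits$start),
                    paste(sp_truth$gene_id, sp_truth$tf_id, sp_truth$start))
  }
  # every supportive tool with threshold 0 lists every planted TF
  supp1 <- Filter(function(r) r$tool_id == "supp1", reports)
  for (r in supp1) {
    expect_setequal(r$reported_tfs, unique(out$truth$tf_id))
  }
})

test_that("a dead channel reports nothing", {
  cfg <- small_config(planting_table = list(G01 = c(TF01 = 2L)),
                      tool_sensitivities = rep(0, 5), tool_fp_rate = 0,
                      supportive_fp_prob = 0, seed = 22)
  out <- generate_promoter_set(cfg)
  reports <- simulate_tool_reports(out$promoters, out$truth, cfg)
  for (r in Filter(function(r) r$tool_class == "main", reports)) {
    expect_identical(nrow(r$hits), 0L)
  }
})

test_that("detection frequency sits inside the exact binomial band", {
  # 1000 independent plantings at sensitivity 0.8: the recovered count
  # must fall between the 0.5% and 99.5% binomial quantiles
  planting <- setNames(
    lapply(1:50, function(i) c(TF01 = 10L, TF02 = 10L)),
    sprintf("G%02d", 1:50))
  cfg <- simulation_config(n_genes = 50, promoter_up = 2000,
                           promoter_down = 500, n_tfs = 2, pwm_length = 8,
                           planting_table = planting, ortholog_fraction = 0,
                           tool_sensitivities = rep(0.8, 5), tool_fp_rate = 0,
                           seed = 77)
  out <- generate_promoter_set(cfg)
  expect_identical(nrow(out$truth), 1000L)
  reports <- simulate_tool_reports(out$promoters, out$truth, cfg)
  main1 <- Filter(function(r) r$tool_id == "main1", reports)[[1]]
  lo <- qbinom(0.005, 1000, 0.8)
  hi <- qbinom(0.995, 1000, 0.8)
  expect_gte(nrow(main1$hits), lo)
  expect_lte(nrow(main1$hits), hi)
})

test_that("configuration invariants are enforced", {
  expect_error(small_config(gc_content = 1.2), "\\[0, 1\\]")
  expect_error(small_config(tool_sensitivities = rep(0.5, 3)), "length")
  expect_error(simulation_config(promoter_up = 4, promoter_down = 4,
                                 pwm_length = 10), "longer than the motif")
  expect_error(small_config(planting_table = list(G01 = c(TF01 = -1))),
               "non-negative")
})
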