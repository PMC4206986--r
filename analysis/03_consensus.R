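#!/usr/bin/env Rscript

# Stage 3: apply the two-condition collection rule — a motif is accepted
# for a gene only when all five main tools identify it there and at least
# one supportive tool corroborates the TF — and build, per species, the
# gene x TF count matrices in both counting modes (pooled per-tool totals,
# the convention behind the dataset mean; and consensus sites, the
# discrete-occurrence convention).

suppressPackageStartupMessages(library(motifzone))

out <- "results/consensus"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

reports <- read_tool_reports("results/reports/tool_reports.tsv")
species <- vapply(reports, `[[`, "", "species")

for (sp in unique(species)) {
  reps <- reports[species == sp]
  acc <- accepted_pairs(reps)
  pooled <- build_count_matrix(reps, acc, "pooled")
  sites <- build_count_matrix(reps, acc, "consensus_sites")
  write_count_matrix(pooled, file.path(out, sprintf("counts_pooled_%s.tsv", sp)))
  write_count_matrix(sites, file.path(out, sprintf("counts_sites_%s.tsv", sp)))
  write_count_matrix(pooled, file.path(out, sprintf("counts_pooled_%s_long.tsv", sp)),
                     long = TRUE)
  cat(sprintf("%s: %d accepted (gene, TF) pairs; %d pooled motifs, %d consensus sites over %d genes x %d TFs\n",
              sp, nrow(acc), sum(pooled), sum(sites), nrow(pooled),
              ncol(pooled)))
}
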