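#!/usr/bin/env Rscript

# Stage 4: threshold and select. The gene threshold is the dataset mean of
# accepted motifs per gene (pooled counts); genes strictly above its floor
# are the co-regulated set. TFs seen in those genes are ranked by gene
# coverage, then total occurrences, and the top 40% are kept. The
# selected-genes x selected-TFs submatrix is the intersection zone.

suppressPackageStartupMessages(library(motifzone))

out <- "results/selection"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

for (sp in c("human", "mouse")) {
  counts <- read_count_matrix(
    sprintf("results/consensus/counts_pooled_%s.tsv", sp))
  th <- compute_gene_threshold(counts)
  genes <- select_genes(counts, th)
  cat(sprintf("%s: mean %.2f (SD %.2f) motifs/gene, cutoff %d -> %d of %d genes selected\n",
              sp, th$gene_mean, th$gene_sd, th$gene_int_cutoff,
              length(genes), th$n_genes))
  if (length(genes) == 0) next
  ranking <- rank_tfs(counts, genes)
  tfs <- select_top_tfs(ranking, tf_top_fraction = 0.40)
  zone <- build_intersection_zone(counts, genes, tfs)
  write.table(ranking, file.path(out, sprintf("tf_ranking_%s.tsv", sp)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_zone(zone, th, file.path(out, sprintf("zone_%s.tsv", sp)),
             file.path(out, sprintf("zone_summary_%s.json", sp)))
  cat(sprintf("%s: top %d of %d candidate TFs -> %dx%d intersection zone; min TF coverage %d/%d genes\n",
              sp, length(tfs), nrow(ranking), length(genes), length(tfs),
              min(zone$tf_coverage), length(genes)))
}
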