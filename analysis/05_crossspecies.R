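#!/usr/bin/env Rscript

# Stage 5: cross-species intersection and TF classification. Human and
# mouse zone TF lists are intersected (case-insensitive symbol identity);
# every human zone TF is classified by pathway scope (process-specific vs
# pathway-ubiquitous, from the modules of the genes it hits), high
# affinity (more than three consensus sites in one promoter), conservation,
# and literature direction where annotated.

suppressPackageStartupMessages(library(motifzone))

out <- "results/crossspecies"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

read_zone <- function(sp) {
  counts <- read_count_matrix(sprintf("results/selection/zone_%s.tsv", sp))
  summ <- jsonlite::read_json(
    sprintf("results/selection/zone_summary_%s.json", sp),
    simplifyVector = TRUE)
  full <- read_count_matrix(
    sprintf("results/consensus/counts_pooled_%s.tsv", sp))
  build_intersection_zone(full, summ$selected_genes, summ$selected_tfs)
}

hz <- read_zone("human")
mz <- read_zone("mouse")
conserved <- conserved_tfs(hz, mz)
writeLines(conserved, file.path(out, "conserved_tfs.txt"))
cat(sprintf("%d of %d human zone TFs conserved in the mouse zone: %s\n",
            length(conserved), length(hz$tfs),
            paste(conserved, collapse = " ")))

# module labels from the simulated metadata; site counts for affinity
meta <- read.table("results/data/promoters.tsv", sep = "\t", header = TRUE,
                   colClasses = "character")
modules <- setNames(meta$module_label, meta$gene_id)
site_counts <- read_count_matrix("results/consensus/counts_sites_human.tsv")

cls <- classify_tfs(hz, site_counts, modules, conserved = conserved)
write.table(cls, file.path(out, "classification.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("classification: %d process-specific, %d pathway-ubiquitous, %d high-affinity\n",
            sum(cls$scope == "process-specific"),
            sum(cls$scope == "pathway-ubiquitous"),
            sum(cls$high_affinity)))
print(cls[, c("tf_id", "scope", "n_modules", "high_affinity", "conserved")])
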