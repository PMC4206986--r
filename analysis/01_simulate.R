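#!/usr/bin/env Rscript

# Stage 1: build the synthetic study dataset — 49 human promoters
# (-5000/+500 around the TSS) with 43 mouse orthologs, 30 TF motif models,
# and a tiered planting of binding sites (a few ubiquitous factors, one of
# them with a seven-copy promoter; many mid-frequency and rare factors).
# Writes the promoter FASTA/TSV, the JASPAR motif file, and the planted
# ground truth under results/data/.

suppressPackageStartupMessages(library(motifzone))

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 1234

cfg <- study_shape_config(seed = seed)
sim <- generate_promoter_set(cfg)

write_promoter_set(sim$promoters, file.path(out, "promoters.fasta"),
                   file.path(out, "promoters.tsv"))
write_promoter_bed(sim$promoters, file.path(out, "promoters.bed"))
write_jaspar(sim$pwms, file.path(out, "pwms.jaspar"))
write.table(sim$truth, file.path(out, "ground_truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
# stages 2+ rebuild the same config deterministically from this seed
writeLines(as.character(seed), file.path(out, "seed.txt"))

species <- vapply(sim$promoters, `[[`, "", "species")
cat(sprintf("dataset: %d human + %d mouse promoters, %d planted sites, %d TFs\n",
            sum(species == "human"), sum(species == "mouse"),
            nrow(sim$truth), length(sim$pwms)))
copies <- with(sim$truth[!grepl("m$", sim$truth$gene_id), ],
               tapply(copy, list(gene_id, tf_id), max))
cat(sprintf("max planted copies in one promoter: %d (%s)\n",
            max(copies, na.rm = TRUE),
            paste(rownames(which(copies == max(copies, na.rm = TRUE),
                                 arr.ind = TRUE)), collapse = ", ")))
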