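#' Promoter record
#'
#' One gene's TSS-anchored promoter window, already oriented 5'->3' along
#' the gene. Coordinates are 0-based, half-open throughout; `tss_offset` is
#' the index of the TSS (first transcribed base) within `sequence`.
#'
#' @param gene_id character scalar.
#' @param species `"human"` or `"mouse"`.
#' @param sequence DNA string over A/C/G/T/N.
#' @param tss_offset integer in `[0, nchar(sequence)]`.
#' @param strand `"+"` or `"-"` (strand of the gene on its source contig).
#' @param ortholog_id gene id of the orthologous partner, or `NA`.
#' @param module_label pathway-module annotation, or `NA`.
#' @return an object of class `promoter_record`.
#' @export
promoter_record <- function(gene_id, species, sequence, tss_offset,
                            strand = "+", ortholog_id = NA_character_,
                            module_label = NA_character_) {
  sequence <- toupper(sequence)
  if (grepl("[^ACGTN]", sequence)) {
    stop("promoter sequence for ", gene_id,
         " contains characters outside {A,C,G,T,N}")
  }
  if (!species %in% c("human", "mouse")) stop("species must be 'human' or 'mouse'")
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  tss_offset <- as.integer(tss_offset)
  if (tss_offset < 0 || tss_offset > nchar(sequence)) {
    stop("tss_offset out of range for ", gene_id)
  }
  structure(
    list(gene_id = as.character(gene_id), species = species,
         sequence = sequence, tss_offset = tss_offset, strand = strand,
         ortholog_id = as.character(ortholog_id),
         module_label = as.character(module_label)),
    class = "promoter_record"
  )
}

#' @export
print.promoter_record <- function(x, ...) {
  cat(sprintf("<promoter_record> %s [%s, %s] %d bp, TSS at %d, module %s\n",
              x$gene_id, x$species, x$strand, nchar(x$sequence),
              x$tss_offset, x$module_label))
  invisible(x)
}

#' Extract a TSS-anchored promoter window from a contig
#'
#' For a + strand gene the window is the half-open contig interval
#' `[tss - up, tss + down)`; for a - strand gene it is the reverse
#' complement of `[tss - down, tss + up)`, so the returned sequence always
#' reads 5'->3' along the gene with upstream sequence first. Windows are
#' clipped at the contig ends (no error) and `tss_offset` adjusted.
#'
#' @param contig_sequence contig DNA string.
#' @param tss 0-based contig position of the TSS.
#' @param strand `"+"` or `"-"`.
#' @param up,down bp upstream / downstream of the TSS (defaults 5000 / 500).
#' @param gene_id,species,ortholog_id,module_label metadata passed through.
#' @return a `promoter_record` of length at most `up + down`.
#' @export
extract_promoter <- function(contig_sequence, tss, strand = "+",
                             up = 5000, down = 500,
                             gene_id = "gene", species = "human",
                             ortholog_id = NA_character_,
                             module_label = NA_character_) {
  n <- nchar(contig_sequence)
  if (tss < 0 || tss >= n) stop("tss ", tss, " outside contig [0, ", n, ")")
  if (up < 0 || down < 0) stop("up and down must be >= 0")
  if (strand == "+") {
    from <- max(0L, as.integer(tss - up))
    to <- min(n, as.integer(tss + down))
    seq <- substr(contig_sequence, from + 1L, to)
    offset <- tss - from
  } else {
    from <- max(0L, as.integer(tss - down))
    to <- min(n, as.integer(tss + up))
    seq <- revcomp(substr(contig_sequence, from + 1L, to))
    # TSS base maps to oriented index (to - 1 - tss)
    offset <- to - 1L - as.integer(tss)
  }
  promoter_record(gene_id, species, seq, offset, strand,
                  ortholog_id, module_label)
}

#' Write a promoter set as FASTA plus a metadata TSV
#'
#' FASTA headers follow `>geneID|species|TSS=<int>|strand=<+/->`; the TSV
#' carries columns gene_id, species, tss, strand, ortholog_id, module_label.
#'
#' @param promoters list of `promoter_record`.
#' @param fasta_path,metadata_tsv_path output paths.
#' @return invisibly, a list of the two paths.
#' @export
write_promoter_set <- function(promoters, fasta_path, metadata_tsv_path) {
  seqs <- Biostrings::DNAStringSet(vapply(promoters, `[[`, "", "sequence"))
  names(seqs) <- vapply(promoters, function(p) {
    sprintf("%s|%s|TSS=%d|strand=%s", p$gene_id, p$species, p$tss_offset, p$strand)
  }, "")
  Biostrings::writeXStringSet(seqs, fasta_path)
  meta <- data.frame(
    gene_id = vapply(promoters, `[[`, "", "gene_id"),
    species = vapply(promoters, `[[`, "", "species"),
    tss = vapply(promoters, function(p) p$tss_offset, 0L),
    strand = vapply(promoters, `[[`, "", "strand"),
    ortholog_id = vapply(promoters, `[[`, "", "ortholog_id"),
    module_label = vapply(promoters, `[[`, "", "module_label"),
    stringsAsFactors = FALSE
  )
  utils::write.table(meta, metadata_tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(list(fasta = fasta_path, metadata = metadata_tsv_path))
}

#' Read a promoter set from FASTA plus metadata TSV
#'
#' Records are joined on gene_id; every FASTA record must have exactly one
#' metadata row and vice versa.
#'
#' @param fasta_path,metadata_tsv_path input paths.
#' @return list of `promoter_record` in FASTA order.
#' @export
read_promoter_set <- function(fasta_path, metadata_tsv_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  meta <- utils::read.table(metadata_tsv_path, sep = "\t", header = TRUE,
                            colClasses = "character", fill = FALSE)
  needed <- c("gene_id", "species", "tss", "strand", "ortholog_id", "module_label")
  if (!all(needed %in% names(meta))) {
    stop("metadata TSV is missing columns: ",
         paste(setdiff(needed, names(meta)), collapse = ", "))
  }
  if (anyDuplicated(meta$gene_id)) {
    stop("duplicate gene_id in metadata: ",
         paste(unique(meta$gene_id[duplicated(meta$gene_id)]), collapse = ", "))
  }
  ids <- vapply(strsplit(names(seqs), "|", fixed = TRUE), `[[`, "", 1)
  if (anyDuplicated(ids)) {
    stop("duplicate gene_id in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  orphan <- setdiff(ids, meta$gene_id)
  if (length(orphan)) {
    stop("FASTA records with no metadata row: ", paste(orphan, collapse = ", "))
  }
  widow <- setdiff(meta$gene_id, ids)
  if (length(widow)) {
    stop("metadata rows with no FASTA record: ", paste(widow, collapse = ", "))
  }
  meta <- meta[match(ids, meta$gene_id), ]
  mapply(function(seq, i) {
    promoter_record(meta$gene_id[i], meta$species[i], seq,
                    as.integer(meta$tss[i]), meta$strand[i],
                    ifelse(meta$ortholog_id[i] %in% c("", "NA"),
                           NA_character_, meta$ortholog_id[i]),
                    ifelse(meta$module_label[i] %in% c("", "NA"),
                           NA_character_, meta$module_label[i]))
  }, as.character(seqs), seq_along(ids), SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Export promoter windows as BED
#'
#' One interval per promoter in promoter-local coordinates (0-based,
#' half-open), with the TSS position in the thickStart/thickEnd columns.
#'
#' @param promoters list of `promoter_record`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_promoter_bed <- function(promoters, path) {
  bed <- data.frame(
    chrom = vapply(promoters, `[[`, "", "gene_id"),
    start = 0L,
    end = vapply(promoters, function(p) nchar(p$sequence), 0L),
    name = vapply(promoters, function(p)
      paste0(p$gene_id, "_promoter"), ""),
    score = 0L,
    strand = vapply(promoters, `[[`, "", "strand"),
    thickStart = vapply(promoters, function(p) p$tss_offset, 0L),
    thickEnd = vapply(promoters, function(p)
      min(p$tss_offset + 1L, nchar(p$sequence)), 0L),
    stringsAsFactors = FALSE
  )
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
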