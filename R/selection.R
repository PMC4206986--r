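#' Gene threshold from a count matrix
#'
#' The mean number of accepted motifs per gene over the whole dataset:
#' total counts divided by the number of genes, reported to 2 decimals
#' (half-up). Genes are later selected when their total strictly exceeds
#' the integer cutoff `floor(mean)`. The spread is reported as the standard
#' deviation of the per-gene totals — population (divide by N) by default,
#' since the dataset is the whole study population, with a sample
#' (N - 1) option.
#'
#' @param counts gene x TF count matrix.
#' @param sd_mode `"population"` (default) or `"sample"`.
#' @return an object of class `selection_thresholds`: gene_mean (2 dp),
#'   gene_mean_raw, gene_sd (2 dp), gene_int_cutoff, n_genes, total.
#' @export
compute_gene_threshold <- function(counts, sd_mode = c("population", "sample")) {
  sd_mode <- match.arg(sd_mode)
  if (is.null(dim(counts)) || nrow(counts) < 1) {
    stop("count matrix must have at least one gene")
  }
  totals <- rowSums(counts)
  n <- nrow(counts)
  mean_raw <- sum(totals) / n
  dev2 <- sum((totals - mean_raw)^2)
  sd_raw <- sqrt(dev2 / if (sd_mode == "population") n else max(1, n - 1))
  structure(
    list(gene_mean = round_half_up(mean_raw, 2), gene_mean_raw = mean_raw,
         gene_sd = round_half_up(sd_raw, 2), gene_sd_mode = sd_mode,
         gene_int_cutoff = as.integer(floor(mean_raw)),
         n_genes = n, total = sum(totals)),
    class = "selection_thresholds"
  )
}

#' @export
print.selection_thresholds <- function(x, ...) {
  cat(sprintf(
    "<selection_thresholds> %d motifs over %d genes: mean %.2f (SD +/- %.2f, %s), integer cutoff %d\n",
    x$total, x$n_genes, x$gene_mean, x$gene_sd, x$gene_sd_mode,
    x$gene_int_cutoff))
  invisible(x)
}

#' Select co-regulated genes above the gene threshold
#'
#' Genes whose per-gene accepted-motif total strictly exceeds the integer
#' cutoff ("more than" the floored mean), sorted by descending total then
#' gene id.
#'
#' @param counts gene x TF count matrix.
#' @param thresholds a `selection_thresholds` from [compute_gene_threshold()].
#' @return character vector of selected gene ids (possibly empty).
#' @export
select_genes <- function(counts, thresholds) {
  totals <- rowSums(counts)
  sel <- totals > thresholds$gene_int_cutoff
  ids <- rownames(counts)[sel]
  ids[order(-totals[sel], ids)]
}

#' Rank TFs over the selected genes
#'
#' Candidate TFs are those with at least one accepted count in a selected
#' gene, ranked by descending number of selected genes hit, then descending
#' total occurrences, then TF id (documented tie-break).
#'
#' @param counts gene x TF count matrix.
#' @param selected_genes non-empty character vector of selected gene ids.
#' @return data.frame (tf_id, n_genes_hit, total_occurrences) in rank order.
#' @export
rank_tfs <- function(counts, selected_genes) {
  if (length(selected_genes) == 0) stop("selected_genes must be non-empty")
  if (length(setdiff(selected_genes, rownames(counts)))) {
    stop("selected gene absent from count matrix: ",
         paste(setdiff(selected_genes, rownames(counts)), collapse = ", "))
  }
  sub <- counts[selected_genes, , drop = FALSE]
  cover <- colSums(sub > 0)
  totals <- colSums(sub)
  keep <- cover > 0
  df <- data.frame(tf_id = colnames(counts)[keep],
                   n_genes_hit = as.integer(cover[keep]),
                   total_occurrences = as.integer(totals[keep]),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$n_genes_hit, -df$total_occurrences, df$tf_id), ,
           drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Select the top fraction of ranked TFs
#'
#' The TF threshold: the first `tf_top_k` factors of the ranking, with
#' `tf_top_k = floor(tf_top_fraction * n_candidates)` when derived from the
#' fraction (61 candidates at 0.40 give 24).
#'
#' @param ranked data.frame from [rank_tfs()].
#' @param tf_top_fraction fraction of the candidate list (default 0.40).
#' @param tf_top_k explicit count, overriding the fraction.
#' @return character vector of selected TF ids, in rank order.
#' @export
select_top_tfs <- function(ranked, tf_top_fraction = 0.40, tf_top_k = NULL) {
  if (nrow(ranked) == 0) stop("ranked TF list must be non-empty")
  k <- if (!is.null(tf_top_k)) tf_top_k else floor(tf_top_fraction * nrow(ranked))
  if (k > nrow(ranked)) {
    warning("requested ", k, " TFs from a list of ", nrow(ranked),
            "; clipping")
    k <- nrow(ranked)
  }
  ranked$tf_id[seq_len(k)]
}

#' Build the intersection zone
#'
#' The selected-genes by selected-TFs count submatrix, with per-TF coverage
#' (how many selected genes each selected TF hits). Row and column order
#' follow the selections.
#'
#' @param counts gene x TF count matrix (the one the selections came from).
#' @param selected_genes,selected_tfs selections from [select_genes()] and
#'   [select_top_tfs()].
#' @return an object of class `intersection_zone`: genes, tfs, submatrix,
#'   tf_coverage.
#' @export
build_intersection_zone <- function(counts, selected_genes, selected_tfs) {
  missing_g <- setdiff(selected_genes, rownames(counts))
  missing_t <- setdiff(selected_tfs, colnames(counts))
  if (length(missing_g) || length(missing_t)) {
    stop("selection ids absent from matrix: ",
         paste(c(missing_g, missing_t), collapse = ", "))
  }
  sub <- counts[selected_genes, selected_tfs, drop = FALSE]
  structure(
    list(genes = selected_genes, tfs = selected_tfs, submatrix = sub,
         tf_coverage = colSums(sub > 0)),
    class = "intersection_zone"
  )
}

#' @export
print.intersection_zone <- function(x, ...) {
  cat(sprintf("<intersection_zone> %d genes x %d TFs, %d accepted motifs\n",
              length(x$genes), length(x$tfs), sum(x$submatrix)))
  if (length(x$tfs)) {
    cat("  TF coverage (selected genes hit): ",
        paste(sprintf("%s=%d", names(x$tf_coverage), x$tf_coverage),
              collapse = " "), "\n")
  }
  invisible(x)
}

#' Write the intersection zone (TSV matrix + JSON summary)
#'
#' @param zone an `intersection_zone`.
#' @param thresholds the `selection_thresholds` used for the selection.
#' @param matrix_path,summary_path output paths (TSV and JSON).
#' @return invisibly, the two paths.
#' @export
write_zone <- function(zone, thresholds, matrix_path, summary_path) {
  write_count_matrix(zone$submatrix, matrix_path)
  summary <- list(
    gene_mean = thresholds$gene_mean, gene_sd = thresholds$gene_sd,
    gene_sd_mode = thresholds$gene_sd_mode,
    gene_int_cutoff = thresholds$gene_int_cutoff,
    total_motifs = thresholds$total, n_genes_dataset = thresholds$n_genes,
    selected_genes = zone$genes, selected_tfs = zone$tfs,
    tf_coverage = as.list(zone$tf_coverage),
    min_coverage = if (length(zone$tfs)) min(zone$tf_coverage) else 0,
    half_coverage_ok = if (length(zone$tfs)) {
      all(zone$tf_coverage >= length(zone$genes) / 2)
    } else NA
  )
  jsonlite::write_json(summary, summary_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(matrix = matrix_path, summary = summary_path))
}
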