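#' Tool report
#'
#' One motif-discovery tool's output over one species' dataset. Main-class
#' tools carry positional per-sequence hits; supportive-class tools carry
#' only the set of TFs they call over the whole dataset.
#'
#' @param tool_id character scalar.
#' @param tool_class `"main"` or `"supportive"`.
#' @param species dataset species the report refers to.
#' @param hits data.frame (gene_id, tf_id, start, end, strand, score); main
#'   class only.
#' @param reported_tfs character vector of TF ids; supportive class only.
#' @return an object of class `tool_report`.
#' @export
tool_report <- function(tool_id, tool_class = c("main", "supportive"),
                        species = "human", hits = NULL, reported_tfs = NULL) {
  tool_class <- match.arg(tool_class)
  if (tool_class == "main") {
    if (is.null(hits)) stop("main reports must carry positional hits")
    if (!is.null(reported_tfs)) stop("main reports must not carry a TF-set")
    hits <- as.data.frame(hits)
  } else {
    if (is.null(reported_tfs)) stop("supportive reports must carry reported_tfs")
    if (!is.null(hits)) stop("supportive reports carry only TF identities")
    reported_tfs <- unique(as.character(reported_tfs))
  }
  structure(
    list(tool_id = as.character(tool_id), tool_class = tool_class,
         species = species, hits = hits, reported_tfs = reported_tfs),
    class = "tool_report"
  )
}

#' @export
print.tool_report <- function(x, ...) {
  body <- if (x$tool_class == "main") {
    sprintf("%d hits", nrow(x$hits))
  } else {
    sprintf("%d reported TFs", length(x$reported_tfs))
  }
  cat(sprintf("<tool_report> %s (%s, %s): %s\n",
              x$tool_id, x$tool_class, x$species, body))
  invisible(x)
}

main_reports <- function(reports) {
  Filter(function(r) r$tool_class == "main", reports)
}

supportive_reports <- function(reports) {
  Filter(function(r) r$tool_class == "supportive", reports)
}

## long data.frame of all main-tool hits, with tool_id column
main_hits_table <- function(reports) {
  mains <- main_reports(reports)
  rows <- lapply(mains, function(r) {
    if (nrow(r$hits) == 0) return(NULL)
    cbind(tool_id = r$tool_id, r$hits, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    cbind(tool_id = character(0), empty_hits())
  } else {
    out
  }
}

#' Two-condition acceptance of a (gene, TF) motif
#'
#' A motif is collected only when (1) at least `min_main` of the main
#' per-sequence tools identified it in that gene's promoter and (2) at
#' least `min_supportive` dataset-wide tools also called that TF. By
#' default every main tool present must agree (unanimity over the panel)
#' and one supportive corroboration suffices.
#'
#' @param gene_id,tf_id the pair to test.
#' @param reports list of `tool_report` (one species' panel).
#' @param min_main required number of agreeing main tools; `NULL` (default)
#'   means all main tools present in `reports`.
#' @param min_supportive required number of supportive tools listing the TF
#'   (default 1).
#' @param genes,tfs optional id universes; ids outside them are an error.
#' @return logical scalar.
#' @export
accept_motif <- function(gene_id, tf_id, reports, min_main = NULL,
                         min_supportive = 1, genes = NULL, tfs = NULL) {
  if (!is.null(genes) && !gene_id %in% genes) stop("unknown gene: ", gene_id)
  if (!is.null(tfs) && !tf_id %in% tfs) stop("unknown TF: ", tf_id)
  mains <- main_reports(reports)
  if (is.null(min_main)) min_main <- length(mains)
  n_main <- sum(vapply(mains, function(r) {
    any(r$hits$gene_id == gene_id & r$hits$tf_id == tf_id)
  }, logical(1)))
  n_supp <- sum(vapply(supportive_reports(reports), function(r) {
    tf_id %in% r$reported_tfs
  }, logical(1)))
  n_main >= min_main && n_supp >= min_supportive
}

#' All accepted (gene, TF) pairs under the two-condition rule
#'
#' Vectorized form of [accept_motif()] over every pair observed in the main
#' reports.
#'
#' @inheritParams accept_motif
#' @return data.frame with columns gene_id, tf_id (lexicographic order).
#' @export
accepted_pairs <- function(reports, min_main = NULL, min_supportive = 1) {
  mains <- main_reports(reports)
  if (is.null(min_main)) min_main <- length(mains)
  hits <- main_hits_table(reports)
  if (nrow(hits) == 0) {
    return(data.frame(gene_id = character(), tf_id = character(),
                      stringsAsFactors = FALSE))
  }
  key <- paste(hits$gene_id, hits$tf_id, sep = "\r")
  n_tools <- tapply(hits$tool_id, key, function(t) length(unique(t)))
  supp_counts <- table(unlist(lapply(supportive_reports(reports),
                                     `[[`, "reported_tfs")))
  pairs <- do.call(rbind, strsplit(names(n_tools), "\r", fixed = TRUE))
  tf_supp <- as.integer(supp_counts[pairs[, 2]])
  tf_supp[is.na(tf_supp)] <- 0L
  ok <- n_tools >= min_main & tf_supp >= min_supportive
  out <- data.frame(gene_id = pairs[ok, 1], tf_id = pairs[ok, 2],
                    stringsAsFactors = FALSE)
  out[order(out$gene_id, out$tf_id), , drop = FALSE]
}

## single-linkage clusters of overlapping same-strand intervals; returns,
## per cluster, the number of distinct supporting tools
overlap_clusters <- function(df) {
  unlist(lapply(split(df, df$strand), function(d) {
    d <- d[order(d$start, d$end), , drop = FALSE]
    gap <- c(TRUE, d$start[-1] >= cummax(d$end[-nrow(d)]))
    cl <- cumsum(gap)
    tapply(d$tool_id, cl, function(t) length(unique(t)))
  }), use.names = FALSE)
}

#' Build the gene x TF accepted-occurrence count matrix
#'
#' Two counting modes. `"pooled"` (the default) sums each main tool's
#' de-overlapped hit count for the pair over tools — five tools reporting
#' the same single site count 5 — which is the totalling convention behind
#' a dataset-wide mean-motifs-per-gene threshold. `"consensus_sites"`
#' instead single-linkage-clusters overlapping same-strand hits across
#' tools and counts the clusters supported by at least `min_main` distinct
#' tools: five tools on one site count 1.
#'
#' @param reports list of `tool_report`.
#' @param accepted data.frame of accepted (gene_id, tf_id) pairs, e.g. from
#'   [accepted_pairs()].
#' @param counting_mode `"pooled"` or `"consensus_sites"`.
#' @param min_main tool support required per consensus site (`NULL`: all
#'   main tools present); ignored for pooled counting.
#' @param genes,tfs row/column universes; default: ids observed in the main
#'   reports union the accepted pairs, sorted lexicographically.
#' @return integer matrix (genes x TFs) with a `provenance` attribute
#'   naming the counting mode.
#' @export
build_count_matrix <- function(reports, accepted,
                               counting_mode = c("pooled", "consensus_sites"),
                               min_main = NULL, genes = NULL, tfs = NULL) {
  counting_mode <- match.arg(counting_mode)
  if (length(reports) == 0) stop("empty report list")
  hits <- main_hits_table(reports)
  if (is.null(min_main)) min_main <- length(main_reports(reports))
  if (is.null(genes)) genes <- sort(unique(c(hits$gene_id, accepted$gene_id)))
  if (is.null(tfs)) tfs <- sort(unique(c(hits$tf_id, accepted$tf_id)))
  counts <- matrix(0L, length(genes), length(tfs),
                   dimnames = list(genes, tfs))
  if (nrow(accepted) > 0 && nrow(hits) > 0) {
    acc_key <- paste(accepted$gene_id, accepted$tf_id, sep = "\r")
    hits <- hits[paste(hits$gene_id, hits$tf_id, sep = "\r") %in% acc_key, ,
                 drop = FALSE]
    groups <- split(hits, paste(hits$gene_id, hits$tf_id, sep = "\r"))
    for (g in groups) {
      n <- if (counting_mode == "pooled") {
        sum(vapply(split(g, g$tool_id),
                   function(d) nrow(prune_hits(d)), 0L))
      } else {
        sum(overlap_clusters(g) >= min_main)
      }
      counts[g$gene_id[1], g$tf_id[1]] <- as.integer(n)
    }
  }
  attr(counts, "provenance") <- counting_mode
  counts
}

#' Write a count matrix as TSV
#'
#' @param counts matrix from [build_count_matrix()].
#' @param path output path.
#' @param long write long form (gene, tf, count) instead of the wide
#'   genes-as-rows matrix.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(counts, path, long = FALSE) {
  if (long) {
    df <- data.frame(
      gene_id = rep(rownames(counts), times = ncol(counts)),
      tf_id = rep(colnames(counts), each = nrow(counts)),
      count = as.vector(counts), stringsAsFactors = FALSE
    )
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    utils::write.table(
      data.frame(gene_id = rownames(counts), counts, check.names = FALSE),
      path, sep = "\t", quote = FALSE, row.names = FALSE
    )
  }
  invisible(path)
}

#' Read a wide count matrix TSV written by [write_count_matrix()]
#'
#' @param path input path.
#' @return integer matrix with gene rownames and TF colnames.
#' @export
read_count_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  m
}

#' Write tool reports as one long TSV
#'
#' Columns: tool, tool_class, species, gene, tf, start, end, strand, score.
#' Supportive reports have empty positional columns (one row per TF).
#'
#' @param reports list of `tool_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tool_reports <- function(reports, path) {
  rows <- lapply(reports, function(r) {
    if (r$tool_class == "main") {
      if (nrow(r$hits) == 0) return(NULL)
      data.frame(tool = r$tool_id, tool_class = "main", species = r$species,
                 gene = r$hits$gene_id, tf = r$hits$tf_id,
                 start = r$hits$start, end = r$hits$end,
                 strand = r$hits$strand, score = r$hits$score,
                 stringsAsFactors = FALSE)
    } else {
      if (length(r$reported_tfs) == 0) return(NULL)
      data.frame(tool = r$tool_id, tool_class = "supportive",
                 species = r$species, gene = NA_character_,
                 tf = r$reported_tfs, start = NA_integer_, end = NA_integer_,
                 strand = NA_character_, score = NA_real_,
                 stringsAsFactors = FALSE)
    }
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) {
    df <- data.frame(tool = character(), tool_class = character(),
                     species = character(), gene = character(),
                     tf = character(), start = integer(), end = integer(),
                     strand = character(), score = numeric())
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read tool reports from the long TSV written by [write_tool_reports()]
#'
#' Empty reports are not representable in the TSV (they carry no rows), so
#' read + write round-trips the non-empty reports only.
#'
#' @param path input path.
#' @return list of `tool_report`.
#' @export
read_tool_reports <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c(tool = "character",
                                         tool_class = "character",
                                         species = "character",
                                         gene = "character",
                                         tf = "character",
                                         strand = "character"),
                          na.strings = "NA")
  keys <- unique(df[, c("tool", "tool_class", "species")])
  lapply(seq_len(nrow(keys)), function(i) {
    sub <- df[df$tool == keys$tool[i] & df$species == keys$species[i], ]
    if (keys$tool_class[i] == "main") {
      tool_report(keys$tool[i], "main", species = keys$species[i],
                  hits = data.frame(gene_id = sub$gene, tf_id = sub$tf,
                                    start = as.integer(sub$start),
                                    end = as.integer(sub$end),
                                    strand = sub$strand,
                                    score = as.numeric(sub$score),
                                    stringsAsFactors = FALSE))
    } else {
      tool_report(keys$tool[i], "supportive", species = keys$species[i],
                  reported_tfs = sub$tf)
    }
  })
}
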