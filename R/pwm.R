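#' Position weight matrix
#'
#' A TF binding model: a 4 x L column-stochastic matrix of per-position base
#' probabilities (rows A, C, G, T). Optionally carries the integer count
#' matrix it was derived from.
#'
#' @param tf_id character scalar identifier.
#' @param probabilities 4 x L numeric matrix; each column must sum to 1
#'   (tolerance 1e-9). Rows are taken in A, C, G, T order; rownames are set.
#' @param source_counts optional 4 x L non-negative matrix of observed counts.
#' @return an object of class `pwm`.
#' @export
pwm <- function(tf_id, probabilities, source_counts = NULL) {
  probabilities <- as.matrix(probabilities)
  if (nrow(probabilities) != 4 || ncol(probabilities) < 1) {
    stop("probabilities must be a 4 x L matrix with L >= 1")
  }
  if (any(probabilities < 0) ||
      any(abs(colSums(probabilities) - 1) > 1e-9)) {
    stop("each PWM column must be a probability vector summing to 1")
  }
  rownames(probabilities) <- DNA_BASES
  if (!is.null(source_counts)) {
    source_counts <- as.matrix(source_counts)
    if (!all(dim(source_counts) == dim(probabilities)) ||
        any(source_counts < 0)) {
      stop("source_counts must be non-negative and match the PWM dimensions")
    }
    rownames(source_counts) <- DNA_BASES
  }
  structure(
    list(tf_id = as.character(tf_id), probabilities = probabilities,
         source_counts = source_counts),
    class = "pwm"
  )
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> %s  (length %d, consensus %s)\n",
              x$tf_id, pwm_length(x), pwm_consensus(x)))
  print(round(x$probabilities, 3))
  invisible(x)
}

#' PWM length (number of positions)
#' @param x a `pwm`.
#' @return integer motif length.
#' @export
pwm_length <- function(x) ncol(x$probabilities)

#' Consensus sequence of a PWM (argmax base per column; ties to the
#' alphabetically first base)
#' @param x a `pwm`.
#' @return character scalar.
#' @export
pwm_consensus <- function(x) {
  paste(DNA_BASES[apply(x$probabilities, 2, which.max)], collapse = "")
}

## per-column Shannon information content, in bits (2 - entropy)
pwm_information <- function(x) {
  apply(x$probabilities, 2, function(p) {
    nz <- p[p > 0]
    2 + sum(nz * log2(nz))
  })
}

## information content of a column with dominant-base probability p
## (other three bases share 1 - p equally); monotone from 0 at p = 1/4
## to 2 at p = 1
ic_dominant <- function(p) {
  q <- (1 - p) / 3
  term <- function(z) ifelse(z > 0, z * log2(z), 0)
  2 + term(p) + 3 * term(q)
}

#' Generate random position weight matrices
#'
#' Each column has one randomly chosen dominant base whose probability is
#' solved so the column's information content equals `info_bits` exactly
#' (the remaining mass is split evenly over the other bases). `info_bits = 2`
#' forces consensus columns (one entry 1); `info_bits` near 0 approaches the
#' uniform column.
#'
#' @param n_tfs number of matrices.
#' @param pwm_length motif length in bp.
#' @param info_bits target per-column information content, in (0, 2].
#' @param seed integer seed; identical seeds give bit-identical output.
#' @return list of `pwm` objects with unique ids `TF01`, `TF02`, ...
#' @export
generate_pwms <- function(n_tfs, pwm_length = 10, info_bits = 1.0, seed = 1) {
  if (n_tfs < 1) stop("n_tfs must be >= 1")
  if (pwm_length < 1) stop("pwm_length must be >= 1")
  if (info_bits <= 0 || info_bits > 2) {
    stop("info_bits must be in (0, 2]: a 4-letter alphabet caps at 2 bits/column")
  }
  p_dom <- if (info_bits >= 2 - 1e-12) {
    1
  } else {
    stats::uniroot(function(p) ic_dominant(p) - info_bits,
                   lower = 0.25, upper = 1 - 1e-12, tol = 1e-12)$root
  }
  with_seed(seed, {
    lapply(seq_len(n_tfs), function(i) {
      dom <- sample.int(4, pwm_length, replace = TRUE)
      mat <- matrix((1 - p_dom) / 3, nrow = 4, ncol = pwm_length)
      mat[cbind(dom, seq_len(pwm_length))] <- p_dom
      pwm(sprintf("TF%02d", i), mat)
    })
  })
}

#' Read position frequency matrices in JASPAR text format
#'
#' Accepts both common dialects: a `>ID name` header followed by four rows
#' `A [ 3 5 ... ]` (letters and brackets optional) or four bare
#' whitespace-separated rows in A, C, G, T order. Counts are converted to
#' column probabilities; integer inputs are kept as `source_counts`.
#'
#' @param path file path.
#' @return list of `pwm` objects. A file with an all-zero column is rejected.
#' @export
read_jaspar <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (length(starts) == 0) stop("no '>' headers found in ", path, ": not JASPAR text")
  out <- vector("list", length(starts))
  bounds <- c(starts, length(lines) + 1L)
  for (k in seq_along(starts)) {
    block <- lines[(bounds[k] + 1L):(bounds[k + 1L] - 1L)]
    if (length(block) != 4) {
      stop("JASPAR record ", k, " in ", path, " has ", length(block),
           " matrix rows; expected 4")
    }
    header <- sub("^>\\s*", "", lines[starts[k]])
    id <- strsplit(trimws(header), "\\s+")[[1]][1]
    rows <- lapply(block, function(ln) {
      ln <- gsub("\\[|\\]", " ", ln)
      fields <- strsplit(trimws(ln), "\\s+")[[1]]
      base <- NA_character_
      if (toupper(fields[1]) %in% DNA_BASES) {
        base <- toupper(fields[1])
        fields <- fields[-1]
      }
      vals <- suppressWarnings(as.numeric(fields))
      if (anyNA(vals)) stop("unparsable matrix row in ", path, ": '", ln, "'")
      list(base = base, vals = vals)
    })
    lens <- lengths(lapply(rows, `[[`, "vals"))
    if (length(unique(lens)) != 1) stop("ragged matrix rows for ", id, " in ", path)
    mat <- do.call(rbind, lapply(rows, `[[`, "vals"))
    bases <- vapply(rows, `[[`, character(1), "base")
    if (!anyNA(bases)) {
      if (!setequal(bases, DNA_BASES)) stop("row letters for ", id, " are not A,C,G,T")
      mat <- mat[match(DNA_BASES, bases), , drop = FALSE]
    }
    cs <- colSums(mat)
    if (any(cs <= 0)) stop("all-zero column in matrix ", id)
    probs <- sweep(mat, 2, cs, "/")
    is_counts <- all(mat == round(mat)) && any(mat > 1)
    out[[k]] <- pwm(id, probs, source_counts = if (is_counts) mat else NULL)
  }
  out
}

#' Write PWMs as JASPAR text
#'
#' Writes the `>ID ID` header plus four bracketed rows. Count matrices are
#' written when present; otherwise probabilities are written in full
#' precision so a read round-trips.
#'
#' @param pwms list of `pwm` objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_jaspar <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    mat <- if (!is.null(p$source_counts)) p$source_counts else p$probabilities
    writeLines(sprintf(">%s %s", p$tf_id, p$tf_id), con)
    for (b in DNA_BASES) {
      writeLines(sprintf("%s  [ %s ]", b,
                         paste(format(mat[b, ], digits = 12, trim = TRUE),
                               collapse = " ")), con)
    }
  }
  invisible(path)
}
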