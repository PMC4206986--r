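#' @keywords internal
"_PACKAGE"

DNA_BASES <- c("A", "C", "G", "T")
DNA_ALPHABET <- c(DNA_BASES, "N")
DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Round half away from zero
#'
#' Display rounding used for reported thresholds (26.428... -> 26.43); base
#' R's `round()` rounds half to even, which is not what readers of the
#' reported values expect.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up.
#' @export
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Reverse complement of a DNA string
#'
#' @param x character vector of sequences over A/C/G/T/N.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## encode a sequence as integer codes 1..5 (A,C,G,T,N)
encode_dna <- function(seq) {
  codes <- match(strsplit(toupper(seq), "", fixed = TRUE)[[1]], DNA_ALPHABET)
  if (anyNA(codes)) stop("sequence contains characters outside {A,C,G,T,N}")
  codes
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so generators are pure
#' functions of their seed argument.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Derive child seeds from a master seed
#'
#' One master seed drives the whole pipeline; each stochastic stage draws its
#' own child seed at a fixed stream index, so adding a stage never perturbs
#' the streams of the others. Derivation: `set.seed(master)` then
#' `sample.int(2^31 - 2, n)`.
#'
#' @param seed master integer seed.
#' @param n number of child seeds.
#' @return integer vector of length `n`.
#' @export
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(2147483646L, n))
}

## background vector from GC content
gc_background <- function(gc) {
  stats::setNames(c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2), DNA_BASES)
}

check_background <- function(background) {
  if (length(background) != 4 || any(background <= 0) ||
      abs(sum(background) - 1) > 1e-9) {
    stop("background must be a strictly positive 4-vector summing to 1")
  }
  invisible(background)
}
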