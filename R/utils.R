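#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores \code{.Random.seed} so seeded simulators do not
#' disturb the caller's RNG stream.
#'
#' @param seed integer seed, or NULL to leave the RNG untouched.
#' @param expr expression to evaluate.
#' @return The value of \code{expr}.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

#' Pairwise sequence identity from a banded edit distance
#'
#' Identity is defined as `1 - d / max(nchar(a), nchar(b))` where `d` is the
#' Levenshtein distance, i.e. matching columns over alignment columns of a
#' unit-cost global alignment. Returns NA where the distance exceeds the
#' band implied by `floor_identity` (the true identity is then certainly
#' below that floor).
#'
#' @param a single sequence (character scalar).
#' @param b character vector of sequences to compare against.
#' @param floor_identity identities below this are not resolved exactly.
#' @return Numeric vector of identities in `[0, 1]`, NA meaning "< floor".
#' @export
seq_identity <- function(a, b, floor_identity = 0.9) {
  stopifnot(length(a) == 1L, floor_identity > 0, floor_identity <= 1)
  maxlen <- pmax(nchar(a), nchar(b))
  band <- as.integer(ceiling((1 - floor_identity) * max(maxlen)) + 1L)
  d <- .cpp_edit_many(a, b, band)
  ifelse(d < 0L, NA_real_, 1 - d / maxlen)
}

#' Reverse-complement nucleotide sequences
#' @param x character vector of DNA sequences.
#' @return character vector.
#' @keywords internal
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Convert Phred+33 quality strings to integer vectors and back
#' @param qual character vector of quality strings.
#' @return `qual_to_int`: list of integer vectors; `int_to_qual`: character.
#' @keywords internal
qual_to_int <- function(qual) lapply(qual, function(q) utf8ToInt(q) - 33L)

#' @rdname qual_to_int
#' @param q list of integer vectors (or a single integer vector).
#' @keywords internal
int_to_qual <- function(q) {
  if (is.numeric(q)) q <- list(as.integer(q))
  vapply(q, function(v) intToUtf8(as.integer(v) + 33L), character(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
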