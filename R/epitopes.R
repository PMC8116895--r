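#' Epitope definition tables
#'
#' An epitope table maps named peptide motifs to a category:
#' `33mer_constituent` (the three DQ2.5 epitopes whose overlapping copies
#' build the 33-mer), `flanking_dq2` (DQ2.5-glia-a3, adjacent to the
#' 33-mer) or `innate_peptide` (p31-43, which triggers the innate response
#' and does not count toward CD-epitope status). The default table shipped
#' with the package holds literature-derived motif strings; both p31-43
#' variant forms (LG- and LP-type) are included.
#'
#' @return data.frame with columns `name`, `peptide`, `category`.
#' @export
default_epitope_table <- function() {
  read_epitope_table(system.file("extdata", "epitopes.tsv", package = "gliadex"))
}

#' @rdname default_epitope_table
#' @param path TSV file with columns `name`, `peptide`, `category`
#'   (`#` comment lines allowed).
#' @export
read_epitope_table <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  validate_epitope_table(x)
  x
}

validate_epitope_table <- function(x) {
  stopifnot(all(c("name", "peptide", "category") %in% names(x)))
  if (anyDuplicated(x$name)) stop("epitope names must be unique")
  if (any(nchar(x$peptide) < 5)) stop("epitope peptides must be >= 5 residues")
  if (any(grepl("[^ACDEFGHIKLMNPQRSTVWY]", x$peptide)))
    stop("epitope peptides must use the 20 amino-acid alphabet")
  ok <- c("33mer_constituent", "flanking_dq2", "innate_peptide")
  if (!all(x$category %in% ok))
    stop("unknown epitope category: ", paste(setdiff(x$category, ok), collapse = ", "))
  invisible(x)
}

#' Count overlapping epitope occurrences in a protein
#'
#' Exact, possibly overlapping substring matches of every motif in
#' `epitope_table` against `protein`. Stops (`*`) may be present; since no
#' motif contains a stop, matches never span one, so segments between stops
#' are effectively scanned independently.
#'
#' @param protein single amino-acid string (stops allowed as `*`).
#' @param epitope_table data.frame as from [default_epitope_table()].
#' @return named integer vector of counts, one per epitope.
#' @export
scan_epitopes <- function(protein, epitope_table = default_epitope_table()) {
  stopifnot(length(protein) == 1L)
  validate_epitope_table(epitope_table)
  subj <- Biostrings::AAString(protein)
  counts <- vapply(epitope_table$peptide, function(p) {
    if (nchar(p) > nchar(protein)) return(0L)
    Biostrings::countPattern(p, subj)
  }, integer(1))
  setNames(as.integer(counts), epitope_table$name)
}

#' Sum 33-mer-constituent epitope copies
#'
#' @param epitope_counts named counts from [scan_epitopes()].
#' @param epitope_table the table the counts were produced with.
#' @return integer: total copies over `33mer_constituent` epitopes.
#' @export
count_33mer_copies <- function(epitope_counts, epitope_table = default_epitope_table()) {
  keep <- epitope_table$name[epitope_table$category == "33mer_constituent"]
  sum(epitope_counts[intersect(names(epitope_counts), keep)])
}

#' Classify a variant into the type-1 subtype scheme
#'
#' Subtypes follow the 33-mer copy number of type-1 alpha-gliadins:
#' 1 copy -> `1.1-1`, 2 -> `1.1-2`, 4 -> `1.2-4`, 6 (the full 33-mer) ->
#' `1.3-6`; other positive copy numbers -> `type1_other`. Variants with no
#' 33-mer-constituent copies are `non_type1` when any other DQ2.5-class
#' epitope (e.g. DQ2.5-glia-a3) is present, else `no_cd_epitope`
#' (p31-43, an innate peptide, does not count toward CD-epitope status).
#'
#' @inheritParams count_33mer_copies
#' @return character scalar subtype label.
#' @export
classify_type <- function(epitope_counts, epitope_table = default_epitope_table()) {
  n33 <- count_33mer_copies(epitope_counts, epitope_table)
  if (n33 > 0) {
    return(switch(as.character(n33),
      "1" = "1.1-1", "2" = "1.1-2", "4" = "1.2-4", "6" = "1.3-6",
      "type1_other"
    ))
  }
  dq2 <- epitope_table$name[epitope_table$category %in%
                              c("33mer_constituent", "flanking_dq2")]
  if (sum(epitope_counts[intersect(names(epitope_counts), dq2)]) > 0)
    "non_type1"
  else
    "no_cd_epitope"
}
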