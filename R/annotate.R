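# Variant annotation: reading frame, translation, pseudogene status,
# epitope counts, subtype and subgenome assignment.

#' Translate an amplicon window in a given frame
#'
#' `frame_offset` follows the convention (1-based reference start position)
#' mod 3: an amplicon starting at reference position 91 has offset 1 and is
#' codon-aligned (no bases skipped); one starting at 90 has offset 0 and
#' skips one base. Trailing bases short of a codon are ignored; internal
#' stops translate to `*`.
#'
#' @param seq nucleotide string.
#' @param frame_offset 0, 1 or 2.
#' @return amino-acid string.
#' @export
translate_amplicon <- function(seq, frame_offset = 1L) {
  stopifnot(frame_offset %in% 0:2)
  skip <- (1L - frame_offset) %% 3L
  s <- substr(seq, skip + 1L, nchar(seq))
  s <- substr(s, 1L, (nchar(s) %/% 3L) * 3L)
  if (nchar(s) < 3L) stop("sequence too short to translate")
  as.character(Biostrings::translate(Biostrings::DNAString(s),
                                     if.fuzzy.codon = "X"))
}

#' Determine the reading frame of a variant against a reference CDS
#'
#' Locally aligns the variant to a reference coding sequence that begins at
#' a start codon and reports `frame_offset` = (1-based start of the aligned
#' region in the reference, extrapolated to the variant's first base) mod 3.
#' When alignment identity falls below `min_identity` the frame maximizing
#' the longest stop-free stretch of the translation is used instead.
#'
#' @param seq variant nucleotide string.
#' @param reference_cds reference gene sequence beginning at ATG.
#' @param min_identity identity below which the ORF fallback applies.
#' @return list with `frame_offset`, `method` ("alignment" or "orf") and
#'   `identity` (NA for the fallback).
#' @export
determine_frame <- function(seq, reference_cds, min_identity = 0.7) {
  aln <- Biostrings::pairwiseAlignment(Biostrings::DNAString(seq),
                                       Biostrings::DNAString(reference_cds),
                                       type = "local")
  id <- Biostrings::nmatch(aln) / Biostrings::nchar(aln)
  if (is.finite(id) && id >= min_identity) {
    start_ref <- Biostrings::start(Biostrings::subject(aln)@range) -
      (Biostrings::start(Biostrings::pattern(aln)@range) - 1L)
    return(list(frame_offset = ((start_ref %% 3L) + 3L) %% 3L,
                method = "alignment", identity = id))
  }
  orf_len <- vapply(0:2, function(off) {
    prot <- translate_amplicon(seq, off)
    max(nchar(strsplit(prot, "*", fixed = TRUE)[[1]]), 0L)
  }, numeric(1))
  if (all(orf_len == 0))
    stop("annotation failure: no alignment and stops in all three frames")
  list(frame_offset = (0:2)[which.max(orf_len)], method = "orf",
       identity = NA_real_)
}

#' Detect pseudogene status by in-frame stop codons
#'
#' Translates the amplicon in the given frame and reports any stop codon as
#' premature: because the amplicon truncates the gene, a stop even at the
#' final translated codon lies before the natural end of the protein.
#'
#' @inheritParams translate_amplicon
#' @return list with `is_pseudogene` and `stop_positions` (1-based
#'   amino-acid coordinates).
#' @export
detect_pseudogene <- function(seq, frame_offset = 1L) {
  if (nchar(seq) < 3L) stop("sequence shorter than one codon")
  prot <- translate_amplicon(seq, frame_offset)
  pos <- which(strsplit(prot, "")[[1]] == "*")
  list(is_pseudogene = length(pos) > 0L, stop_positions = pos,
       protein = prot)
}

#' Assign a variant to a wheat subgenome by nearest exemplar
#'
#' Nearest-exemplar classification by global-alignment identity (see
#' [seq_identity()]). A variant is `unassigned` when the best identity is
#' below `min_identity` or the top two genomes tie within `tie_margin`
#' identity points.
#'
#' @param seq variant nucleotide string.
#' @param exemplars named character vector of genome-labeled exemplar
#'   sequences (names are genome labels, repeated names allowed).
#' @param min_identity identity floor (default 0.90).
#' @param tie_margin tie window in identity fraction (default 0.005, i.e.
#'   0.5 identity points).
#' @return list with `genome`, `identity`, `tie` (logical).
#' @export
assign_genome <- function(seq, exemplars, min_identity = 0.9,
                          tie_margin = 0.005) {
  if (length(exemplars) == 0L) stop("configuration error: empty exemplar set")
  if (is.null(names(exemplars))) stop("exemplars must be genome-named")
  ids <- seq_identity(seq, unname(exemplars), floor_identity = min_identity - 0.05)
  by_genome <- tapply(ids, names(exemplars), function(x)
    if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE))
  if (all(is.na(by_genome)) || max(by_genome, na.rm = TRUE) < min_identity)
    return(list(genome = "unassigned", identity = suppressWarnings(
      max(by_genome, na.rm = TRUE)), tie = FALSE))
  ord <- order(by_genome, decreasing = TRUE, na.last = TRUE)
  best <- by_genome[ord[1]]
  tie <- length(by_genome) > 1L && !is.na(by_genome[ord[2]]) &&
    (best - by_genome[ord[2]]) < tie_margin
  if (tie)
    return(list(genome = "unassigned", identity = unname(best), tie = TRUE))
  list(genome = names(by_genome)[ord[1]], identity = unname(best), tie = FALSE)
}

#' Annotate a set of amplicon variants
#'
#' Runs the full annotation stack per variant: frame determination against
#' the reference CDS, translation, pseudogene detection, overlapping
#' epitope counting, 33-mer copy number, type-1 subtype classification and
#' subgenome assignment.
#'
#' @param seqs named character vector of variant nucleotide sequences.
#' @param reference_cds full-length reference gene (starts at ATG); NULL
#'   skips alignment-based framing and uses the ORF fallback.
#' @param epitope_table epitope definitions, see [default_epitope_table()].
#' @param exemplars genome-labeled exemplar sequences, or NULL to skip
#'   genome assignment.
#' @return data.frame: variant_id, frame_offset, is_pseudogene, one count
#'   column per epitope, n33mer_copies, type_label, genome.
#' @export
annotate_variants <- function(seqs, reference_cds = NULL,
                              epitope_table = default_epitope_table(),
                              exemplars = NULL) {
  stopifnot(length(seqs) >= 1L)
  ids <- names(seqs) %||% paste0("variant", seq_along(seqs))
  rows <- lapply(seq_along(seqs), function(i) {
    s <- seqs[[i]]
    fr <- if (is.null(reference_cds)) {
      orf_len <- vapply(0:2, function(off)
        max(nchar(strsplit(translate_amplicon(s, off), "*", fixed = TRUE)[[1]]), 0L),
        numeric(1))
      list(frame_offset = (0:2)[which.max(orf_len)])
    } else determine_frame(s, reference_cds)
    ps <- detect_pseudogene(s, fr$frame_offset)
    counts <- scan_epitopes(ps$protein, epitope_table)
    gen <- if (is.null(exemplars)) list(genome = "unassigned")
           else assign_genome(s, exemplars)
    cbind(
      data.frame(variant_id = ids[i], frame_offset = fr$frame_offset,
                 is_pseudogene = ps$is_pseudogene, stringsAsFactors = FALSE),
      as.data.frame(as.list(counts), check.names = FALSE),
      data.frame(n33mer_copies = count_33mer_copies(counts, epitope_table),
                 type_label = classify_type(counts, epitope_table),
                 genome = gen$genome, stringsAsFactors = FALSE)
    )
  })
  do.call(rbind, rows)
}
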