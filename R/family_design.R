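# Building blocks for synthetic alpha-gliadin-like amplicon proteins.
#
# The epitope region is assembled from literature-motif inserts; the
# repetitive filler ("pad") mimics the P/Q-rich gliadin repeat but carries
# H where the real repeat has Y, so it can never match an epitope (every
# default motif requires F or Y). Flanks are built from codons that are at
# Hamming distance >= 2 from all stop codons, contain no F/Y/Q codons, and
# tolerate any third-position substitution without creating a stop, F or Y
# - so variant barcode/SNP mutations are always safe.

# Every variant's epitope region is the same-width repeat scaffold: the
# full 33-mer with Y->H substitutions knocking out specific overlapping
# epitope copies (positions 13/20/27 of the repeat carry the tyrosines the
# motifs require). This mirrors how natural epitope-loss repeat variants
# differ from the immunodominant D-genome form.
.CORE_INSERTS <- list(
  "0" = "LQLQPFPQPQLPHPQPQLPHPQPQLPHPQPQPF",
  "1" = "LQLQPFPQPQLPHPQPQLPHPQPQLPYPQPQPF",
  "2" = "LQLQPFPQPQLPYPQPQLPHPQPQLPHPQPQPF",
  "3" = "LQLQPFPQPQLPHPQPQLPYPQPQLPYPQPQPF",
  "4" = "LQLQPFPQPQLPYPQPQLPYPQPQLPHPQPQPF",
  "6" = "LQLQPFPQPQLPYPQPQLPYPQPQLPYPQPQPF"
)

# designed per-epitope breakdown of each core geometry
.CORE_COUNTS <- list(
  "0" = c("DQ2.5-glia-a1a" = 0L, "DQ2.5-glia-a1b" = 0L, "DQ2.5-glia-a2" = 0L),
  "1" = c("DQ2.5-glia-a1a" = 0L, "DQ2.5-glia-a1b" = 0L, "DQ2.5-glia-a2" = 1L),
  "2" = c("DQ2.5-glia-a1a" = 1L, "DQ2.5-glia-a1b" = 0L, "DQ2.5-glia-a2" = 1L),
  "3" = c("DQ2.5-glia-a1a" = 0L, "DQ2.5-glia-a1b" = 1L, "DQ2.5-glia-a2" = 2L),
  "4" = c("DQ2.5-glia-a1a" = 1L, "DQ2.5-glia-a1b" = 1L, "DQ2.5-glia-a2" = 2L),
  "6" = c("DQ2.5-glia-a1a" = 1L, "DQ2.5-glia-a1b" = 2L, "DQ2.5-glia-a2" = 3L)
)

.P31_PEPTIDES <- c(LG = "LGQQQPFPPQQPY", LP = "LPQQQPFPPQQPY")
.P31_FILLER <- "LGQQQPFPPQQPH"   # motif-dead p31 slot (Y->H)
.A3_PEPTIDE <- "FRPQQPYPQ"
.A3_FILLER <- "FRPQQPHPQ"        # motif-dead a3 slot (Y->H)
.PAD_UNIT <- "PQPQLPHPQ"
.SEG_LINKER <- "QQQQ"

# codon table for insert/pad amino acids (fixed so sequences are
# reproducible); Q and Y codons occur only in regions never mutated
.MID_CODON <- c(P = "CCA", Q = "CAA", L = "CTT", Y = "TAT", F = "TTT",
                G = "GGT", R = "CGT", H = "CAT")

# flank codons: >= 2 substitutions away from any stop, no TA/TG prefix,
# amino acid not F/Y/Q
.FLANK_CODONS <- c("CCA", "CCT", "CCG", "CTC", "CTT", "CAT", "CAC", "GCT",
                   "GCC", "ACT", "ACC", "TCT", "TCC", "GTT", "GTC", "GGT",
                   "ATT", "AAT", "GAT", "CGT")

.N_FLANK_CODONS <- 45L
.C_FLANK_CODONS <- 35L
.GENOME_TAG_CODONS <- seq(2L, 36L, by = 2L)  # 18 N-flank codons
.STOP_ZONE <- 5L:30L                          # C-flank codons reserved for stops
.N_BARCODE <- 4L
.MIN_PAIR_DIFF <- 7L                          # >= 7 diffs -> identity <= 98.5%

encode_aa <- function(aa) {
  if (!nzchar(aa)) return("")
  chars <- strsplit(aa, "")[[1]]
  bad <- setdiff(chars, names(.MID_CODON))
  if (length(bad)) stop("no codon defined for residue(s): ", paste(bad, collapse = ","))
  paste(.MID_CODON[chars], collapse = "")
}

#' Specify one synthetic amplicon variant
#'
#' A variant is described by its subgenome, pseudogene status, intended
#' epitope content (33-mer-constituent copy number, presence of
#' DQ2.5-glia-a3, p31-43 form), amplicon length and DNA frequency within
#' the family. Realizable 33-mer copy numbers are 0, 1, 2, 3, 4 and 6
#' (the overlapping-copy geometries of the natural repeat); other requests
#' raise a constraint error when the family is built.
#'
#' @param variant_id label, e.g. `"Amp13"`.
#' @param genome one of `"A"`, `"B"`, `"D"`.
#' @param is_pseudogene logical; pseudogenes carry an in-frame premature
#'   stop codon downstream of the epitope region.
#' @param n33mer intended total copies of 33-mer-constituent epitopes.
#' @param a3 logical; include one DQ2.5-glia-a3 copy.
#' @param p31 `NA` (absent), `"LG"` or `"LP"` (p31-43 variant form).
#' @param length_bp amplicon length in nucleotides (multiple of 3,
#'   >= 160 so all designed variants survive the pipeline length filter).
#' @param dna_frequency fraction of the family in (0, 1].
#' @return one-row data.frame.
#' @export
variant_design <- function(variant_id, genome, is_pseudogene, n33mer = 0L,
                           a3 = FALSE, p31 = NA_character_,
                           length_bp = 450L, dna_frequency = 1) {
  stopifnot(genome %in% c("A", "B", "D"), length_bp >= 160L,
            dna_frequency > 0, dna_frequency <= 1)
  if (!is.na(p31) && !p31 %in% names(.P31_PEPTIDES))
    stop("p31 must be NA, 'LG' or 'LP'")
  data.frame(variant_id = variant_id, genome = genome,
             is_pseudogene = isTRUE(is_pseudogene),
             n33mer = as.integer(n33mer), a3 = isTRUE(a3),
             p31 = as.character(p31), length_bp = as.integer(length_bp),
             dna_frequency = dna_frequency, stringsAsFactors = FALSE)
}

#' Specify a synthetic amplicon family
#'
#' @param variants data.frame of stacked [variant_design()] rows.
#' @param snp_rate substitution probability per mutable (third-codon
#'   position) flank site, applied on top of each variant's barcode
#'   mutations.
#' @param seed integer; all randomness of the family build flows from it.
#' @param name optional design name.
#' @return object of class `gliadex_family_design`.
#' @export
family_design <- function(variants, snp_rate = 0.01, seed = 1L,
                          name = "custom") {
  stopifnot(is.data.frame(variants), nrow(variants) >= 1L)
  if (anyDuplicated(variants$variant_id)) stop("variant ids must be unique")
  if (abs(sum(variants$dna_frequency) - 1) > 1e-9)
    stop("dna_frequency must sum to 1 over the family (off by ",
         format(sum(variants$dna_frequency) - 1), ")")
  if (snp_rate < 0 || snp_rate > 0.2) stop("snp_rate out of range [0, 0.2]")
  structure(list(variants = variants, snp_rate = snp_rate,
                 seed = as.integer(seed), name = name),
            class = "gliadex_family_design")
}

#' The default BW208-like family design
#'
#' The named default instance used throughout the package: 45 variants
#' (20 pseudogenes, 25 putative genes) whose marginal structure mirrors the
#' study system - exactly one genome-D putative gene with the full six-copy
#' 33-mer complement at DNA frequency 0.024; six genome-B putative genes,
#' none with 33-mer-constituent epitopes and exactly two with
#' DQ2.5-glia-a3; p31-43 present in 38 of 45 variants and 20 of 25 putative
#' genes; six variants (four putative genes) free of DQ2.5-class epitopes;
#' five putative genes with one 33-mer copy and four with four copies; and
#' a genome-B putative gene carrying only p31-43 as the most abundant
#' variant.
#'
#' @param seed build seed of the named default instance (42).
#' @return `gliadex_family_design`.
#' @export
bw208_like_design <- function(seed = 42L) {
  v <- function(...) variant_design(...)
  variants <- do.call(rbind, list(
    # genome-D putative type-1 variants
    v("Amp01", "D", FALSE, n33mer = 4, a3 = TRUE,  p31 = "LG", length_bp = 462, dna_frequency = 0.045),
    v("Amp02", "D", FALSE, n33mer = 4, a3 = TRUE,  p31 = NA,   length_bp = 459, dna_frequency = 0.026),
    v("Amp03", "D", FALSE, n33mer = 4, a3 = TRUE,  p31 = "LG", length_bp = 456, dna_frequency = 0.018),
    v("Amp04", "D", FALSE, n33mer = 4, a3 = FALSE, p31 = NA,   length_bp = 465, dna_frequency = 0.014),
    v("Amp05", "D", FALSE, n33mer = 1, a3 = TRUE,  p31 = "LG", length_bp = 438, dna_frequency = 0.042),
    v("Amp06", "D", FALSE, n33mer = 1, a3 = FALSE, p31 = "LG", length_bp = 435, dna_frequency = 0.038),
    v("Amp07", "D", FALSE, n33mer = 1, a3 = TRUE,  p31 = "LG", length_bp = 441, dna_frequency = 0.033),
    v("Amp08", "D", FALSE, n33mer = 2, a3 = TRUE,  p31 = "LG", length_bp = 450, dna_frequency = 0.030),
    v("Amp09", "D", FALSE, n33mer = 2, a3 = TRUE,  p31 = NA,   length_bp = 447, dna_frequency = 0.022),
    # genome-A putative type-1 variants
    v("Amp10", "A", FALSE, n33mer = 1, a3 = TRUE,  p31 = "LG", length_bp = 438, dna_frequency = 0.040),
    v("Amp11", "A", FALSE, n33mer = 1, a3 = FALSE, p31 = NA,   length_bp = 435, dna_frequency = 0.016),
    v("Amp12", "A", FALSE, n33mer = 2, a3 = TRUE,  p31 = "LG", length_bp = 444, dna_frequency = 0.025),
    # the single full-33-mer variant (six copies, genome D)
    v("Amp13", "D", FALSE, n33mer = 6, a3 = TRUE,  p31 = "LG", length_bp = 465, dna_frequency = 0.024),
    # non-type-1 putative genes on A/D (DQ2.5-glia-a3 only)
    v("Amp14", "A", FALSE, n33mer = 0, a3 = TRUE,  p31 = "LG", length_bp = 450, dna_frequency = 0.035),
    v("Amp15", "A", FALSE, n33mer = 0, a3 = TRUE,  p31 = "LG", length_bp = 444, dna_frequency = 0.024),
    v("Amp16", "A", FALSE, n33mer = 0, a3 = TRUE,  p31 = NA,   length_bp = 456, dna_frequency = 0.010),
    v("Amp17", "A", FALSE, n33mer = 0, a3 = TRUE,  p31 = "LP", length_bp = 438, dna_frequency = 0.009),
    v("Amp18", "D", FALSE, n33mer = 0, a3 = TRUE,  p31 = "LG", length_bp = 453, dna_frequency = 0.008),
    # genome-B putative genes: no 33-mer epitopes at all
    v("Amp19", "B", FALSE, n33mer = 0, a3 = FALSE, p31 = "LG", length_bp = 450, dna_frequency = 0.120),
    v("Amp20", "B", FALSE, n33mer = 0, a3 = FALSE, p31 = "LG", length_bp = 444, dna_frequency = 0.052),
    v("Amp21", "B", FALSE, n33mer = 0, a3 = FALSE, p31 = "LP", length_bp = 438, dna_frequency = 0.028),
    v("Amp22", "B", FALSE, n33mer = 0, a3 = FALSE, p31 = "LG", length_bp = 456, dna_frequency = 0.012),
    v("Amp23", "B", FALSE, n33mer = 0, a3 = TRUE,  p31 = "LG", length_bp = 447, dna_frequency = 0.048),
    v("Amp24", "B", FALSE, n33mer = 0, a3 = TRUE,  p31 = "LP", length_bp = 441, dna_frequency = 0.020),
    v("Amp25", "D", FALSE, n33mer = 0, a3 = TRUE,  p31 = "LG", length_bp = 447, dna_frequency = 0.007),
    # genome-D pseudogenes
    v("Amp26", "D", TRUE,  n33mer = 1, a3 = TRUE,  p31 = "LG", length_bp = 441, dna_frequency = 0.024),
    v("Amp27", "D", TRUE,  n33mer = 1, a3 = TRUE,  p31 = "LG", length_bp = 438, dna_frequency = 0.022),
    v("Amp28", "D", TRUE,  n33mer = 2, a3 = TRUE,  p31 = "LG", length_bp = 447, dna_frequency = 0.020),
    v("Amp29", "D", TRUE,  n33mer = 3, a3 = TRUE,  p31 = "LG", length_bp = 456, dna_frequency = 0.018),
    v("Amp30", "D", TRUE,  n33mer = 0, a3 = TRUE,  p31 = "LG", length_bp = 444, dna_frequency = 0.016),
    v("Amp31", "D", TRUE,  n33mer = 0, a3 = TRUE,  p31 = "LG", length_bp = 450, dna_frequency = 0.015),
    v("Amp32", "D", TRUE,  n33mer = 2, a3 = TRUE,  p31 = "LP", length_bp = 450, dna_frequency = 0.014),
    v("Amp33", "D", TRUE,  n33mer = 1, a3 = FALSE, p31 = NA,   length_bp = 435, dna_frequency = 0.013),
    v("Amp34", "D", TRUE,  n33mer = 3, a3 = TRUE,  p31 = "LG", length_bp = 459, dna_frequency = 0.012),
    v("Amp35", "D", TRUE,  n33mer = 0, a3 = TRUE,  p31 = "LG", length_bp = 441, dna_frequency = 0.012),
    v("Amp36", "D", TRUE,  n33mer = 0, a3 = FALSE, p31 = "LG", length_bp = 438, dna_frequency = 0.011),
    # genome-A pseudogenes
    v("Amp37", "A", TRUE,  n33mer = 1, a3 = TRUE,  p31 = "LG", length_bp = 444, dna_frequency = 0.011),
    v("Amp38", "A", TRUE,  n33mer = 1, a3 = TRUE,  p31 = "LG", length_bp = 438, dna_frequency = 0.010),
    v("Amp39", "A", TRUE,  n33mer = 1, a3 = TRUE,  p31 = "LP", length_bp = 441, dna_frequency = 0.010),
    v("Amp40", "A", TRUE,  n33mer = 2, a3 = TRUE,  p31 = "LG", length_bp = 447, dna_frequency = 0.009),
    v("Amp41", "A", TRUE,  n33mer = 2, a3 = TRUE,  p31 = "LG", length_bp = 444, dna_frequency = 0.009),
    v("Amp42", "A", TRUE,  n33mer = 0, a3 = TRUE,  p31 = "LG", length_bp = 435, dna_frequency = 0.008),
    v("Amp43", "A", TRUE,  n33mer = 0, a3 = TRUE,  p31 = "LG", length_bp = 450, dna_frequency = 0.008),
    v("Amp44", "A", TRUE,  n33mer = 0, a3 = FALSE, p31 = NA,   length_bp = 438, dna_frequency = 0.007),
    v("Amp45", "A", TRUE,  n33mer = 0, a3 = TRUE,  p31 = "LG", length_bp = 453, dna_frequency = 0.005)
  ))
  family_design(variants, snp_rate = 0.01, seed = seed, name = "bw208_like")
}
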