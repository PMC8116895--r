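# Read-pair merging and quality filtering (expected errors, length).

#' Pipeline parameters
#'
#' Defaults are the study's printed values: minimum merged length 160 nt,
#' maximum expected errors 1.0, UNOISE alpha 2.0, 99% clustering identity,
#' and the high-confidence rule of >= 75 reads in >= 3 samples.
#'
#' @param min_merged_len minimum merged amplicon length (nt).
#' @param max_expected_errors expected-error filter threshold (inclusive).
#' @param unoise_alpha abundance-skew stringency of the denoiser.
#' @param cluster_identity greedy clustering identity in (0.5, 1].
#' @param min_reads,min_samples high-confidence support rule (inclusive).
#' @return list of class `gliadex_params`.
#' @export
pipeline_params <- function(min_merged_len = 160L, max_expected_errors = 1.0,
                            unoise_alpha = 2.0, cluster_identity = 0.99,
                            min_reads = 75L, min_samples = 3L) {
  stopifnot(min_merged_len > 0, max_expected_errors > 0, unoise_alpha > 0,
            cluster_identity > 0.5, cluster_identity <= 1,
            min_reads > 0, min_samples > 0)
  structure(list(min_merged_len = as.integer(min_merged_len),
                 max_expected_errors = max_expected_errors,
                 unoise_alpha = unoise_alpha,
                 cluster_identity = cluster_identity,
                 min_reads = as.integer(min_reads),
                 min_samples = as.integer(min_samples)),
            class = "gliadex_params")
}

#' Merge read pairs by best ungapped overlap
#'
#' The forward read is aligned without gaps against the reverse-complemented
#' mate over every candidate overlap of at least `min_overlap` bases; the
#' overlap maximizing matches (mismatches penalized) wins, provided its
#' mismatch fraction does not exceed `max_mismatch_frac`. In the overlap,
#' agreeing bases get posterior quality q1+q2 capped at Q45; disagreements
#' keep the higher-quality base with quality |q1-q2| floored at Q2. Pairs
#' with no acceptable overlap are rejected (status `no_overlap`), not
#' errors.
#'
#' @param fwd,fwd_qual forward sequences and Phred+33 quality strings.
#' @param rev,rev_qual reverse-mate sequences/qualities (raw orientation).
#' @param min_overlap minimum overlap length (default 16).
#' @param max_mismatch_frac maximum mismatch fraction in the overlap.
#' @return data.frame: id (if given), seq, qual, status, overlap,
#'   mismatches. Rejected rows carry NA seq/qual.
#' @export
merge_pairs <- function(fwd, fwd_qual, rev, rev_qual, min_overlap = 16L,
                        max_mismatch_frac = 0.1) {
  stopifnot(length(fwd) == length(rev),
            all(nchar(fwd) == nchar(fwd_qual)),
            all(nchar(rev) == nchar(rev_qual)),
            all(nchar(fwd) > 0), all(nchar(rev) > 0))
  rc <- revcomp(rev)
  rcq <- vapply(strsplit(rev_qual, ""), function(x)
    paste(rev(x), collapse = ""), character(1))
  res <- .cpp_merge_pairs(fwd, fwd_qual, rc, rcq, as.integer(min_overlap),
                          max_mismatch_frac, 45L, 2L, 33L)
  data.frame(seq = res$seq, qual = res$qual, status = res$status,
             overlap = res$overlap, mismatches = res$mismatches,
             stringsAsFactors = FALSE)
}

#' Expected errors of a read from its Phred qualities
#'
#' Sum over bases of `10^(-Q/10)`; an empty sequence has 0 expected
#' errors.
#'
#' @param qual Phred+33 quality strings (vectorized), or a numeric vector
#'   of Phred scores for a single read.
#' @return numeric vector of expected error counts.
#' @export
expected_errors <- function(qual) {
  if (is.numeric(qual)) {
    stopifnot(all(qual >= 0))
    return(sum(10^(-qual / 10)))
  }
  .cpp_expected_errors(qual, 33L)
}

#' Filter merged reads by length and expected errors
#'
#' Keeps reads with length >= `min_merged_len` and expected errors
#' <= `max_expected_errors` (both inclusive); input order is preserved and
#' per-reason rejection counts are reported.
#'
#' @param merged data.frame from [merge_pairs()] (rows with status other
#'   than "merged" are dropped and counted).
#' @param params a [pipeline_params()].
#' @return list: `reads` (retained rows), `log` (named counts: input,
#'   not_merged, too_short, too_many_ee, retained).
#' @export
filter_reads <- function(merged, params = pipeline_params()) {
  ok <- merged$status == "merged"
  len_ok <- ok & nchar(merged$seq) >= params$min_merged_len
  ee <- rep(NA_real_, nrow(merged))
  ee[len_ok] <- expected_errors(merged$qual[len_ok])
  # small epsilon so a read whose EE is exactly the threshold is retained
  # despite floating-point accumulation (the threshold is inclusive)
  keep <- len_ok & !is.na(ee) & ee <= params$max_expected_errors + 1e-9
  log <- c(input = nrow(merged), not_merged = sum(!ok),
           too_short = sum(ok & !len_ok),
           too_many_ee = sum(len_ok & !keep), retained = sum(keep))
  list(reads = merged[keep, , drop = FALSE], log = log)
}
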