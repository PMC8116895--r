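# Variant x sample abundance matrices: database mapping, high-confidence
# filtering and normalization.

#' Map denoised reads to an amplicon variant database
#'
#' Each unique sequence (weighted by its per-sample sizes) is assigned to
#' the best-identity database variant with identity >= `identity`; ties
#' are broken by database order and logged. Unassigned reads are counted
#' separately.
#'
#' @param uniques a [dereplicate()] or [denoise()] result (anything with
#'   `seq` and `sample_counts`).
#' @param database named character vector of variant sequences.
#' @param identity assignment threshold (default 0.99).
#' @return list of class `gliadex_abundance`: `counts` (variants x samples
#'   matrix, database order), `unassigned` (per-sample counts), `ties`
#'   (number of tied assignments), `assignment` (per-unique assigned
#'   variant id, named by sequence, NA when unassigned), `provenance`
#'   (character vector of transformations applied, here "raw").
#' @export
map_samples_to_database <- function(uniques, database, identity = 0.99) {
  stopifnot(length(database) > 0)
  vid <- names(database) %||% paste0("v", seq_along(database))
  counts <- uniques$sample_counts
  samples <- colnames(counts)
  mat <- matrix(0, length(database), length(samples),
                dimnames = list(vid, samples))
  unassigned <- setNames(numeric(length(samples)), samples)
  ties <- 0L
  assignment <- setNames(rep(NA_character_, length(uniques$seq)),
                         uniques$seq)
  for (i in seq_along(uniques$seq)) {
    ids <- seq_identity(uniques$seq[i], unname(database),
                        floor_identity = identity)
    ok <- !is.na(ids) & ids >= identity
    if (!any(ok)) {
      unassigned <- unassigned + counts[i, ]
      next
    }
    best <- max(ids[ok])
    hits <- which(ok & ids >= best - 1e-12)
    if (length(hits) > 1L) ties <- ties + 1L
    assignment[i] <- vid[hits[1]]
    mat[hits[1], ] <- mat[hits[1], ] + counts[i, ]
  }
  if (all(mat == 0))
    warning("no read mapped to the database at identity >= ", identity)
  structure(list(counts = mat, unassigned = unassigned, ties = ties,
                 assignment = assignment, provenance = "raw"),
            class = "gliadex_abundance")
}

#' Abundance matrix from denoised centroids (discovery mode)
#'
#' Wraps a [denoise()]/[cluster_centroids()] result into the same
#' abundance container used by database mapping.
#'
#' @param centroids a `gliadex_centroids`.
#' @return `gliadex_abundance` with centroid sequences as variant names.
#' @export
abundance_from_centroids <- function(centroids) {
  mat <- centroids$sample_counts
  rownames(mat) <- sprintf("zotu%03d", seq_len(nrow(mat)))
  structure(list(counts = mat,
                 unassigned = setNames(numeric(ncol(mat)), colnames(mat)),
                 ties = 0L, provenance = "raw",
                 sequences = setNames(centroids$seq, rownames(mat))),
            class = "gliadex_abundance")
}

#' High-confidence variant filter
#'
#' A variant is retained iff its raw count is at least `min_reads` in at
#' least `min_samples` distinct samples (both inclusive).
#'
#' @param abund a `gliadex_abundance` (raw counts).
#' @param min_reads,min_samples support rule (defaults 75 and 3).
#' @return the filtered `gliadex_abundance`, with `dropped` recording the
#'   removed variant ids.
#' @export
high_confidence_filter <- function(abund, min_reads = 75L, min_samples = 3L) {
  mat <- abund$counts
  keep <- rowSums(mat >= min_reads) >= min_samples
  abund$dropped <- rownames(mat)[!keep]
  abund$counts <- mat[keep, , drop = FALSE]
  if (!is.null(abund$sequences)) abund$sequences <- abund$sequences[keep]
  abund$provenance <- c(abund$provenance,
                        sprintf("high_confidence(>=%d reads in >=%d samples)",
                                min_reads, min_samples))
  abund
}

#' Normalize counts to the smallest sample, dilution factor and qPCR NF
#'
#' normalized(v, s) = raw(v, s) x (min sample total / total_s) x
#' dilution(s) / NF(s): reads are scaled to the sample with the lowest
#' read count, the pre-sequencing dilution is undone by multiplying with
#' the dilution factor, and the RT-qPCR normalization factor divides
#' (geNorm convention: normalized quantity = N0 / NF). The factors
#' commute; provenance records each.
#'
#' @param abund a `gliadex_abundance`.
#' @param dilution named per-sample dilution factors (> 0); default 1.
#' @param nf named per-sample qPCR normalization factors (> 0); default 1.
#' @return the `gliadex_abundance` with normalized `counts`.
#' @export
normalize_counts <- function(abund, dilution = NULL, nf = NULL) {
  mat <- abund$counts
  samples <- colnames(mat)
  totals <- colSums(mat)
  if (any(totals <= 0))
    stop("zero total reads in sample(s): ",
         paste(samples[totals <= 0], collapse = ", "))
  get_factor <- function(x, what) {
    if (is.null(x)) return(setNames(rep(1, length(samples)), samples))
    if (is.null(names(x)) && length(x) == length(samples)) names(x) <- samples
    if (!all(samples %in% names(x))) stop("missing ", what, " for some samples")
    if (any(x <= 0)) stop(what, " must be > 0")
    x[samples]
  }
  dil <- get_factor(dilution, "dilution factor")
  nfv <- get_factor(nf, "normalization factor")
  scale <- (min(totals) / totals) * dil / nfv
  abund$counts <- sweep(mat, 2L, scale, "*")
  abund$provenance <- c(abund$provenance, "rarefied_to_min_total",
                        "dilution_adjusted", "nf_adjusted")
  abund
}
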