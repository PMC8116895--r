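# Dereplication, UNOISE-style denoising with chimera removal, and greedy
# centroid clustering.

#' Dereplicate reads into unique sequences with per-sample sizes
#'
#' Exact-sequence grouping; total size equals the input read count.
#' Uniques are sorted by total size descending, ties broken
#' lexicographically by sequence.
#'
#' @param seqs character vector of reads.
#' @param sample_ids sample id per read (defaults to one pooled sample).
#' @return list of class `gliadex_uniques`: `seq`, `size`, and
#'   `sample_counts` (uniques x samples integer matrix).
#' @export
dereplicate <- function(seqs, sample_ids = NULL) {
  stopifnot(length(seqs) >= 1L)
  if (is.null(sample_ids)) sample_ids <- rep("pooled", length(seqs))
  stopifnot(length(sample_ids) == length(seqs))
  samples <- unique(sample_ids)
  tab <- table(factor(seqs), factor(sample_ids, levels = samples))
  counts <- matrix(as.integer(tab), nrow = nrow(tab),
                   dimnames = list(rownames(tab), samples))
  size <- rowSums(counts)
  ord <- order(-size, rownames(counts))
  structure(list(seq = rownames(counts)[ord], size = unname(size[ord]),
                 sample_counts = counts[ord, , drop = FALSE]),
            class = "gliadex_uniques")
}

# maximum edit distance at which a unique of size s can be absorbed by a
# centroid of size S under the UNOISE skew rule s/S <= 1/2^(alpha d + 1)
.skew_dmax <- function(s, S, alpha) {
  if (s >= S) return(-1L)
  as.integer(floor((log2(S / s) - 1) / alpha))
}

#' UNOISE-style denoising of dereplicated reads
#'
#' Greedy pass over uniques in decreasing-size order: a unique joins the
#' first (largest) existing centroid whose Levenshtein distance d
#' satisfies the abundance-skew rule size_unique / size_centroid <=
#' beta(d) = 1 / 2^(alpha d + 1); otherwise it founds a new centroid.
#' Singletons are discarded by default. A final two-parent chimera check
#' removes centroids exactly reconstructable as a single crossover of two
#' larger centroids.
#'
#' @param uniques a [dereplicate()] result.
#' @param alpha abundance-skew stringency (default 2).
#' @param min_size minimum unique size considered (default 2: singletons
#'   discarded).
#' @param remove_chimeras logical.
#' @return list of class `gliadex_centroids`: `seq`, `size`,
#'   `sample_counts`, `n_chimeras_removed`.
#' @export
denoise <- function(uniques, alpha = 2, min_size = 2L,
                    remove_chimeras = TRUE) {
  stopifnot(inherits(uniques, "gliadex_uniques"))
  keep <- uniques$size >= min_size
  seqs <- uniques$seq[keep]
  sizes <- uniques$size[keep]
  counts <- uniques$sample_counts[keep, , drop = FALSE]
  if (!length(seqs))
    return(structure(list(seq = character(0), size = integer(0),
                          sample_counts = counts, n_chimeras_removed = 0L),
                     class = "gliadex_centroids"))
  cent_idx <- 1L
  assign_to <- integer(length(seqs)); assign_to[1] <- 1L
  for (i in seq_along(seqs)[-1]) {
    joined <- FALSE
    for (ci in cent_idx) {
      dmax <- .skew_dmax(sizes[i], sizes[ci], alpha)
      if (dmax < 1L) next
      d <- .cpp_edit_one(seqs[i], seqs[ci], dmax)
      if (d >= 0L) { assign_to[i] <- ci; joined <- TRUE; break }
    }
    if (!joined) { cent_idx <- c(cent_idx, i); assign_to[i] <- i }
  }
  cseq <- seqs[cent_idx]
  csize <- vapply(cent_idx, function(ci) sum(sizes[assign_to == ci]), numeric(1))
  ccounts <- t(vapply(cent_idx, function(ci)
    colSums(counts[assign_to == ci, , drop = FALSE]),
    numeric(ncol(counts))))
  if (ncol(counts) == 1L) ccounts <- matrix(ccounts, ncol = 1L)
  colnames(ccounts) <- colnames(counts)
  n_chim <- 0L
  if (remove_chimeras && length(cseq) >= 3L) {
    is_chim <- vapply(seq_along(cseq), function(i) {
      larger <- which(csize > csize[i])
      if (length(larger) < 2L) return(FALSE)
      lcp <- .cpp_lcp_many(cseq[i], cseq[larger])
      lcs <- .cpp_lcs_many(cseq[i], cseq[larger])
      n <- nchar(cseq[i])
      # a crossover needs a left parent contributing a proper prefix and a
      # right parent (with matching length) contributing the rest
      full_left <- lcp >= n
      for (a in seq_along(larger)) {
        if (full_left[a]) next      # identical to a parent: not a chimera
        for (b in seq_along(larger)) {
          if (a == b || lcs[b] >= n) next
          if (nchar(cseq[larger[b]]) == n && lcp[a] >= 1L && lcs[b] >= 1L &&
              lcp[a] + lcs[b] >= n) return(TRUE)
        }
      }
      FALSE
    }, logical(1))
    n_chim <- sum(is_chim)
    cseq <- cseq[!is_chim]; csize <- csize[!is_chim]
    ccounts <- ccounts[!is_chim, , drop = FALSE]
  }
  ord <- order(-csize, cseq)
  structure(list(seq = cseq[ord], size = as.integer(csize[ord]),
                 sample_counts = ccounts[ord, , drop = FALSE],
                 n_chimeras_removed = n_chim),
            class = "gliadex_centroids")
}

#' Greedy centroid clustering at an identity threshold
#'
#' Sequences are visited in decreasing-size order; each joins the first
#' centroid with identity >= `identity` (see [seq_identity()] for the
#' identity definition), else founds a new cluster. At identity 1 this
#' reduces to dereplication of its input.
#'
#' @param seqs character vector of sequences (e.g. denoised centroids).
#' @param sizes abundance per sequence (default 1 each).
#' @param identity threshold in (0.5, 1].
#' @return data.frame: seq, size, cluster (centroid index per input row,
#'   in input order), is_centroid.
#' @export
cluster_centroids <- function(seqs, sizes = NULL, identity = 0.99) {
  stopifnot(length(seqs) >= 1L, identity > 0.5, identity <= 1)
  if (is.null(sizes)) sizes <- rep(1L, length(seqs))
  ord <- order(-sizes, seqs)
  cent <- integer(0)
  cluster <- integer(length(seqs))
  for (i in ord) {
    assigned <- FALSE
    if (length(cent)) {
      ids <- seq_identity(seqs[i], seqs[cent], floor_identity = identity)
      hit <- which(!is.na(ids) & ids >= identity)
      if (length(hit)) { cluster[i] <- cent[hit[1]]; assigned <- TRUE }
    }
    if (!assigned) { cent <- c(cent, i); cluster[i] <- i }
  }
  data.frame(seq = seqs, size = sizes, cluster = cluster,
             is_centroid = seq_along(seqs) == cluster,
             stringsAsFactors = FALSE)
}
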