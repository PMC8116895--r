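# Shared fixtures and independent oracles for the test suite.

# The default ground-truth family, built once per test run.
fixture_family <- local({
  fam <- NULL
  function() {
    if (is.null(fam)) fam <<- build_family(bw208_like_design())
    fam
  }
})

# Brute-force overlapping-substring counter: the independent oracle for
# scan_epitopes (explicit loop over every start position).
oracle_count_overlapping <- function(protein, motif) {
  n <- nchar(protein); k <- nchar(motif)
  if (k > n) return(0L)
  hits <- 0L
  for (s in seq_len(n - k + 1L))
    if (substr(protein, s, s + k - 1L) == motif) hits <- hits + 1L
  hits
}

# Row-scan oracle for the high-confidence filter.
oracle_high_confidence <- function(mat, min_reads, min_samples) {
  keep <- logical(nrow(mat))
  for (i in seq_len(nrow(mat))) {
    n_ok <- 0L
    for (j in seq_len(ncol(mat))) if (mat[i, j] >= min_reads) n_ok <- n_ok + 1L
    keep[i] <- n_ok >= min_samples
  }
  keep
}

# Naive O(n^3) average-linkage agglomeration: oracle for heatmap_order's
# dendrogram heights/merges.
oracle_average_linkage_heights <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(NA, NA); bh <- Inf
    for (i in seq_len(length(clusters) - 1L)) {
      for (j in (i + 1L):length(clusters)) {
        h <- mean(d[clusters[[i]], clusters[[j]]])
        if (h < bh) { bh <- h; best <- c(i, j) }
      }
    }
    heights <- c(heights, bh)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

random_protein <- function(n, alphabet = c("P", "Q", "L", "Y", "F", "S", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

CANONICAL_33MER <- "LQLQPFPQPQLPYPQPQLPYPQPQLPYPQPQPF"
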