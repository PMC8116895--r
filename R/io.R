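#' Read and write FASTA files
#'
#' Thin wrappers over Biostrings that return plain named character vectors
#' and understand the `;size=N` header dialect used for dereplicated and
#' denoised sequences (see [parse_size_headers()]).
#'
#' @param path file path (gzip handled transparently by Biostrings).
#' @return `read_fasta`: named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param seqs named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- names(seqs) %||% paste0("seq", seq_along(seqs))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Parse and format `;size=N` FASTA headers
#'
#' @param headers character vector like `"v1;size=42"`.
#' @return `parse_size_headers`: data.frame with columns `id` and `size`
#'   (size NA when absent); `format_size_headers`: character vector.
#' @export
parse_size_headers <- function(headers) {
  m <- regmatches(headers, regexec("^([^;]*)(?:;size=([0-9]+))?;?", headers))
  data.frame(
    id = vapply(m, `[`, character(1), 2L),
    size = as.integer(vapply(m, `[`, character(1), 3L)),
    stringsAsFactors = FALSE
  )
}

#' @rdname parse_size_headers
#' @param id,size vectors of ids and abundances.
#' @export
format_size_headers <- function(id, size) sprintf("%s;size=%d", id, as.integer(size))

#' Read and write FASTQ files
#'
#' Minimal 4-line FASTQ support with Phred+33 qualities kept as strings.
#' Gzip is auto-detected from the `.gz` extension. Records are validated:
#' sequence/quality length mismatches and malformed records raise an error
#' naming the offending record.
#'
#' @param path file path, optionally ending in `.gz`.
#' @return data.frame with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  if (length(lines) %% 4L != 0L)
    stop("malformed FASTQ (line count not a multiple of 4): ", path)
  n <- length(lines) / 4L
  id <- sub("^@", "", lines[seq(1L, by = 4L, length.out = n)])
  seq <- lines[seq(2L, by = 4L, length.out = n)]
  plus <- lines[seq(3L, by = 4L, length.out = n)]
  qual <- lines[seq(4L, by = 4L, length.out = n)]
  bad <- which(!startsWith(plus, "+"))
  if (length(bad))
    stop("malformed FASTQ record ", bad[1], " (line ", bad[1] * 4L - 1L,
         "): missing '+' separator")
  bad <- which(nchar(seq) != nchar(qual))
  if (length(bad))
    stop("FASTQ record ", bad[1], " ('", id[bad[1]],
         "'): sequence and quality lengths differ")
  if (any(grepl("[^ACGTN]", seq)))
    stop("FASTQ contains characters outside ACGTN: ", path)
  data.frame(id = id, seq = seq, qual = qual, stringsAsFactors = FALSE)
}

#' @rdname read_fastq
#' @param reads data.frame with columns `id`, `seq`, `qual`.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "seq", "qual") %in% names(reads)))
  if (any(nchar(reads$seq) != nchar(reads$qual)))
    stop("sequence and quality lengths differ")
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(paste0("@", reads$id, "\n", reads$seq, "\n+\n", reads$qual), con)
  invisible(path)
}

#' Read a tab-separated sample sheet
#'
#' Expected columns: `sample_id` plus any of `genotype`, `n_level`, `dpa`,
#' `block`, `dilution_factor`, `nf`, `fastq1`, `fastq2`.
#'
#' @param path TSV file path.
#' @return data.frame.
#' @export
read_sample_sheet <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!"sample_id" %in% names(x)) stop("sample sheet needs a 'sample_id' column")
  x
}

#' Write a data.frame as TSV
#' @param x data.frame.
#' @param path output path.
#' @export
write_tsv <- function(x, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
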