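# Paired-end amplicon read simulation from a variant database.

#' Configure the paired-end read simulator
#'
#' @param depth_per_sample read pairs per sample (> 0).
#' @param read_length read length in nt (default 300, i.e. 2x300 chemistry).
#' @param per_base_error substitution probability per base, in [0, 0.05].
#' @param chimera_rate probability that a read pair derives from a
#'   single-crossover two-parent chimera instead of a single variant.
#' @param seed integer seed.
#' @return list of class `gliadex_read_sim_config`.
#' @export
read_sim_config <- function(depth_per_sample = 100000L, read_length = 300L,
                            per_base_error = 0.001, chimera_rate = 0,
                            seed = 1L) {
  stopifnot(depth_per_sample > 0, read_length > 0,
            per_base_error >= 0, per_base_error <= 0.05,
            chimera_rate >= 0, chimera_rate < 1)
  structure(list(depth_per_sample = as.integer(depth_per_sample),
                 read_length = as.integer(read_length),
                 per_base_error = per_base_error,
                 chimera_rate = chimera_rate, seed = as.integer(seed)),
            class = "gliadex_read_sim_config")
}

phred_from_error <- function(p) {
  if (p <= 0) return(40L)
  as.integer(max(2L, min(40L, round(-10 * log10(p)))))
}

add_substitutions <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  lens <- nchar(seqs)
  nerr <- rbinom(length(seqs), lens, rate)
  hit <- which(nerr > 0L)
  bases <- c("A", "C", "G", "T")
  for (i in hit) {
    pos <- sample.int(lens[i], nerr[i])
    for (p in pos) {
      cur <- substr(seqs[i], p, p)
      substr(seqs[i], p, p) <- sample(setdiff(bases, cur), 1L)
    }
  }
  seqs
}

#' Simulate paired-end amplicon reads
#'
#' Read pairs are drawn multinomially from per-sample variant abundances;
#' the forward read covers the amplicon 5' end and the reverse read the
#' reverse complement of the 3' end, each with independent substitution
#' errors at `per_base_error` and uniform Phred qualities
#' `Q = -10 log10(p)` (Q40 for error-free simulation). With probability
#' `chimera_rate` a pair is generated from a two-parent single-crossover
#' chimera. Deterministic given `config$seed`.
#'
#' @param database named character vector of amplicon sequences.
#' @param per_sample_abundances numeric matrix (variants x samples) of
#'   non-negative weights; column names become sample ids. A vector is
#'   treated as a single sample.
#' @param config a [read_sim_config()].
#' @param out_dir optional; when given, gzipped FASTQ pairs
#'   (`<sample>_R1.fastq.gz` / `_R2.fastq.gz`) and a sample sheet are
#'   written there.
#' @return named list per sample: list(fwd, rev) data.frames with columns
#'   id, seq, qual. Read ids carry `variant=<id>` truth tags.
#' @export
simulate_reads <- function(database, per_sample_abundances, config,
                           out_dir = NULL) {
  stopifnot(length(database) > 0)
  if (is.null(dim(per_sample_abundances)))
    per_sample_abundances <- matrix(per_sample_abundances,
                                    ncol = 1L, dimnames = list(NULL, "S1"))
  if (nrow(per_sample_abundances) != length(database))
    stop("abundance rows must match the database")
  if (any(per_sample_abundances < 0)) stop("abundances must be >= 0")
  if (config$read_length > min(nchar(database)))
    stop("configuration error: read_length (", config$read_length,
         ") exceeds the shortest amplicon (", min(nchar(database)), ")")
  samples <- colnames(per_sample_abundances) %||%
    paste0("S", seq_len(ncol(per_sample_abundances)))
  vid <- names(database) %||% paste0("v", seq_along(database))
  q <- phred_from_error(config$per_base_error)
  R <- config$read_length

  with_seed(config$seed, {
    out <- lapply(seq_along(samples), function(si) {
      ab <- per_sample_abundances[, si]
      counts <- as.vector(rmultinom(1L, config$depth_per_sample, ab))
      src <- rep.int(seq_along(database), counts)
      src <- src[sample.int(length(src))]
      templ <- unname(database[src])
      label <- vid[src]
      if (config$chimera_rate > 0 && length(database) > 1L) {
        is_chim <- runif(length(src)) < config$chimera_rate
        for (i in which(is_chim)) {
          cand <- seq_along(database)[-src[i]]
          p2 <- if (length(cand) == 1L) cand else
            sample(cand, 1L, prob = ab[cand] + 1e-12)
          l1 <- nchar(database[src[i]]); l2 <- nchar(database[p2])
          x <- sample(seq(2L, min(l1, l2) - 1L), 1L)
          templ[i] <- paste0(substr(database[src[i]], 1L, x),
                             substr(database[p2], x + 1L, l2))
          label[i] <- sprintf("chimera:%s:%s:%d", vid[src[i]], vid[p2], x)
        }
      }
      fwd <- add_substitutions(substr(templ, 1L, R), config$per_base_error)
      rev3 <- substr(templ, nchar(templ) - R + 1L, nchar(templ))
      rev <- add_substitutions(revcomp(rev3), config$per_base_error)
      ids <- sprintf("%s:%06d;variant=%s", samples[si], seq_along(templ), label)
      qual <- strrep(intToUtf8(q + 33L), R)
      list(fwd = data.frame(id = ids, seq = fwd, qual = qual,
                            stringsAsFactors = FALSE),
           rev = data.frame(id = ids, seq = rev, qual = qual,
                            stringsAsFactors = FALSE))
    })
    names(out) <- samples
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      for (s in samples) {
        write_fastq(out[[s]]$fwd, file.path(out_dir, paste0(s, "_R1.fastq.gz")))
        write_fastq(out[[s]]$rev, file.path(out_dir, paste0(s, "_R2.fastq.gz")))
      }
      write_tsv(data.frame(sample_id = samples,
                           fastq1 = paste0(samples, "_R1.fastq.gz"),
                           fastq2 = paste0(samples, "_R2.fastq.gz")),
                file.path(out_dir, "sample_sheet.tsv"))
    }
    out
  })
}
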