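# Realization of a family design into nucleotide sequences with verified
# ground-truth annotations.

# Designed epitope counts for one design row, over the default table names.
designed_epitope_counts <- function(row) {
  core_key <- as.character(row$n33mer)
  if (!core_key %in% names(.CORE_COUNTS))
    stop("constraint error for variant '", row$variant_id,
         "': ", row$n33mer, " 33-mer copies is not realizable ",
         "(supported: 0,1,2,3,4,6)")
  counts <- c(.CORE_COUNTS[[core_key]],
              "DQ2.5-glia-a3" = as.integer(isTRUE(row$a3)),
              "p31-43_LG" = as.integer(identical(row$p31, "LG")),
              "p31-43_LP" = as.integer(identical(row$p31, "LP")))
  counts
}

# Amino-acid middle region (between the flanks): fixed-width slots for
# p31-43, the 33-mer repeat and DQ2.5-glia-a3 (absent epitopes become
# same-width motif-dead fillers), followed by a repeat pad to the target
# length.
middle_aa <- function(row) {
  core_key <- as.character(row$n33mer)
  if (!core_key %in% names(.CORE_INSERTS))
    stop("constraint error for variant '", row$variant_id,
         "': ", row$n33mer, " 33-mer copies is not realizable ",
         "(supported: 0,1,2,3,4,6)")
  segs <- c(
    if (is.na(row$p31)) .P31_FILLER else .P31_PEPTIDES[[row$p31]],
    .CORE_INSERTS[[core_key]],
    if (row$a3) .A3_PEPTIDE else .A3_FILLER
  )
  ins <- paste(segs, collapse = .SEG_LINKER)
  n_aa <- row$length_bp / 3L
  pad_aa <- n_aa - .N_FLANK_CODONS - .C_FLANK_CODONS - nchar(ins)
  if (pad_aa < 0)
    stop("constraint error for variant '", row$variant_id,
         "': epitope content does not fit length_bp = ", row$length_bp)
  pad <- if (pad_aa > 0)
    substr(strrep(.PAD_UNIT, ceiling(pad_aa / nchar(.PAD_UNIT))), 1L, pad_aa)
  else ""
  paste0(ins, pad)
}

split_codons <- function(nt) {
  n <- nchar(nt) %/% 3L
  substring(nt, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

# apply a third-position substitution to codon index i of a codon vector
mutate_third <- function(codons, idx, bases) {
  for (k in seq_along(idx)) {
    cd <- codons[idx[k]]
    substr(cd, 3L, 3L) <- bases[k]
    codons[idx[k]] <- cd
  }
  codons
}

#' Build a ground-truth amplicon family
#'
#' Realizes every [variant_design()] of a [family_design()] into a
#' nucleotide sequence: shared flanks carrying a 12-site subgenome tag and
#' a per-variant barcode of third-codon-position substitutions, an epitope
#' region assembled from motif inserts, a P/Q-rich repeat pad to the target
#' length, and - for pseudogenes - one premature in-frame stop codon
#' downstream of the epitope region. The build verifies its own output:
#' realized epitope counts must equal the design exactly (via
#' [scan_epitopes()]), pseudogene status must match, and every pair of
#' variants must differ by at least 7 substitutions (identity <= 98.5%, so
#' 99%-identity clustering cannot merge distinct variants); a variant whose
#' barcode collides is redrawn, and a collision persisting past the retry
#' budget is a generation error.
#'
#' @param design a `gliadex_family_design`, e.g. [bw208_like_design()].
#' @param max_retries barcode redraw budget per variant pair.
#' @return object of class `gliadex_family`: list with `sequences` (named
#'   nucleotide vector), `truth` (annotation data.frame with designed
#'   epitope counts), `template_cds` (full-length gene-like reference
#'   beginning at ATG), `amplicon_start` (1-based window start in the
#'   template), `exemplars` (one truth sequence per genome, the per-genome
#'   medoid) and `design`.
#' @export
build_family <- function(design, max_retries = 60L) {
  stopifnot(inherits(design, "gliadex_family_design"))
  variants <- design$variants
  n <- nrow(variants)

  with_seed(design$seed, {
    # shared reference flanks (codon vectors)
    nflank <- sample(.FLANK_CODONS, .N_FLANK_CODONS, replace = TRUE)
    cflank <- sample(.FLANK_CODONS, .C_FLANK_CODONS, replace = TRUE)
    signal <- sample(.FLANK_CODONS, 20L, replace = TRUE)

    # subgenome tag: genome-specific third base at 12 fixed N-flank codons
    tag_bases <- lapply(.GENOME_TAG_CODONS, function(i) {
      ref <- substr(nflank[i], 3L, 3L)
      alts <- setdiff(c("A", "C", "G", "T"), ref)
      setNames(alts[1:3], c("A", "B", "D"))
    })

    # barcode pool: flank third positions not used by tags or the stop zone
    pool <- rbind(
      data.frame(flank = "N", codon = setdiff(seq_len(.N_FLANK_CODONS),
                                              .GENOME_TAG_CODONS)),
      data.frame(flank = "C", codon = setdiff(seq_len(.C_FLANK_CODONS),
                                              .STOP_ZONE))
    )

    apply_genome_tag <- function(codons, genome) {
      for (k in seq_along(.GENOME_TAG_CODONS)) {
        i <- .GENOME_TAG_CODONS[k]
        substr(codons[i], 3L, 3L) <- tag_bases[[k]][[genome]]
        codons[i] <- codons[i]
      }
      codons
    }

    draw_barcode <- function() {
      idx <- sample(nrow(pool), .N_BARCODE)
      bases <- vapply(idx, function(j) {
        i <- pool$codon[j]
        ref <- if (pool$flank[j] == "N") substr(nflank[i], 3L, 3L)
               else substr(cflank[i], 3L, 3L)
        sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
      }, character(1))
      list(idx = idx, bases = bases)
    }

    draw_snps <- function() {
      hit <- which(runif(nrow(pool)) < design$snp_rate)
      bases <- vapply(hit, function(j) {
        i <- pool$codon[j]
        ref <- if (pool$flank[j] == "N") substr(nflank[i], 3L, 3L)
               else substr(cflank[i], 3L, 3L)
        sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
      }, character(1))
      list(idx = hit, bases = bases)
    }

    realize <- function(row, barcode, snps, stop_pick) {
      nf <- apply_genome_tag(nflank, row$genome)
      cf <- cflank
      muts <- list(barcode, snps)
      for (m in muts) {
        if (!length(m$idx)) next
        sel_n <- m$idx[pool$flank[m$idx] == "N"]
        sel_c <- m$idx[pool$flank[m$idx] == "C"]
        nf <- mutate_third(nf, pool$codon[sel_n], m$bases[match(sel_n, m$idx)])
        cf <- mutate_third(cf, pool$codon[sel_c], m$bases[match(sel_c, m$idx)])
      }
      if (row$is_pseudogene) cf[stop_pick$codon] <- stop_pick$stop
      paste0(paste(nf, collapse = ""), encode_aa(middle_aa(row)),
             paste(cf, collapse = ""))
    }

    barcodes <- replicate(n, draw_barcode(), simplify = FALSE)
    snps <- replicate(n, draw_snps(), simplify = FALSE)
    stops <- replicate(n, list(codon = sample(.STOP_ZONE, 1L),
                               stop = sample(c("TAA", "TAG", "TGA"), 1L)),
                       simplify = FALSE)

    seqs <- vapply(seq_len(n), function(i)
      realize(variants[i, ], barcodes[[i]], snps[[i]], stops[[i]]), character(1))

    # enforce the pairwise divergence floor; redraw the later variant's
    # barcode on collision
    band <- 80L
    for (round in seq_len(max_retries)) {
      collided <- FALSE
      for (j in seq_len(n)[-1]) {
        d <- .cpp_edit_many(seqs[j], seqs[seq_len(j - 1L)], band)
        bad <- which(d >= 0L & d < .MIN_PAIR_DIFF)
        if (length(bad)) {
          collided <- TRUE
          barcodes[[j]] <- draw_barcode()
          seqs[j] <- realize(variants[j, ], barcodes[[j]], snps[[j]], stops[[j]])
        }
      }
      if (!collided) break
      if (round == max_retries)
        stop("generation error: pairwise identity collision persists after ",
             max_retries, " retries")
    }

    names(seqs) <- variants$variant_id

    # template: ATG + signal-like region + reference amplicon window + stop
    template_window <- paste0(
      paste(nflank, collapse = ""),
      encode_aa(substr(strrep(.PAD_UNIT, 9L), 1L,
                       150L - .N_FLANK_CODONS - .C_FLANK_CODONS)),
      paste(cflank, collapse = "")
    )
    template_cds <- paste0("ATG", paste(signal, collapse = ""),
                           template_window, "TAA")
    amplicon_start <- 3L + 20L * 3L + 1L  # 1-based: position 64

    # verify: realized epitope counts equal the design, stop status matches
    et <- default_epitope_table()
    truth_counts <- matrix(0L, n, nrow(et), dimnames = list(variants$variant_id, et$name))
    for (i in seq_len(n)) {
      prot <- translate_amplicon(seqs[i], frame_offset = amplicon_start %% 3L)
      got <- scan_epitopes(prot, et)
      want <- designed_epitope_counts(variants[i, ])
      want <- setNames(as.integer(want[et$name]), et$name)
      want[is.na(want)] <- 0L
      if (!identical(as.integer(got[et$name]), unname(want)))
        stop("generation error: realized epitope counts for '",
             variants$variant_id[i], "' differ from the design")
      has_stop <- grepl("*", prot, fixed = TRUE)
      if (has_stop != variants$is_pseudogene[i])
        stop("generation error: stop-codon status mismatch for '",
             variants$variant_id[i], "'")
      truth_counts[i, ] <- got[et$name]
    }

    truth <- variants
    truth$n33mer_copies <- apply(truth_counts, 1L, count_33mer_copies, epitope_table = et)
    truth$p31_present <- truth_counts[, "p31-43_LG"] + truth_counts[, "p31-43_LP"] > 0
    truth$type_label <- apply(truth_counts, 1L, classify_type, epitope_table = et)
    truth <- cbind(truth, as.data.frame(truth_counts, check.names = FALSE))

    # per-genome medoid exemplars (truth sequences)
    exemplars <- vapply(split(seq_len(n), variants$genome), function(idx) {
      if (length(idx) == 1L) return(seqs[idx])
      dm <- sapply(idx, function(i) {
        d <- .cpp_edit_many(seqs[i], seqs[idx], band)
        d[d < 0L] <- band + 1L
        max(d)
      })
      seqs[idx[which.min(dm)]]
    }, character(1))

    structure(list(sequences = seqs, truth = truth,
                   template_cds = template_cds,
                   amplicon_start = amplicon_start,
                   exemplars = exemplars, design = design),
              class = "gliadex_family")
  })
}

#' @export
print.gliadex_family <- function(x, ...) {
  cat("gliadex_family '", x$design$name, "': ", length(x$sequences),
      " variants (", sum(x$truth$is_pseudogene), " pseudogenes), lengths ",
      min(nchar(x$sequences)), "-", max(nchar(x$sequences)), " nt\n", sep = "")
  invisible(x)
}

#' Write a family to disk (database FASTA + truth TSV)
#'
#' @param family a `gliadex_family`.
#' @param out_dir output directory.
#' @return invisibly, the paths written.
#' @export
write_family <- function(family, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(out_dir, "database.fasta")
  tsv <- file.path(out_dir, "truth.tsv")
  write_fasta(family$sequences, fa)
  write_tsv(family$truth, tsv)
  write_fasta(family$exemplars, file.path(out_dir, "genome_exemplars.fasta"))
  writeLines(c(">template_cds", family$template_cds),
             file.path(out_dir, "template_cds.fasta"))
  invisible(c(fa, tsv))
}
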