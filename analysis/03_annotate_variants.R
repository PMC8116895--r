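#!/usr/bin/env Rscript
# Annotate the recovered variants (from 02) against the family template:
# reading frame, pseudogene status, CD-epitope counts, 33-mer copy
# number, type-1 subtype and subgenome of origin.

suppressMessages(library(gliadex))

family <- build_family(bw208_like_design())
rec_path <- "results/recovered_variants.fasta"
seqs <- if (file.exists(rec_path)) {
  x <- read_fasta(rec_path)
  setNames(unname(x), parse_size_headers(names(x))$id)
} else {
  cat("note: run analysis/02_recover_variants.R first;",
      "annotating the ground-truth database instead\n")
  family$sequences
}

ann <- annotate_variants(seqs, reference_cds = family$template_cds,
                         exemplars = family$exemplars)
dir.create("results", showWarnings = FALSE)
write_tsv(ann, "results/annotation.tsv")

cat("variants annotated:", nrow(ann), "\n")
cat("pseudogenes (in-frame stop):", sum(ann$is_pseudogene), "\n")
cat("six-copy 33-mer variants:", sum(ann$n33mer_copies == 6), "\n")
p31 <- ann$`p31-43_LG` + ann$`p31-43_LP` > 0
cat("variants with p31-43:", sum(p31), "\n")
cat("\nsubtype x genome (putative genes):\n")
print(table(ann$type_label[!ann$is_pseudogene], ann$genome[!ann$is_pseudogene]))
cat("\nwritten: results/annotation.tsv\n")
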