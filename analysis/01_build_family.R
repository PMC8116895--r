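#!/usr/bin/env Rscript
# Build the default BW208-like ground-truth amplicon family and summarize
# its epitope structure: 45 variants (20 pseudogenes), one genome-D
# putative gene with the full six-copy 33-mer complement at 2.4% DNA
# frequency, six genome-B putative genes without 33-mer epitopes, and
# p31-43 in 38/45 variants.

suppressMessages(library(gliadex))

family <- build_family(bw208_like_design())
dir.create("results", showWarnings = FALSE)
write_family(family, "results/family")

tr <- family$truth
cat("variants:", nrow(tr), " pseudogenes:", sum(tr$is_pseudogene), "\n")
cat("amplicon lengths:", min(tr$length_bp), "-", max(tr$length_bp), "nt\n")
cat("per-genome counts:\n")
print(table(tr$genome, ifelse(tr$is_pseudogene, "pseudogene", "putative")))
cat("\n33-mer copy-number spectrum (putative genes):\n")
print(table(tr$n33mer_copies[!tr$is_pseudogene]))
cat("\ntype-1 subtype labels (putative genes):\n")
print(table(tr$type_label[!tr$is_pseudogene]))
cat("\np31-43 present in", sum(tr$p31_present), "of", nrow(tr),
    "variants (", sum(tr$p31_present & !tr$is_pseudogene), "of",
    sum(!tr$is_pseudogene), "putative genes)\n")
six <- tr[tr$n33mer_copies == 6, ]
cat("full 33-mer variant:", six$variant_id, "genome", six$genome,
    "frequency", six$dna_frequency, "\n")
cat("\nwritten: results/family/{database.fasta,truth.tsv,genome_exemplars.fasta}\n")
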