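#!/usr/bin/env Rscript
# Expression analysis over the genotype x nitrogen x DPA design:
# simulate cDNA amplicon reads from the designed true abundances, map
# them to the DNA variant database, normalize (smallest sample, dilution
# factor, qPCR NF), then aggregate by genome, compute high/low-N fold
# changes, test the N contrasts (ANOVA + two-sided Dunnett), and order
# the variant heatmap by Spearman-distance clustering; PCA with the
# per-genotype aggregates.

suppressMessages(library(gliadex))

family <- build_family(bw208_like_design())
truth <- family$truth
expr <- simulate_expression(expression_design(family, seed = 1))
sheet <- expr$sample_sheet
nf_tab <- tryCatch(read.delim("results/qpcr_nf.tsv"), error = function(e) NULL)
nf <- if (is.null(nf_tab)) setNames(rep(1, nrow(sheet)), sheet$sample_id) else
  setNames(nf_tab$nf, nf_tab$sample_id)

# Sequencing counts are compositional: every library is diluted to the
# same amplicon input before PCR (the study dilutes by target Cq), so the
# per-sample dilution factor - here the target's qPCR N0 from the
# quantification step - is what restores the absolute scale during
# normalization.
quant_tab <- tryCatch(read.delim("results/qpcr_quantification.tsv"),
                      error = function(e) NULL)
dilution <- if (!is.null(quant_tab)) {
  tgt <- quant_tab[quant_tab$target == "alpha_gli", ]
  setNames(tgt$N0 / min(tgt$N0), tgt$sample)
} else {
  tot <- tapply(expr$abundance$abundance, expr$abundance$sample_id, sum)
  setNames(as.vector(tot / min(tot)), names(tot))
}
sheet$dilution_factor <- unname(dilution[sheet$sample_id])

# reduced-depth cDNA sequencing of every design cell
ab_mat <- with(expr$abundance,
               tapply(abundance, list(variant_id, sample_id), sum))
ab_mat <- ab_mat[truth$variant_id, sheet$sample_id]
reads <- simulate_reads(family$sequences, ab_mat,
                        read_sim_config(depth_per_sample = 6000L,
                                        per_base_error = 0.001, seed = 11))
merged <- lapply(reads, function(rp) {
  m <- merge_pairs(rp$fwd$seq, rp$fwd$qual, rp$rev$seq, rp$rev$qual)
  filter_reads(m)$reads$seq
})
u <- dereplicate(unlist(merged, use.names = FALSE),
                 rep(names(merged), vapply(merged, length, integer(1))))
mapped <- map_samples_to_database(u, family$sequences)
mapped$counts <- mapped$counts[, sheet$sample_id]
cat("cDNA reads mapped:", sum(mapped$counts), " unassigned:",
    sum(mapped$unassigned), "\n")

norm <- normalize_counts(mapped,
                         dilution = setNames(sheet$dilution_factor, sheet$sample_id),
                         nf = nf[sheet$sample_id])
long <- data.frame(sample_id = rep(colnames(norm$counts),
                                   each = nrow(norm$counts)),
                   variant_id = rep(rownames(norm$counts),
                                    ncol(norm$counts)),
                   abundance = as.vector(norm$counts))
long <- merge(long, sheet[, c("sample_id", "genotype", "n_level", "dpa")],
              by = "sample_id")

agg <- aggregate_abundance(long[!long$variant_id %in%
                                  truth$variant_id[truth$is_pseudogene], ],
                           truth, keys = c("genome", "genotype", "n_level"))
fc <- fold_change(agg, keys = c("genome", "genotype"))
cat("\nhigh/low-N expression ratios per genome (putative genes):\n")
print(transform(fc, fold_change = round(fold_change, 2)))

# N-contrast tests per genotype on log per-sample aggregates
per_sample <- aggregate_abundance(long, truth,
                                  keys = c("sample_id", "genotype", "n_level"))
cat("\nhigh-vs-low N contrasts (two-sided Dunnett vs low N):\n")
for (gt in unique(per_sample$genotype)) {
  g <- per_sample[per_sample$genotype == gt, ]
  g$cell <- paste(g$genotype, g$n_level, sep = ".")
  r <- compare_groups(log(g$abundance), g$cell, paste0(gt, ".low"),
                      n_mc = 1e5, seed = 3)
  cat(sprintf("  %-22s p = %.4f %s\n", gt, r$dunnett$p_adjusted,
              ifelse(r$dunnett$p_adjusted <= 0.05, "(significant)", "")))
}

# heatmap ordering and PCA
hm <- heatmap_order(norm$counts)
agg_cell <- aggregate_abundance(long, truth,
                                keys = c("genotype", "n_level", "variant_id"))
wide <- with(agg_cell, tapply(abundance, list(paste(genotype, n_level, sep = "."),
                                              variant_id), sum))
pca <- pca_with_supplementary(wide)
cat("\nPCA variance explained (PC1, PC2):",
    round(pca$var_explained[1:2], 3), "\n")

dir.create("results", showWarnings = FALSE)
write_tsv(fc, "results/fold_change_by_genome.tsv")
write_tsv(data.frame(variant = rownames(norm$counts)[hm$row_order]),
          "results/heatmap_row_order.tsv")
write_tsv(data.frame(pc = seq_along(pca$var_explained),
                     var_explained = pca$var_explained),
          "results/pca_variance.tsv")
write_tsv(per_sample, "results/normalized_per_sample.tsv")
cat("written: results/{fold_change_by_genome,heatmap_row_order,pca_variance,normalized_per_sample}.tsv\n")
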