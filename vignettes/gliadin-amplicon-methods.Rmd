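---
title: "Methods: alpha-gliadin amplicon variants, CD epitopes and expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: alpha-gliadin amplicon variants, CD epitopes and expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`gliadex` analyses a targeted amplicon of the wheat alpha-gliadin gene
family that spans the main celiac-disease (CD) immunogenic region: the
p31-43 innate peptide, the 33-mer (six overlapping copies of the
DQ2.5-glia-alpha1a/alpha1b/alpha2 T-cell epitopes) and the flanking
DQ2.5-glia-alpha3 epitope. The package covers five stages — synthetic
ground truth, read-level variant recovery, variant annotation, RT-qPCR
quantification, and expression statistics — each exposed as plain
functions so the numbered drivers under `analysis/`, the test suite and
`scripts/acceptance.R` all exercise the same code.

# Variant recovery from paired-end reads

**Merging.** Each 2x300 pair is merged by the best ungapped overlap of
the forward read against the reverse-complemented mate (minimum overlap
16 nt, mismatch fraction <= 0.1). Agreeing overlap bases get posterior
quality `min(45, q1 + q2)`; disagreements keep the higher-quality base
with quality `max(2, |q1 - q2|)`. With equal qualities the forward base
is kept — an arbitrary but fixed tie-break. A pair with no acceptable
overlap is a rejection state, not an error.

**Filtering.** Reads are kept iff merged length >= 160 nt and expected
errors `EE = sum(10^(-Q/10)) <= 1.0`. Both thresholds are inclusive
("at least"/"at most" semantics), and the EE comparison carries a 1e-9
epsilon so a read whose EE is exactly 1.0 survives floating-point
accumulation. Note that EE is computed from the *posterior* qualities:
an overlap disagreement between two equal-quality bases contributes
~0.63 expected errors, so reads with two or more unresolved overlap
conflicts are typically discarded.

**Denoising.** Filtered reads are pooled across samples and
dereplicated exactly (sizes conserved; ordering by total size, ties
lexicographic). A greedy UNOISE-style pass in decreasing-size order
lets a unique of size *s* join the first centroid of size *S* whose
Levenshtein distance *d* satisfies the abundance-skew rule
`s/S <= beta(d) = 1 / 2^(alpha d + 1)` with `alpha = 2`; otherwise it
founds a centroid. Singletons are discarded (the conventional default;
with substitution-only errors they are overwhelmingly error reads).
Finally, a centroid is removed as chimeric when it is *exactly*
reconstructable as a single crossover of two larger centroids — the
same two-parent model the read simulator uses, which is the simplest
form such a detector can catch.

**Clustering and support.** Denoised centroids are clustered greedily
at 99% identity. Identity between sequences of lengths `n1`, `n2` is
defined as `1 - d / max(n1, n2)` with *d* the unit-cost (Levenshtein)
global-alignment distance: matching columns over alignment columns,
i.e. 199/200 = 0.995 and 197/200 = 0.985 for substitution-only pairs.
Distances are computed with a banded dynamic program (Rcpp): when *d*
exceeds the band implied by the identity floor the pair is certainly
below threshold, which keeps full-depth runs fast. The final
variant-by-sample table keeps a variant iff it has >= 75 reads in >= 3
distinct samples (inclusive), read as per-sample counts, matching
USEARCH-style otutab filtering.

**Database mapping.** For cDNA samples, uniques are assigned (weighted
by per-sample sizes) to the best-identity database variant at >= 99%;
ties go to the earlier database entry and are logged; unassigned reads
are counted separately.

# Annotation

**Frame.** `frame_offset` is the (1-based) start position of the
variant in the reference CDS, mod 3 — so a fragment starting at
position 91 has offset 1 and is codon-aligned; translation skips
`(1 - offset) mod 3` bases. The start is found by local alignment,
extrapolated to the variant's first base so that end clipping cannot
shift the frame; below 70% alignment identity the frame maximizing the
longest stop-free ORF is used instead.

**Pseudogenes.** A variant is a pseudogene iff its translation contains
any stop codon; because the amplicon truncates the gene, a stop even at
the final translated codon is premature. Positions are reported 1-based
in amino-acid coordinates; translation table 1.

**Epitopes.** Motifs are counted as exact, possibly overlapping
substring matches on the native (Q-form) protein — deamidation (Q->E)
is deliberately not modeled since genomic/transcript sequences encode
Q. No motif contains a stop, so matches never span one. The default
motif table (`inst/extdata/epitopes.tsv`) is literature-derived
configuration data, never hard-coded: the three 33-mer constituents,
DQ2.5-glia-alpha3, and both major p31-43 forms (LG-/LP-type). p31-43 is
categorized as an innate peptide and does not count toward CD-epitope
status, following its "non-immunodominant" role.

**Subtype.** The 33-mer copy number (sum over constituent epitopes)
maps to type-1 subtypes: 1 -> 1.1-1, 2 -> 1.1-2, 4 -> 1.2-4, 6 ->
1.3-6; other positive counts -> `type1_other`; zero copies with
DQ2.5-glia-alpha3 -> `non_type1`; zero DQ2.5-class epitopes ->
`no_cd_epitope`.

**Genome.** Nearest-exemplar classification against genome-labeled
truth sequences by the same identity definition, with a 90% identity
floor and a 0.5-point tie margin (ties -> `unassigned`). The method
behind the published genome addressing is not described at this level
of detail anywhere we can implement from, so this documented
stand-in - with truth exemplars for synthetic data - is the package's
own design.

# RT-qPCR quantification

**Efficiency.** Per well, the baseline is first estimated as the mean
fluorescence of cycles 3-8 lying below 5% of the curve maximum; the
window of 4-6 consecutive cycles (above baseline, below 90% of the
maximum) maximizing the r-squared of `log10(F - b)` vs cycle is
selected; the baseline is then refined by a 1-D search within the
window maximizing that r-squared, which makes noiseless exponential
curves recover E exactly. `E = 10^slope`. Estimates with r-squared <
0.99 or outside (1, 2.2] are flagged, never silently altered.

**Cq and N0.** Cq is the fractional cycle where the curve crosses a
threshold, interpolated linearly in log fluorescence; a threshold never
reached yields NA with an `undefined` flag. One common threshold per
target is placed at the geometric middle of the exponential windows of
that target's wells, keeping N0 comparable within a target. N0 is the
literal formula `threshold / E^Cq`.

**geNorm.** Gene stability `M_j` is the mean over other genes *k* of
the SD across samples of `log2(expr_j / expr_k)`; the least stable gene
is excluded iteratively; `V(n/n+1)` is the SD across samples of
`log2(NF_n / NF_{n+1})` where `NF_n` is the geometric mean of the *n*
most stable genes. With only three reference genes only V(2/3) exists;
it is reported, not auto-thresholded at 0.15. Normalization factors are
rescaled so their geometric mean across samples is 1 (geNorm's manual
convention); normalized expression is `N0 / NF`. NF is computed per
sample (whether the original workflow bulked replicates before or after
NF is not recoverable; per-sample is the documented choice).

# Normalization of read counts

`normalized(v, s) = raw(v, s) x (min_t total_t / total_s) x
dilution(s) / NF(s)`: reads are scaled to the smallest sample, the
pre-sequencing dilution (each library diluted by target Cq to equal
amplicon input) is undone by multiplying with the dilution factor, and
the qPCR normalization factor divides. The factors commute;
`provenance` records each applied step in order. Because fixed-depth
sequencing is purely compositional, the dilution factor is what
restores the absolute scale — `analysis/05_expression_analysis.R`
derives it from the target's qPCR N0, which is the simulated analogue
of diluting by Cq.

# Expression statistics

Aggregation is group-and-sum over any keys (genome, subtype, gene
class, genotype, N level, DPA), with an exact conservation invariant.
Fold change is the elementwise high/low-N ratio. Group comparisons run
one-way ANOVA then two-sided Dunnett tests against the control, with
familywise control by seeded Monte-Carlo integration of the
multivariate-t null (>= 1e5 draws; the k = 1 case reduces to the
pooled t-test, and the implementation is cross-checked against an
independent multivariate-t implementation in the tests). Shapiro-Wilk
per group and a median-centered Levene (Brown-Forsythe) test are always
reported alongside, never used to gate the analysis. No correction
beyond Dunnett's own familywise control is applied.

PCA is centered and unit-variance-scaled on the active variables;
supplementary quantitative variables are projected as correlations with
the scores and never influence the axes; constant columns are dropped
with a warning. Heatmap ordering uses distance = 1 - Spearman
correlation (average ranks on ties), average linkage, per-row z-scoring
for display on a divergent scale, and deterministic leaf order;
zero-variance rows get correlation 0 with a warning. Average linkage
and z-scoring are fixed, documented choices where the original figure
caption leaves them open.

# The synthetic ground truth

**Family generator.** No real template sequence is required or shipped:
variants are built from a synthetic alpha-gliadin-like architecture —
unique coding flanks (45 + 35 codons drawn from codons that are >= 2
substitutions away from every stop codon and encode no F/Y/Q, so that
any third-position mutation is guaranteed stop-free and cannot create
an epitope residue), a fixed-width epitope region, and a P/Q-rich
repeat pad. The epitope region holds three same-width slots: p31-43
(LG-/LP-form or a motif-dead Y->H filler), the 33-mer repeat, and
DQ2.5-glia-alpha3 (or its Y->H filler). 33-mer copy numbers 0-4 and 6
are realized by Y->H substitutions at repeat positions 13/20/27, which
knock out exactly the overlapping copies whose 9-mer windows contain
those tyrosines — mirroring how natural epitope-loss repeat variants
relate to the immunodominant form. Because every default motif requires
F or Y, and pads/fillers carry H in those positions, no unintended
match can arise; the builder still *verifies* every realized variant
with the scanner and fails loudly on any discrepancy.

Subgenome identity is encoded as 18 genome-specific third-position tag
sites in the 5' flank; each variant additionally carries a 4-site
barcode and optional extra SNPs (`snp_rate`, default 0.01 per mutable
site). The builder enforces >= 7 substitutions between every pair of
variants (identity <= 98.5%, margin below the 99% clustering
threshold), redrawing barcodes on collision and raising a generation
error past the retry budget. Pseudogenes get one premature stop codon
in the 3' flank, downstream of all epitopes, so designed epitope counts
are never altered. Genome exemplars are the per-genome medoid truth
sequences.

The default `bw208_like` design (seed 42) realizes the study system's
printed structure: 45 variants, 20 pseudogenes; exactly one genome-D
putative gene with the six-copy 33-mer at DNA frequency 0.024; six
genome-B putative genes with no 33-mer epitopes, two carrying
DQ2.5-glia-alpha3 and the other four only p31-43 (these are the
CD-epitope-free putative genes, and the most abundant variant is one of
them); p31-43 in 38/45 variants and 20/25 putative genes; five
single-copy and four four-copy putative genes. Quantities the study
does not pin — the genome split (A 16 / B 6 / D 23), the frequency
vector, the pseudogene epitope mix, amplicon lengths — were chosen once
as plausible values and are fixed in `bw208_like_design()`. Lengths
span 435-465 nt, narrower than real amplicon-length variation, so that
2x300 pairs always span and overlap every variant and nearest-exemplar
genome assignment stays above its identity floor; the amplicon window
sits immediately downstream of the signal-peptide-like region of the
template gene (the real coordinates are not recoverable from the
figure-level description).

**Read simulator.** Pairs are drawn multinomially from per-sample
abundances; substitutions are i.i.d. at `per_base_error` (indels,
quality-by-cycle decay and instrument profiles are out of scope);
qualities are uniform at `Q = -10 log10(p)` so the expected-error
filter is analytically checkable; chimeras are two-parent single
crossovers at rate `chimera_rate`. One RNG stream per call, seeded.
The variant-recovery experiment uses 4 DNA samples x 100,000 pairs at
error 0.001 and chimera rate 0.005 — >= 500 expected pairs per variant
per sample at the rarest design frequency (0.005). A fundamental
consequence of the 2x300 geometry over a ~450-nt amplicon: ~300 bases
per merged read are covered by only one mate, so at error rate *p* at
most `(1-p)^300` of merged reads can be bit-exact; error correction
beyond that is the denoiser's job, not the merger's.

**Expression design.** Three genotypes (wild type; RNAi lines driven by
a D-hordein and a gamma-gliadin endosperm promoter), two N levels,
DPA 10/18/26, two blocks — 36 cDNA samples, plus 4 DNA samples, i.e.
the 40-sample layout of the emulated experiment. True abundance =
baseline (DNA frequency x 1000) x silencing (putative genes only; 0.35
hordein-promoter line, 0.12 gliadin-promoter line — the latter designed
as the stronger, more stable silencer) x N response (genome-A/D
putative genes at high N: 2.5 wild type, 4.0 hordein line per its
fourfold published response, 1.0 gliadin line) x DPA profile (0.4 / 1.0
/ 0.7, peaking at 18 DPA) x lognormal noise (CV 0.2, chosen as a
typical between-replicate spread for RT-qPCR-scale expression data).
Pseudogene N-responsiveness under RNAi, which the real data hints at,
is not modeled.

**qPCR simulator.** `F(c) = baseline + min(N0 x E^c, plateau) + noise`.
The hard saturation keeps the sub-plateau region exactly exponential,
giving closed-form expectations for the efficiency and Cq tests.

# What passing tests do and do not show

The generator carries the designed marginal structure, substitution-only
errors and uniform qualities. Pipeline recovery being exact on this
fixture shows the algorithms implement their definitions and separate
variants at the designed divergence under realistic depth; it does not
certify performance on real MiSeq error profiles (indels, quality
decay, PCR bias), on amplicons outside the simulated length window, or
on real reference-gene behavior. The expression smoke tests are
design-calibrated: they verify the qualitative pattern the design
encodes (significant wild-type N response, none for the
gliadin-promoter line), not the original measurements.

# Problem sizes

The test suite and acceptance script run, per invocation: one family
build (45 variants), one 4 x 100,000-pair recovery experiment, several
smaller seeded simulations (500-6,000 pairs), 1,000-case scanner oracle
sweeps, and Monte-Carlo Dunnett nulls at 2e4-2e5 draws — sizes chosen
so the full suite completes in minutes on a single CPU while every
headline quantity is still computed from scratch.

# Known limitations

* Identity is Levenshtein-based; for substitution-only divergence it
  equals column identity, but alignments with many indels can differ
  from affine-gap aligner output.
* The chimera detector only removes exact single-crossover mosaics;
  PCR chimeras with post-crossover errors survive only until the
  support filter.
* Genome assignment presumes exemplars within ~10% identity of their
  family members; it is a documented stand-in, not a reimplementation
  of the published genome-addressing method.
* p31-43 motif strings (LG-/LP-form) are literature-derived defaults
  and overridable; deamidated epitope forms are not matched.
* Dunnett p-values are Monte-Carlo estimates; at 1e5 draws their
  standard error near p = 0.05 is ~0.0007.
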