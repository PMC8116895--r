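Package: gliadex
Title: Alpha-Gliadin Amplicon Variant Recovery, CD-Epitope Annotation and
    Expression Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to recover high-confidence alpha-gliadin amplicon variants
    from paired-end amplicon sequencing reads (read merging, expected-error
    filtering, UNOISE-style denoising with chimera removal, 99 percent
    identity clustering and abundance filtering), to annotate variants for
    pseudogene status, celiac-disease epitope content, 33-mer copy number,
    type-1 subtype and wheat subgenome of origin, and to quantify variant
    expression with an RT-qPCR anchored normalization (LinRegPCR-style
    efficiency estimation, N0 quantification, geNorm reference-gene
    stability and normalization factors). A synthetic-data module generates
    ground-truth gene families, paired-end reads, qPCR fluorescence curves
    and genotype x nitrogen x developmental-stage expression designs so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    car,
    jsonlite,
    multcomp,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
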