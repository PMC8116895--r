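# Frame determination, pseudogene detection, epitope scanning, subtype
# classification and genome assignment.

test_that("frame offset follows the reference-start convention", {
  fam <- fixture_family()
  ref <- fam$template_cds
  v90 <- substr(ref, 90, 500)
  v91 <- substr(ref, 91, 501)
  expect_equal(determine_frame(v90, ref)$frame_offset, 90 %% 3)
  expect_equal(determine_frame(v91, ref)$frame_offset, 91 %% 3)
  expect_equal(determine_frame(substr(ref, 92, 502), ref)$frame_offset, 92 %% 3)
})

test_that("frames of all generated variants are recovered from the template", {
  fam <- fixture_family()
  truth_frame <- fam$amplicon_start %% 3L
  fr <- vapply(fam$sequences, function(s)
    determine_frame(s, fam$template_cds)$frame_offset, numeric(1))
  expect_true(all(fr == truth_frame))
})

test_that("pseudogene detection reports in-frame stop positions", {
  # codon-aligned sequence with TAA at codon 3
  s <- paste0("ATGCCC", "TAA", "CCCGGG")
  res <- detect_pseudogene(s, frame_offset = 1L)
  expect_true(res$is_pseudogene)
  expect_equal(res$stop_positions, 3L)
  clean <- detect_pseudogene("ATGCCCGGGTTT", 1L)
  expect_false(clean$is_pseudogene)
  expect_error(detect_pseudogene("AT", 1L), "shorter")
  # invariance under a synonymous edit that cannot create a stop
  s2 <- paste0("ATGCCA", "TAA", "CCCGGG")  # CCC -> CCA (both Pro)
  expect_equal(detect_pseudogene(s2, 1L)$stop_positions, 3L)
})

test_that("the bw208_like fixture flags exactly the 20 designed pseudogenes", {
  fam <- fixture_family()
  ann <- annotate_variants(fam$sequences, reference_cds = fam$template_cds)
  expect_equal(sum(ann$is_pseudogene), 20L)
  expect_equal(ann$is_pseudogene, fam$truth$is_pseudogene)
})

test_that("the canonical 33-mer carries six overlapping constituent copies", {
  counts <- scan_epitopes(CANONICAL_33MER)
  expect_equal(count_33mer_copies(counts), 6L)
  expect_equal(unname(counts["DQ2.5-glia-a1a"]), 1L)
  expect_equal(unname(counts["DQ2.5-glia-a1b"]), 2L)
  expect_equal(unname(counts["DQ2.5-glia-a2"]), 3L)
})

test_that("scanner counts overlapping matches and respects stops", {
  # overlapping occurrences at positions 1 and 8
  expect_equal(unname(scan_epitopes("PQPQLPYPQPQLPYPQ")["DQ2.5-glia-a2"]), 2L)
  expect_true(all(scan_epitopes("KKKKKKKKKKKK") == 0L))
  # a stop inside the motif window breaks the match
  left <- "PQPQ"; right <- "LPYPQ"
  expect_equal(unname(scan_epitopes(paste0(left, "*", right))["DQ2.5-glia-a2"]), 0L)
  expect_equal(unname(scan_epitopes(paste0("PQPQLPYPQ", "*", "PQPQLPYPQ"))["DQ2.5-glia-a2"]), 2L)
})

test_that("scanner equals the brute-force oracle on random protein/motif pairs", {
  set.seed(81)
  et0 <- default_epitope_table()
  for (i in 1:1000) {
    prot <- random_protein(sample(20:120, 1))
    motif <- random_protein(sample(5:9, 1))
    tab <- data.frame(name = "m", peptide = motif, category = "innate_peptide")
    expect_identical(unname(scan_epitopes(prot, tab)[["m"]]),
                     oracle_count_overlapping(prot, motif))
  }
  # and on the shipped motifs against gliadin-like proteins
  for (i in 1:50) {
    prot <- random_protein(200, c("P", "Q", "L", "Y", "F"))
    got <- scan_epitopes(prot, et0)
    want <- vapply(et0$peptide, oracle_count_overlapping, integer(1),
                   protein = prot)
    expect_equal(unname(got), unname(want))
  }
})

test_that("subtype classification follows the copy-number rule table", {
  et <- default_epitope_table()
  mk <- function(a1a = 0, a1b = 0, a2 = 0, a3 = 0, lg = 0, lp = 0)
    c("DQ2.5-glia-a1a" = a1a, "DQ2.5-glia-a1b" = a1b, "DQ2.5-glia-a2" = a2,
      "DQ2.5-glia-a3" = a3, "p31-43_LG" = lg, "p31-43_LP" = lp)
  expect_equal(classify_type(mk(a1a = 1)), "1.1-1")
  expect_equal(classify_type(mk(a1a = 1, a2 = 1)), "1.1-2")
  expect_equal(classify_type(mk(a1a = 1, a1b = 1, a2 = 2)), "1.2-4")
  expect_equal(classify_type(mk(a1a = 1, a1b = 2, a2 = 3)), "1.3-6")
  expect_equal(classify_type(mk(a1b = 1, a2 = 2)), "type1_other")
  expect_equal(classify_type(mk(a3 = 5)), "non_type1")
  # p31-43 does not count toward CD-epitope status
  expect_equal(classify_type(mk(lg = 1)), "no_cd_epitope")
  expect_equal(classify_type(mk()), "no_cd_epitope")
  # a flanking epitope never contributes to the 33-mer copy number
  expect_equal(count_33mer_copies(mk(a1a = 1, a2 = 1, a3 = 5)), 2)
  # classification is a pure function: idempotent re-annotation
  fam <- fixture_family()
  a1 <- annotate_variants(fam$sequences[1:5], fam$template_cds)
  a2 <- annotate_variants(fam$sequences[1:5], fam$template_cds)
  expect_identical(a1, a2)
})

test_that("genome assignment is exact on exemplars and honors tie/floor rules", {
  fam <- fixture_family()
  ex <- fam$exemplars
  for (g in names(ex))
    expect_equal(assign_genome(ex[[g]], ex)$genome, g)
  # equidistant to two exemplars -> unassigned with tie flag
  two <- c(A = strrep("ACGT", 50), B = strrep("ACGT", 50))
  res <- assign_genome(strrep("ACGT", 50), two)
  expect_equal(res$genome, "unassigned")
  expect_true(res$tie)
  # nothing close -> unassigned; empty exemplars -> configuration error
  far <- assign_genome(strrep("A", 200), fam$exemplars)
  expect_equal(far$genome, "unassigned")
  expect_error(assign_genome("ACGT", character(0)), "configuration error")
})

test_that("all 45 fixture variants are assigned to their designed genome", {
  fam <- fixture_family()
  got <- vapply(fam$sequences, function(s)
    assign_genome(s, fam$exemplars)$genome, character(1))
  expect_equal(unname(got), fam$truth$genome)
})
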