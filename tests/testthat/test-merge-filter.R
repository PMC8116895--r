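# Read merging, expected errors, quality filtering, dereplication.

make_pair <- function(amplicon, read_len = 300L, q = 30L) {
  qs <- strrep(intToUtf8(q + 33L), read_len)
  list(fwd = substr(amplicon, 1, read_len),
       rev = as.character(Biostrings::reverseComplement(Biostrings::DNAString(
         substr(amplicon, nchar(amplicon) - read_len + 1, nchar(amplicon))))),
       qual = qs)
}

test_that("a perfectly overlapping pair merges to the amplicon length", {
  amp <- random_dna(420)
  p <- make_pair(amp)
  m <- merge_pairs(p$fwd, p$qual, p$rev, p$qual)
  expect_equal(m$status, "merged")
  expect_equal(nchar(m$seq), 420L)       # 300 + 300 - 180
  expect_equal(m$overlap, 180L)
  expect_equal(m$seq, amp)
  expect_equal(m$mismatches, 0L)
})

test_that("pairs without an acceptable overlap are rejected, not errors", {
  set.seed(6)
  f <- random_dna(120); r <- random_dna(120)
  q <- strrep("?", 120)  # Q30
  m <- merge_pairs(f, q, r, q)
  expect_equal(m$status, "no_overlap")
  expect_true(is.na(m$seq))
})

test_that("posterior qualities rise on agreement and cap at Q45", {
  amp <- random_dna(400)
  p <- make_pair(amp, q = 30L)
  m <- merge_pairs(p$fwd, p$qual, p$rev, p$qual)
  qs <- utf8ToInt(m$qual) - 33L
  # overlap region 101..300: agreement posterior min(45, 30+30) = 45
  expect_true(all(qs[101:300] == 45L))
  expect_true(all(qs[c(1:100, 301:400)] == 30L))
})

test_that("simulated pairs merge at >= 99% even at elevated error rates", {
  fam <- fixture_family()
  reads <- simulate_reads(fam$sequences, fam$truth$dna_frequency,
                          read_sim_config(depth_per_sample = 4000,
                                          per_base_error = 0.005, seed = 31))
  m <- merge_pairs(reads$S1$fwd$seq, reads$S1$fwd$qual,
                   reads$S1$rev$seq, reads$S1$rev$qual)
  expect_gte(mean(m$status == "merged"), 0.99)
})

test_that("at low error rates merged sequences reconstruct the truth", {
  # exact reconstruction is bounded by the single-covered (non-overlap)
  # bases, which no merger can correct: a 450-nt amplicon read as 2x300
  # leaves ~300 such bases, so near-complete exactness needs a per-base
  # error around 1e-4 or less
  fam <- fixture_family()
  reads <- simulate_reads(fam$sequences, fam$truth$dna_frequency,
                          read_sim_config(depth_per_sample = 4000,
                                          per_base_error = 5e-5, seed = 32))
  m <- merge_pairs(reads$S1$fwd$seq, reads$S1$fwd$qual,
                   reads$S1$rev$seq, reads$S1$rev$qual)
  expect_gte(mean(m$status == "merged"), 0.99)
  truth_id <- sub(".*variant=", "", reads$S1$fwd$id)
  ok <- m$status == "merged"
  exact <- m$seq[ok] == unname(fam$sequences[truth_id[ok]])
  expect_gte(mean(exact), 0.95)
})

test_that("expected errors follow the Phred closed forms", {
  expect_equal(expected_errors(rep(20, 10)), 0.1)
  expect_equal(expected_errors(strrep(intToUtf8(20 + 33), 10)), 0.1)
  ee <- expected_errors(rep(2, 100))
  expect_equal(ee, 100 * 10^(-0.2), tolerance = 1e-9)
  expect_gt(ee, 1)  # rejected at maxEE 1
  expect_equal(expected_errors(numeric(0)), 0)
  expect_equal(expected_errors(""), 0)
})

test_that("the length/EE filter applies inclusive thresholds", {
  lens <- c(150, 159, 160, 161, 300)
  merged <- data.frame(
    seq = vapply(lens, random_dna, character(1)),
    qual = strrep("I", lens),   # Q40: negligible EE
    status = "merged", overlap = 100L, mismatches = 0L,
    stringsAsFactors = FALSE)
  fl <- filter_reads(merged, pipeline_params())
  expect_equal(nchar(fl$reads$seq), c(160, 161, 300))
  expect_equal(unname(fl$log["too_short"]), 2)
  # 200 bases at Q30: EE = 0.2, retained
  r30 <- data.frame(seq = random_dna(200), qual = strrep("?", 200),
                    status = "merged", overlap = 1L, mismatches = 0L)
  expect_equal(nrow(filter_reads(r30)$reads), 1L)
  # EE exactly at the threshold is retained (inclusive)
  q20 <- data.frame(seq = random_dna(160), qual = strrep("5", 160),
                    status = "merged", overlap = 1L, mismatches = 0L)
  expect_equal(expected_errors(q20$qual), 1.6, tolerance = 1e-9)
  expect_equal(nrow(filter_reads(q20)$reads), 0L)
  # EE exactly equal to the threshold is retained (inclusive boundary)
  exact1 <- data.frame(seq = random_dna(100),
                       qual = strrep(intToUtf8(20 + 33), 100),
                       status = "merged", overlap = 1L, mismatches = 0L)
  expect_equal(expected_errors(exact1$qual), 1, tolerance = 1e-12)
  fl1 <- filter_reads(exact1, pipeline_params(min_merged_len = 100,
                                              max_expected_errors = 1.0))
  expect_equal(nrow(fl1$reads), 1L)
})

test_that("filtering is monotone in its thresholds", {
  set.seed(41)
  merged <- data.frame(
    seq = vapply(sample(140:220, 50, TRUE), random_dna, character(1)),
    status = "merged", overlap = 1L, mismatches = 0L,
    stringsAsFactors = FALSE)
  merged$qual <- vapply(nchar(merged$seq), function(n)
    intToUtf8(sample(25:40, n, TRUE) + 33L), character(1))
  base <- filter_reads(merged, pipeline_params())$reads$seq
  looser_ee <- filter_reads(merged, pipeline_params(max_expected_errors = 2))$reads$seq
  looser_len <- filter_reads(merged, pipeline_params(min_merged_len = 100))$reads$seq
  expect_true(all(base %in% looser_ee))
  expect_true(all(base %in% looser_len))
})

test_that("dereplication conserves counts and orders by size then sequence", {
  seqs <- c(rep("AAAA", 100), rep("CCCC", 3), "GGGG")
  u <- dereplicate(seqs)
  expect_equal(u$seq, c("AAAA", "CCCC", "GGGG"))
  expect_equal(u$size, c(100L, 3L, 1L))
  expect_equal(sum(u$size), length(seqs))
  # one-base difference keeps sequences distinct
  u2 <- dereplicate(c("ACGT", "ACGA"))
  expect_equal(length(u2$seq), 2L)
  # per-sample conservation on random input
  set.seed(12)
  s <- sample(c("AA", "AC", "AG"), 200, TRUE)
  sid <- sample(c("s1", "s2"), 200, TRUE)
  u3 <- dereplicate(s, sid)
  expect_equal(sum(u3$sample_counts), 200L)
  expect_equal(unname(colSums(u3$sample_counts)[c("s1", "s2")]),
               unname(table(sid)[c("s1", "s2")]), ignore_attr = TRUE)
  # ties broken lexicographically
  u4 <- dereplicate(c("TT", "AA", "CC"))
  expect_equal(u4$seq, c("AA", "CC", "TT"))
})
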