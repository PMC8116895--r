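# UNOISE-style denoising, chimera removal, clustering and database
# mapping.

mutate_at <- function(seq, pos, base) { substr(seq, pos, pos) <- base; seq }

test_that("abundance skew absorbs satellites and separates true variants", {
  set.seed(51)
  truth <- random_dna(200)
  sat <- mutate_at(truth, 50, setdiff(c("A", "C", "G", "T"),
                                      substr(truth, 50, 50))[1])
  u <- dereplicate(c(rep(truth, 1000), rep(sat, 50)))
  cent <- denoise(u, alpha = 2)
  # beta(1) = 1/8; 50/1000 = 0.05 <= 1/8 -> absorbed
  expect_equal(cent$seq, truth)
  expect_equal(cent$size, 1050L)
  # two equal-size sequences at d = 5: ratio 1 > beta(5) -> two centroids
  far <- truth
  for (p in c(10, 40, 80, 120, 160))
    far <- mutate_at(far, p, setdiff(c("A", "C", "G", "T"),
                                     substr(far, p, p))[1])
  u2 <- dereplicate(c(rep(truth, 500), rep(far, 500)))
  expect_equal(length(denoise(u2)$seq), 2L)
  # just above the skew boundary a satellite founds its own centroid:
  # beta(1) = 1/8, 200/1000 > 1/8
  u3 <- dereplicate(c(rep(truth, 1000), rep(sat, 200)))
  expect_equal(length(denoise(u3)$seq), 2L)
})

test_that("singletons are discarded by default", {
  set.seed(52)
  truth <- random_dna(150)
  lone <- mutate_at(truth, 10, "A")
  u <- dereplicate(c(rep(truth, 20), if (substr(truth, 10, 10) == "A")
    mutate_at(truth, 10, "C") else lone))
  cent <- denoise(u)
  expect_equal(cent$size, 20L)
  cent_all <- denoise(u, min_size = 1L)
  expect_equal(sum(cent_all$size), 21L)
})

test_that("an exact two-parent crossover centroid is removed as chimeric", {
  set.seed(53)
  a <- random_dna(300)
  b <- random_dna(300)
  chim <- paste0(substr(a, 1, 150), substr(b, 151, 300))
  u <- dereplicate(c(rep(a, 1000), rep(b, 900), rep(chim, 40)))
  cent <- denoise(u)
  expect_equal(cent$n_chimeras_removed, 1L)
  expect_setequal(cent$seq, c(a, b))
  # without the chimera check it persists (sizes too large to absorb)
  cent_raw <- denoise(u, remove_chimeras = FALSE)
  expect_true(chim %in% cent_raw$seq)
})

test_that("clustering identity arithmetic matches the worked examples", {
  set.seed(54)
  s <- random_dna(200)
  one_diff <- mutate_at(s, 77, setdiff(c("A", "C", "G", "T"),
                                       substr(s, 77, 77))[1])
  expect_equal(seq_identity(s, one_diff), 199 / 200)
  cl <- cluster_centroids(c(s, one_diff), c(10, 5), identity = 0.99)
  expect_equal(sum(cl$is_centroid), 1L)
  three <- s
  for (p in c(20, 90, 150))
    three <- mutate_at(three, p, setdiff(c("A", "C", "G", "T"),
                                         substr(three, p, p))[1])
  expect_equal(seq_identity(s, three), 197 / 200)
  cl3 <- cluster_centroids(c(s, three), c(10, 5), identity = 0.99)
  expect_equal(sum(cl3$is_centroid), 2L)
  # identical sequences always collapse
  cl_id <- cluster_centroids(c(s, s, s), c(3, 2, 1))
  expect_equal(sum(cl_id$is_centroid), 1L)
})

test_that("clustering at identity 1 equals dereplication of its input", {
  set.seed(55)
  seqs <- sample(vapply(1:5, function(i) random_dna(100), character(1)),
                 40, TRUE)
  u <- dereplicate(seqs)
  cl <- cluster_centroids(u$seq, u$size, identity = 1)
  expect_equal(sum(cl$is_centroid), length(u$seq))
})

test_that("database mapping assigns error-free reads perfectly and logs ties", {
  fam <- fixture_family()
  reads <- simulate_reads(fam$sequences, fam$truth$dna_frequency,
                          read_sim_config(depth_per_sample = 3000,
                                          per_base_error = 0, seed = 61))
  m <- merge_pairs(reads$S1$fwd$seq, reads$S1$fwd$qual,
                   reads$S1$rev$seq, reads$S1$rev$qual)
  u <- dereplicate(m$seq)
  ab <- map_samples_to_database(u, fam$sequences)
  expect_equal(sum(ab$counts), 3000)
  expect_equal(sum(ab$unassigned), 0)
  truth_counts <- table(factor(sub(".*variant=", "", reads$S1$fwd$id),
                               levels = fam$truth$variant_id))
  expect_equal(unname(ab$counts[, 1]), as.vector(truth_counts))
  # tie: read equidistant to two database entries goes to the first
  db <- c(x = "AAAAAAAAAATTTTTTTTTT", y = "AAAAAAAAAATTTTTTTTTC")
  read <- "AAAAAAAAAATTTTTTTTTG"
  u2 <- dereplicate(read)
  ab2 <- map_samples_to_database(u2, db, identity = 0.9)
  expect_equal(unname(ab2$counts[, 1]), c(1, 0))
  expect_equal(ab2$ties, 1L)
})

test_that("seeded noisy simulation maps back to the true variants", {
  fam <- fixture_family()
  reads <- simulate_reads(fam$sequences, fam$truth$dna_frequency,
                          read_sim_config(depth_per_sample = 4000,
                                          per_base_error = 0.002, seed = 62))
  m <- merge_pairs(reads$S1$fwd$seq, reads$S1$fwd$qual,
                   reads$S1$rev$seq, reads$S1$rev$qual)
  m$truth <- sub(".*variant=", "", reads$S1$fwd$id)
  fl <- filter_reads(m, pipeline_params())
  expect_gt(nrow(fl$reads), 1000)
  u <- dereplicate(fl$reads$seq)
  ab <- map_samples_to_database(u, fam$sequences)
  assigned <- sum(ab$counts)
  expect_gte(assigned / (assigned + sum(ab$unassigned)), 0.99)
  # per-read assignment matches each read's true source variant
  per_read <- unname(ab$assignment[fl$reads$seq])
  ok <- !is.na(per_read)
  expect_gte(mean(per_read[ok] == fl$reads$truth[ok]), 0.99)
})

test_that("mapping warns when nothing reaches the identity floor", {
  u <- dereplicate(strrep("A", 100))
  expect_warning(ab <- map_samples_to_database(u, c(v = strrep("C", 100))),
                 "no read mapped")
  expect_equal(sum(ab$counts), 0)
  expect_equal(sum(ab$unassigned), 1)
})
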