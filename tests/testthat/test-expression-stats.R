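# Aggregation, fold changes, ANOVA + Dunnett, PCA and heatmap ordering.

test_that("aggregation conserves totals and matches hand-computed sums", {
  fam <- fixture_family()
  sim <- simulate_expression(expression_design(fam, noise_cv = 0, seed = 1))
  x <- sim$abundance
  by_genome <- aggregate_abundance(x, fam$truth, keys = "genome")
  expect_equal(sum(by_genome$abundance), sum(x$abundance), tolerance = 1e-9)
  # singleton group equals the variant's own values
  one <- x[x$variant_id == "Amp13", ]
  agg1 <- aggregate_abundance(one, fam$truth, keys = c("variant_id"))
  expect_equal(agg1$abundance, sum(one$abundance))
  # hand-computed genome-D check on one noiseless sample
  s1 <- x[x$sample_id == x$sample_id[1], ]
  dsum <- sum(s1$abundance[fam$truth$genome[match(s1$variant_id,
                                                  fam$truth$variant_id)] == "D"])
  aggs <- aggregate_abundance(s1, fam$truth, keys = "genome")
  expect_equal(aggs$abundance[aggs$genome == "D"], dsum, tolerance = 1e-12)
  # unannotated variants are an error listing the ids
  rogue <- data.frame(variant_id = "ghost", abundance = 1)
  expect_error(aggregate_abundance(rogue, fam$truth, "genome"), "ghost")
})

test_that("noiseless fold change recovers the designed N-response factors", {
  fam <- fixture_family()
  des <- expression_design(fam, noise_cv = 0, seed = 1)
  sim <- simulate_expression(des)
  put <- fam$truth[!fam$truth$is_pseudogene, "variant_id"]
  x <- sim$abundance[sim$abundance$variant_id %in% put, ]
  agg <- aggregate_abundance(x, fam$truth, keys = c("genome", "genotype", "n_level"))
  fc <- fold_change(agg, keys = c("genome", "genotype"))
  # the hordein-promoter RNAi line responds fourfold on genomes A and D
  hp <- fc[fc$genotype == "rnai_hordein_promoter", ]
  expect_equal(hp$fold_change[hp$genome == "A"], 4, tolerance = 1e-12)
  expect_equal(hp$fold_change[hp$genome == "D"], 4, tolerance = 1e-12)
  expect_equal(hp$fold_change[hp$genome == "B"], 1, tolerance = 1e-12)
  wt <- fc[fc$genotype == "wild_type", ]
  expect_equal(wt$fold_change[wt$genome == "A"], 2.5, tolerance = 1e-12)
  gp <- fc[fc$genotype == "rnai_gliadin_promoter", ]
  expect_true(all(abs(gp$fold_change - 1) < 1e-12))
  # trivial ratio identities
  expect_equal(fold_change(data.frame(g = c("x", "x"),
                                      n_level = c("high", "low"),
                                      abundance = c(400, 100)),
                           keys = "g")$fold_change, 4)
  expect_equal(fold_change(data.frame(g = "x", n_level = c("high", "low"),
                                      abundance = c(7, 7)),
                           keys = "g")$fold_change, 1)
})

test_that("identical groups give F near 0 and Dunnett p near 1", {
  x <- rep(c(5, 6, 7, 8), 3)
  g <- rep(c("ctrl", "t1", "t2"), each = 4)
  r <- compare_groups(x, g, "ctrl", n_mc = 2e4, seed = 1)
  expect_lt(r$anova$F, 1e-12)
  expect_true(all(r$dunnett$p_adjusted > 0.99))
})

test_that("with one comparison Dunnett reduces to the two-sample t-test", {
  set.seed(91)
  x <- c(rnorm(8), rnorm(8, 1))
  g <- rep(c("ctrl", "trt"), each = 8)
  r <- compare_groups(x, g, "ctrl", n_mc = 2e5, seed = 2)
  pt_ref <- t.test(x[g == "trt"], x[g == "ctrl"], var.equal = TRUE)$p.value
  expect_equal(r$dunnett$p_adjusted, pt_ref, tolerance = 0.01)
})

test_that("Monte-Carlo Dunnett agrees with the multivariate-t reference", {
  skip_if_not_installed("multcomp")
  set.seed(92)
  x <- c(rnorm(6), rnorm(6, 0.8), rnorm(6, -0.4), rnorm(6, 0.1))
  g <- factor(rep(c("ctrl", "a", "b", "c"), each = 6),
              levels = c("ctrl", "a", "b", "c"))
  r <- compare_groups(x, as.character(g), "ctrl", n_mc = 2e5, seed = 3)
  fit <- multcomp::glht(aov(x ~ g), linfct = multcomp::mcp(g = "Dunnett"))
  ref <- summary(fit)$test$pvalues
  expect_equal(r$dunnett$p_adjusted, as.numeric(ref), tolerance = 0.02)
})

test_that("simulated null keeps familywise type-I error near 0.05", {
  set.seed(93)
  k <- 3; n <- 6; df <- k * n + n - (k + 1)
  # Monte-Carlo critical value for max |T| once (same balanced design)
  z0 <- rnorm(2e5); s <- sqrt(rchisq(2e5, df) / df)
  tmax <- rep(0, 2e5)
  for (j in 1:k) {
    zj <- rnorm(2e5)
    tmax <- pmax(tmax, abs((zj - z0) / (s * sqrt(2))))
  }
  crit <- quantile(tmax, 0.95)
  nrep <- 1000
  rej <- logical(nrep)
  for (r in seq_len(nrep)) {
    x <- rnorm((k + 1) * n)
    g <- rep(0:k, each = n)
    ms <- tapply(x, g, mean)
    s2 <- sum(tapply(x, g, function(v) sum((v - mean(v))^2))) / df
    tobs <- max(abs((ms[-1] - ms[1]) / sqrt(s2 * 2 / n)))
    rej[r] <- tobs > crit
  }
  fwer <- mean(rej)
  mc_se <- sqrt(0.05 * 0.95 / nrep)
  expect_lt(abs(fwer - 0.05), 2 * mc_se + 0.01)
  # the package's p-values reproduce the same rejection decisions
  set.seed(94)
  x <- rnorm((k + 1) * n)
  g <- rep(c("ctrl", "a", "b", "c"), each = n)
  r <- compare_groups(x, g, "ctrl", n_mc = 5e4, seed = 4)
  expect_true(all(r$dunnett$p_adjusted >= 0 & r$dunnett$p_adjusted <= 1))
  expect_false(is.null(r$shapiro$ctrl$p))
  expect_false(is.null(r$levene$p))
})

test_that("assumption checks and input validation behave", {
  x <- c(1, 2, 3, 4, 10, 20, 30, 40)
  g <- rep(c("ctrl", "trt"), each = 4)
  r <- compare_groups(x, g, "ctrl", n_mc = 1e4, seed = 5)
  expect_length(r$shapiro, 2L)
  expect_true(is.finite(r$levene$F))
  expect_error(compare_groups(c(1, 2, 3), c("a", "a", "b"), "a"), ">= 2")
})

test_that("the homogeneity check matches the reference Levene implementation", {
  skip_if_not_installed("car")
  set.seed(97)
  x <- c(rnorm(8, sd = 1), rnorm(8, sd = 4), rnorm(8, sd = 1))
  g <- rep(c("ctrl", "a", "b"), each = 8)
  r <- compare_groups(x, g, "ctrl", n_mc = 1e4, seed = 6)
  ref <- car::leveneTest(x ~ factor(g), center = median)
  expect_equal(r$levene$F, ref[1, "F value"], tolerance = 1e-10)
  expect_equal(r$levene$p, ref[1, "Pr(>F)"], tolerance = 1e-10)
})

test_that("PCA separates active and supplementary roles", {
  set.seed(95)
  # rank-1 structure: two perfectly correlated variables
  z <- rnorm(10)
  X <- cbind(v1 = z, v2 = 2 * z + 3)
  p <- pca_with_supplementary(X)
  expect_equal(p$var_explained[1], 1, tolerance = 1e-12)
  expect_equal(sum(p$var_explained), 1, tolerance = 1e-12)
  # supplementary identical to an active variable projects like it
  X2 <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, paste0("v", 1:4)))
  p2 <- pca_with_supplementary(X2, supplementary = X2[, 2, drop = FALSE])
  expect_equal(unname(p2$sup_cor[1, ]), unname(p2$loadings[2, ]),
               tolerance = 1e-12)
  # supplementary variables never influence the axes
  p2b <- pca_with_supplementary(X2, supplementary = matrix(rnorm(10)))
  expect_equal(p2$scores, p2b$scores)
  # eigen-structure matches a direct eigendecomposition oracle
  C <- cor(X2)
  ev <- eigen(C)$values
  expect_equal(p2$var_explained, ev / sum(ev), tolerance = 1e-9)
  expect_warning(pca_with_supplementary(cbind(X2, const = 1)), "constant")
})

test_that("heatmap ordering uses Spearman distance with average linkage", {
  set.seed(96)
  m <- matrix(rnorm(60), 6, 10)
  m[2, ] <- m[1, ] * 3 + 5          # identical ranks -> distance 0
  m[3, ] <- -m[1, ]                 # reversed ranks -> distance 2
  rownames(m) <- paste0("r", 1:6)
  h <- heatmap_order(m)
  d <- as.matrix(1 - cor(t(m), method = "spearman"))
  expect_equal(d["r1", "r2"], 0, tolerance = 1e-12)
  expect_equal(d["r1", "r3"], 2, tolerance = 1e-12)
  expect_equal(h$row_hclust$height[1], 0, tolerance = 1e-12)
  expect_equal(sort(abs(h$row_hclust$merge[1, ])), c(1, 2))
  # dendrogram heights equal a naive O(n^3) average-linkage oracle
  expect_equal(sort(h$row_hclust$height),
               sort(oracle_average_linkage_heights(as.dist(d))),
               tolerance = 1e-12)
  # row scaling is per-row z-score
  expect_equal(unname(rowMeans(h$scaled)), rep(0, 6), tolerance = 1e-12)
  expect_equal(unname(apply(h$scaled, 1, sd)), rep(1, 6), tolerance = 1e-12)
  expect_warning(heatmap_order(rbind(a = rep(1, 5), b = rnorm(5))),
                 "zero-variance")
})
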