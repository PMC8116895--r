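# Aggregation, nitrogen-response ratios, group comparisons (ANOVA +
# two-sided Dunnett with Monte-Carlo critical values), PCA with
# supplementary variables and Spearman-distance heatmap ordering.

#' Aggregate a long abundance table by grouping keys
#'
#' Group-and-sum over any combination of annotation and design keys
#' (e.g. genome, type_label, gene class, genotype, n_level, dpa). The sum
#' over any partition equals the ungrouped total (conservation).
#'
#' @param abundance long data.frame with an `abundance` column and a
#'   `variant_id` column.
#' @param annotations data.frame keyed by `variant_id` (e.g. the family
#'   truth or [annotate_variants()] output); every variant present in
#'   `abundance` must be annotated.
#' @param keys character vector of grouping columns, drawn from
#'   `abundance` or `annotations`.
#' @return data.frame with the keys and the summed `abundance`.
#' @export
aggregate_abundance <- function(abundance, annotations, keys) {
  stopifnot("abundance" %in% names(abundance),
            "variant_id" %in% names(abundance),
            "variant_id" %in% names(annotations), length(keys) >= 1L)
  missing <- setdiff(unique(abundance$variant_id), annotations$variant_id)
  if (length(missing))
    stop("unannotated variant(s): ", paste(missing, collapse = ", "))
  extra <- setdiff(keys, names(abundance))
  x <- abundance
  if (length(extra)) {
    idx <- match(x$variant_id, annotations$variant_id)
    for (k in extra) {
      if (!k %in% names(annotations)) stop("unknown key: ", k)
      x[[k]] <- annotations[[k]][idx]
    }
  }
  agg <- aggregate(x["abundance"], x[keys], sum)
  agg[do.call(order, agg[keys]), , drop = FALSE]
}

#' High/low-nitrogen expression ratio per group
#'
#' @param agg aggregated data.frame with an `n_level` key and `abundance`.
#' @param keys grouping keys excluding `n_level`.
#' @param numerator,denominator the two `n_level` values to ratio.
#' @return data.frame with keys and `fold_change` = numerator/denominator.
#' @export
fold_change <- function(agg, keys, numerator = "high", denominator = "low") {
  stopifnot(all(c(keys, "n_level", "abundance") %in% names(agg)))
  hi <- agg[agg$n_level == numerator, c(keys, "abundance")]
  lo <- agg[agg$n_level == denominator, c(keys, "abundance")]
  m <- merge(hi, lo, by = keys, suffixes = c("_num", "_den"))
  if (any(m$abundance_den <= 0)) stop("denominator must be > 0")
  m$fold_change <- m$abundance_num / m$abundance_den
  m[do.call(order, m[keys]), c(keys, "fold_change"), drop = FALSE]
}

# Monte-Carlo two-sided Dunnett p-values: distribution of max_j |T_j|
# where T_j = (Z_j sqrt(1/n_j) - Z_0 sqrt(1/n_0)) / (s* sqrt(1/n_j+1/n_0))
.dunnett_mc <- function(t_obs, n_ctrl, n_groups, df, n_mc, seed) {
  k <- length(n_groups)
  with_seed(seed, {
    z0 <- rnorm(n_mc)
    s <- sqrt(rchisq(n_mc, df) / df)
    tmax <- rep(0, n_mc)
    for (j in seq_len(k)) {
      zj <- rnorm(n_mc)
      tj <- (zj / sqrt(n_groups[j]) - z0 / sqrt(n_ctrl)) /
        (s * sqrt(1 / n_groups[j] + 1 / n_ctrl))
      tmax <- pmax(tmax, abs(tj))
    }
    vapply(abs(t_obs), function(t) mean(tmax >= t), numeric(1))
  })
}

#' Compare treatment groups against a control
#'
#' One-way ANOVA followed by two-sided Dunnett comparisons against the
#' control group, with familywise error control via Monte-Carlo
#' integration of the multivariate t null distribution (seeded, >= 1e5
#' draws by default). Assumption checks (Shapiro-Wilk per group, Levene
#' across groups) are always reported alongside.
#'
#' @param values numeric response vector.
#' @param groups grouping factor/character, same length.
#' @param control the control group's level.
#' @param n_mc Monte-Carlo draws for the Dunnett null.
#' @param seed seed for the Monte-Carlo draws.
#' @return list of class `gliadex_stat_report`: `anova` (F, df, p),
#'   `dunnett` (per-comparison estimate, t, p_adjusted), `shapiro`,
#'   `levene`.
#' @export
compare_groups <- function(values, groups, control, n_mc = 1e5, seed = 1L) {
  groups <- as.character(groups)
  stopifnot(length(values) == length(groups), control %in% groups)
  tab <- table(groups)
  if (any(tab < 2L))
    stop("every group needs >= 2 observations: ",
         paste(names(tab)[tab < 2L], collapse = ", "))
  if (length(tab) < 2L) stop("need >= 2 groups")
  g <- factor(groups, levels = c(control, setdiff(sort(unique(groups)), control)))
  fit <- aov(values ~ g)
  an <- summary(fit)[[1]]
  anova_res <- list(F = an[1, "F value"], df = c(an[1, "Df"], an[2, "Df"]),
                    p = an[1, "Pr(>F)"])
  s2 <- an[2, "Mean Sq"]
  df <- an[2, "Df"]
  means <- tapply(values, g, mean)
  ns <- tapply(values, g, length)
  others <- levels(g)[-1]
  est <- means[others] - means[[control]]
  se <- sqrt(s2 * (1 / ns[others] + 1 / ns[[control]]))
  t_obs <- est / se
  p_adj <- .dunnett_mc(t_obs, ns[[control]], ns[others], df, n_mc, seed)
  shapiro <- lapply(split(values, g), function(x) {
    if (length(unique(x)) == 1L) return(list(W = NA_real_, p = NA_real_))
    s <- shapiro.test(x); list(W = unname(s$statistic), p = s$p.value)
  })
  levene <- .levene_test(values, g)
  structure(list(
    anova = anova_res,
    dunnett = data.frame(comparison = paste(others, "-", control),
                         estimate = unname(est), t = unname(t_obs),
                         p_adjusted = p_adj, stringsAsFactors = FALSE),
    shapiro = shapiro, levene = levene),
    class = "gliadex_stat_report")
}

# Brown-Forsythe/Levene homogeneity test: one-way ANOVA on absolute
# deviations from the group medians
.levene_test <- function(values, g) {
  dev <- abs(values - tapply(values, g, median)[g])
  if (all(dev == dev[1]))
    return(list(F = NA_real_, df = c(NA, NA), p = NA_real_))
  an <- summary(aov(dev ~ g))[[1]]
  list(F = an[1, "F value"], df = c(an[1, "Df"], an[2, "Df"]),
       p = an[1, "Pr(>F)"])
}

#' PCA with supplementary quantitative variables
#'
#' Centered, unit-variance PCA on the active variables; supplementary
#' variables are projected afterwards as their correlations with the
#' component scores and never influence the axes. Constant columns are
#' dropped with a warning.
#'
#' @param active numeric matrix/data.frame, individuals x active variables.
#' @param supplementary optional numeric matrix/data.frame, individuals x
#'   supplementary variables.
#' @return list: `scores`, `loadings` (variable-score correlations),
#'   `var_explained` (fractions summing to 1), `sup_cor` (supplementary
#'   projections), `sdev`.
#' @export
pca_with_supplementary <- function(active, supplementary = NULL) {
  X <- as.matrix(active)
  stopifnot(nrow(X) >= 2L, ncol(X) >= 2L)
  const <- apply(X, 2L, function(x) sd(x) == 0)
  if (any(const)) {
    warning("dropping constant column(s): ",
            paste(colnames(X)[const], collapse = ", "))
    X <- X[, !const, drop = FALSE]
  }
  p <- prcomp(X, center = TRUE, scale. = TRUE)
  ve <- p$sdev^2 / sum(p$sdev^2)
  loadings <- suppressWarnings(cor(X, p$x))
  sup_cor <- NULL
  if (!is.null(supplementary)) {
    S <- as.matrix(supplementary)
    stopifnot(nrow(S) == nrow(X))
    sup_cor <- suppressWarnings(cor(S, p$x))
  }
  list(scores = p$x, loadings = loadings, var_explained = ve,
       sup_cor = sup_cor, sdev = p$sdev)
}

#' Heatmap row/column ordering by Spearman-correlation distance
#'
#' Distance = 1 - Spearman correlation (average ranks for ties), average
#' linkage; rows are z-scored per row for display on a divergent scale.
#' Zero-variance rows get correlation 0 against everything, with a
#' warning. Leaf order is deterministic (ties by input order).
#'
#' @param mat numeric matrix (e.g. variants x samples of normalized
#'   reads).
#' @param cluster_cols also cluster columns (default TRUE when >= 2).
#' @return list: `row_hclust`, `col_hclust`, `row_order`, `col_order`,
#'   `scaled` (row-z-scored matrix).
#' @export
heatmap_order <- function(mat, cluster_cols = TRUE) {
  mat <- as.matrix(mat)
  stopifnot(nrow(mat) >= 2L)
  spearman_dist <- function(m) {
    v <- apply(m, 1L, sd)
    cc <- suppressWarnings(cor(t(m), method = "spearman"))
    if (any(v == 0)) {
      warning("zero-variance row(s); correlation set to 0 for them")
      cc[v == 0, ] <- 0; cc[, v == 0] <- 0
    }
    diag(cc) <- 1
    as.dist(1 - cc)
  }
  rh <- hclust(spearman_dist(mat), method = "average")
  ch <- NULL
  if (cluster_cols && ncol(mat) >= 2L)
    ch <- hclust(spearman_dist(t(mat)), method = "average")
  rs <- apply(mat, 1L, sd)
  scaled <- sweep(mat, 1L, rowMeans(mat), "-")
  scaled <- sweep(scaled, 1L, ifelse(rs == 0, 1, rs), "/")
  list(row_hclust = rh, col_hclust = ch, row_order = rh$order,
       col_order = if (is.null(ch)) seq_len(ncol(mat)) else ch$order,
       scaled = scaled)
}
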