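# Genotype x nitrogen x developmental-stage expression simulation.

#' Configure an expression design
#'
#' Emulates the study design: three genotypes (a wild type and two RNAi
#' lines differing in the endosperm promoter driving the same silencing
#' hairpin), two nitrogen levels, three grain developmental stages (days
#' post anthesis) and two replicate blocks. Per-variant true abundance is
#' baseline x silencing (putative genes only, RNAi genotypes only) x
#' nitrogen response (genome A/D putative genes only, at high N) x DPA
#' profile x lognormal noise.
#'
#' @param family a `gliadex_family` supplying variant annotations;
#'   baselines default to `dna_frequency * 1000`.
#' @param silencing_factor named multiplier (< 1 for RNAi genotypes)
#'   applied to putative genes.
#' @param n_response_factor named high/low-N ratio applied to N-responsive
#'   variants (genome A/D putative genes); the RNAi line driven by the
#'   gliadin promoter is designed non-responsive (ratio 1).
#' @param dpa_profile named multiplier per DPA (peak at 18 DPA).
#' @param noise_cv lognormal coefficient of variation (0 = noiseless).
#' @param n_blocks replicate blocks per design cell.
#' @param seed integer seed.
#' @return list of class `gliadex_expression_design`.
#' @export
expression_design <- function(family,
                              silencing_factor = c(wild_type = 1,
                                                   rnai_hordein_promoter = 0.35,
                                                   rnai_gliadin_promoter = 0.12),
                              n_response_factor = c(wild_type = 2.5,
                                                    rnai_hordein_promoter = 4,
                                                    rnai_gliadin_promoter = 1),
                              dpa_profile = c("10" = 0.4, "18" = 1, "26" = 0.7),
                              noise_cv = 0.2, n_blocks = 2L, seed = 1L) {
  stopifnot(inherits(family, "gliadex_family"),
            identical(sort(names(silencing_factor)), sort(names(n_response_factor))),
            noise_cv >= 0, n_blocks >= 1L)
  if (silencing_factor[["wild_type"]] != 1)
    stop("wild-type silencing factor must be 1")
  if (any(silencing_factor[setdiff(names(silencing_factor), "wild_type")] >= 1))
    stop("RNAi silencing factors must be < 1")
  truth <- family$truth
  structure(list(
    variants = truth$variant_id,
    baseline = setNames(truth$dna_frequency * 1000, truth$variant_id),
    is_putative = setNames(!truth$is_pseudogene, truth$variant_id),
    responsive = setNames(!truth$is_pseudogene & truth$genome %in% c("A", "D"),
                          truth$variant_id),
    genome = setNames(truth$genome, truth$variant_id),
    silencing_factor = silencing_factor,
    n_response_factor = n_response_factor,
    dpa_profile = dpa_profile, noise_cv = noise_cv,
    n_blocks = as.integer(n_blocks), seed = as.integer(seed)),
    class = "gliadex_expression_design")
}

#' Simulate true per-sample variant abundances
#'
#' @param design an [expression_design()].
#' @return list with `abundance` (long data.frame: sample_id, genotype,
#'   n_level, dpa, block, variant_id, abundance) and `sample_sheet`
#'   (one row per sample with dilution_factor and nf placeholders of 1).
#' @export
simulate_expression <- function(design) {
  stopifnot(inherits(design, "gliadex_expression_design"))
  genotypes <- names(design$silencing_factor)
  grid <- expand.grid(block = seq_len(design$n_blocks),
                      dpa = as.integer(names(design$dpa_profile)),
                      n_level = c("low", "high"), genotype = genotypes,
                      stringsAsFactors = FALSE)
  grid$sample_id <- sprintf("%s_%sN_%02ddpa_b%d", grid$genotype,
                            ifelse(grid$n_level == "high", "H", "L"),
                            grid$dpa, grid$block)
  sigma <- sqrt(log(1 + design$noise_cv^2))
  nv <- length(design$variants)
  with_seed(design$seed, {
    rows <- lapply(seq_len(nrow(grid)), function(i) {
      g <- grid[i, ]
      mu <- design$baseline
      mu[design$is_putative] <- mu[design$is_putative] *
        design$silencing_factor[[g$genotype]]
      if (g$n_level == "high")
        mu[design$responsive] <- mu[design$responsive] *
          design$n_response_factor[[g$genotype]]
      mu <- mu * design$dpa_profile[[as.character(g$dpa)]]
      noise <- if (design$noise_cv > 0)
        rlnorm(nv, meanlog = -sigma^2 / 2, sdlog = sigma) else rep(1, nv)
      data.frame(sample_id = g$sample_id, genotype = g$genotype,
                 n_level = g$n_level, dpa = g$dpa, block = g$block,
                 variant_id = design$variants, abundance = mu * noise,
                 stringsAsFactors = FALSE)
    })
    abundance <- do.call(rbind, rows)
    sheet <- grid[, c("sample_id", "genotype", "n_level", "dpa", "block")]
    sheet$dilution_factor <- 1
    sheet$nf <- 1
    list(abundance = abundance, sample_sheet = sheet)
  })
}
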