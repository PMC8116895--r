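# qPCR fluorescence-curve simulation used to validate the quantification
# stack (efficiency estimation, Cq calling, N0 computation).

#' Configure the qPCR curve simulator
#'
#' The amplification model is `F(c) = baseline + min(N0 * E^c, plateau)`
#' plus Gaussian noise: exactly exponential below the plateau, so the
#' log-linear window has closed-form slope `log10(E)`.
#'
#' @param efficiency named vector of true per-target efficiencies in (1, 2].
#' @param cycles number of PCR cycles (default 40).
#' @param plateau saturation level (arbitrary fluorescence units).
#' @param baseline additive background fluorescence.
#' @param noise_sd Gaussian noise SD (same units).
#' @param seed integer seed.
#' @return list of class `gliadex_qpcr_sim_config`.
#' @export
qpcr_sim_config <- function(efficiency = c(alpha_gli = 1.9, CDC = 1.95,
                                           ADP_RF = 1.9, RLI = 1.85),
                            cycles = 40L, plateau = 1e4, baseline = 50,
                            noise_sd = 0.5, seed = 1L) {
  stopifnot(all(efficiency > 1), all(efficiency <= 2), cycles >= 10L,
            plateau > 0, noise_sd >= 0)
  structure(list(efficiency = efficiency, cycles = as.integer(cycles),
                 plateau = plateau, baseline = baseline,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "gliadex_qpcr_sim_config")
}

#' Simulate qPCR fluorescence curves
#'
#' @param config a [qpcr_sim_config()].
#' @param true_n0 data.frame with columns `well`, `target`, `sample`, `n0`
#'   (true starting quantity per well; targets must appear in
#'   `config$efficiency`).
#' @return long data.frame: well, target, sample, cycle, fluorescence.
#' @export
simulate_qpcr <- function(config, true_n0) {
  stopifnot(inherits(config, "gliadex_qpcr_sim_config"),
            all(c("well", "target", "sample", "n0") %in% names(true_n0)),
            all(true_n0$n0 > 0))
  missing <- setdiff(true_n0$target, names(config$efficiency))
  if (length(missing))
    stop("no efficiency configured for target(s): ",
         paste(missing, collapse = ", "))
  cyc <- seq_len(config$cycles)
  with_seed(config$seed, {
    rows <- lapply(seq_len(nrow(true_n0)), function(i) {
      w <- true_n0[i, ]
      E <- config$efficiency[[w$target]]
      f <- config$baseline + pmin(w$n0 * E^cyc, config$plateau)
      if (config$noise_sd > 0) f <- f + rnorm(length(cyc), 0, config$noise_sd)
      data.frame(well = w$well, target = w$target, sample = w$sample,
                 cycle = cyc, fluorescence = f, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}
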