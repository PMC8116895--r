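# RT-qPCR quantification: LinRegPCR-style per-well efficiency from raw
# fluorescence, Cq calling, N0 = threshold / E^Cq, geNorm reference-gene
# stability and per-sample normalization factors.

#' Estimate amplification efficiency from a raw fluorescence curve
#'
#' Baseline is first estimated as the mean fluorescence of cycles 3-8 that
#' lie below 5% of the curve maximum, then refined within the selected
#' window by a 1-D search maximizing the r-squared of log10(F - baseline)
#' versus cycle. The window of `min_window` to `max_window` consecutive
#' cycles in the log-linear phase (above baseline, below 90% of maximum)
#' with the highest r-squared is selected; efficiency is `10^slope`.
#' Estimates outside (1, 2.2] or with r-squared below 0.99 are flagged,
#' never silently altered.
#'
#' @param fluorescence numeric vector, one value per cycle (cycles 1..C,
#'   C >= 10).
#' @param min_window,max_window window size bounds in cycles.
#' @return list of class `gliadex_efficiency`: `E`, `window` (cycle
#'   interval), `r_squared`, `baseline`, `flags` (character vector).
#' @export
estimate_efficiency <- function(fluorescence, min_window = 4L,
                                max_window = 6L) {
  f <- as.numeric(fluorescence)
  stopifnot(length(f) >= 10L, all(is.finite(f)), min_window >= 3L,
            max_window >= min_window)
  fmax <- max(f)
  if (fmax <= 0 || (fmax - min(f)) / max(abs(fmax), 1e-12) < 0.05)
    stop("no-amplification error: flat fluorescence curve")
  early <- f[3:8][f[3:8] < 0.05 * fmax]
  b0 <- if (length(early)) mean(early) else 0
  cand <- which(f > b0 & f < 0.9 * fmax)
  best <- NULL
  for (w in seq(max_window, min_window)) {
    if (length(cand) < w) next
    for (s in seq_len(length(cand) - w + 1L)) {
      idx <- cand[s:(s + w - 1L)]
      if (!all(diff(idx) == 1L)) next
      r2 <- .window_r2(f, idx, b0)
      if (is.null(best) || r2 > best$r2 + 1e-12) best <- list(idx = idx, r2 = r2)
    }
  }
  if (is.null(best))
    stop("no-amplification error: no usable log-linear window")
  idx <- best$idx
  # refine the baseline within the window: maximize log-linearity
  upper <- min(f[idx]) * 0.999999
  b <- if (upper > 0)
    optimize(function(bb) .window_r2(f, idx, bb), c(0, upper),
             maximum = TRUE, tol = 1e-10)$maximum
  else 0
  fit <- lm(log10(f[idx] - b) ~ idx)
  r2 <- summary(fit)$r.squared
  E <- 10^coef(fit)[[2]]
  flags <- character(0)
  if (r2 < 0.99) flags <- c(flags, "low_r_squared")
  if (E <= 1 || E > 2.2) flags <- c(flags, "efficiency_out_of_range")
  structure(list(E = E, window = range(idx), r_squared = r2,
                 baseline = b, flags = flags),
            class = "gliadex_efficiency")
}

.window_r2 <- function(f, idx, b) {
  y <- f[idx] - b
  if (any(y <= 0)) return(-Inf)
  y <- log10(y)
  r <- suppressWarnings(cor(idx, y))
  if (!is.finite(r)) -Inf else r^2
}

#' Call the quantification cycle (Cq) at a fluorescence threshold
#'
#' Fractional cycle at which the curve crosses `threshold`, by linear
#' interpolation in log fluorescence between the bracketing cycles.
#' Monotone in the threshold. A threshold never reached (e.g. above the
#' plateau) yields `NA` with an `undefined` flag.
#'
#' @param fluorescence numeric vector per cycle (background-corrected).
#' @param threshold fluorescence threshold within the exponential phase.
#' @return list: `Cq` (fractional cycle or NA), `flags`.
#' @export
call_cq <- function(fluorescence, threshold) {
  f <- as.numeric(fluorescence)
  stopifnot(threshold > 0)
  cross <- which(f >= threshold)
  if (!length(cross))
    return(list(Cq = NA_real_, flags = "undefined"))
  c2 <- cross[1]
  if (c2 == 1L) return(list(Cq = 1, flags = "reached_before_first_cycle"))
  f1 <- f[c2 - 1L]; f2 <- f[c2]
  if (f1 <= 0)
    return(list(Cq = as.numeric(c2), flags = "nonpositive_bracket"))
  cq <- (c2 - 1L) + (log(threshold) - log(f1)) / (log(f2) - log(f1))
  list(Cq = cq, flags = character(0))
}

#' Starting quantity from threshold, efficiency and Cq
#'
#' Evaluates `N0 = threshold / E^Cq`.
#'
#' @param threshold fluorescence threshold (arbitrary units).
#' @param E amplification efficiency per cycle, must exceed 1.
#' @param Cq quantification cycle (>= 0).
#' @return N0 in the threshold's units.
#' @export
compute_n0 <- function(threshold, E, Cq) {
  if (any(E <= 1)) stop("domain error: efficiency must exceed 1")
  stopifnot(all(threshold > 0), all(Cq >= 0))
  threshold / E^Cq
}

#' geNorm reference-gene stability
#'
#' For each gene j, `M_j` is the mean over the other genes k of the
#' standard deviation across samples of log2(expr_j / expr_k). The least
#' stable gene (highest M) is excluded iteratively until two remain; at
#' each step the pairwise variation `V(n/n+1)` = SD across samples of
#' log2(NF_n / NF_{n+1}) is recorded, with NF_n the geometric mean of the
#' n most stable genes.
#'
#' @param expr numeric matrix, reference genes x samples, all values > 0.
#' @return list of class `gliadex_genorm`: `M` (full-set stability per
#'   gene), `exclusion_order` (least stable first), `stability_order`
#'   (most stable first; the final two genes are tied and kept in input
#'   order), `V` (named vector, `V2/3` etc.).
#' @export
genorm_stability <- function(expr) {
  expr <- as.matrix(expr)
  if (any(expr <= 0)) stop("domain error: expression values must be > 0")
  g <- nrow(expr)
  stopifnot(g >= 3L, ncol(expr) >= 2L)
  genes <- rownames(expr) %||% paste0("gene", seq_len(g))
  rownames(expr) <- genes
  lx <- log2(expr)
  m_of <- function(rows) {
    vapply(rows, function(j) {
      others <- setdiff(rows, j)
      mean(vapply(others, function(k) sd(lx[j, ] - lx[k, ]), numeric(1)))
    }, numeric(1))
  }
  remaining <- genes
  M_full <- setNames(m_of(genes), genes)
  exclusion <- character(0)
  while (length(remaining) > 2L) {
    M <- m_of(remaining)
    worst <- remaining[which.max(M)]
    exclusion <- c(exclusion, worst)
    remaining <- setdiff(remaining, worst)
  }
  stability <- c(remaining, rev(exclusion))
  geo_nf <- function(rows) exp(colMeans(log(expr[rows, , drop = FALSE])))
  V <- numeric(0)
  if (g >= 3L) {
    for (nn in 2:(g - 1L)) {
      nf_n <- geo_nf(stability[seq_len(nn)])
      nf_n1 <- geo_nf(stability[seq_len(nn + 1L)])
      V[sprintf("V%d/%d", nn, nn + 1L)] <- sd(log2(nf_n / nf_n1))
    }
  }
  structure(list(M = M_full, exclusion_order = exclusion,
                 stability_order = stability, V = V),
            class = "gliadex_genorm")
}

#' Per-sample normalization factors from stable reference genes
#'
#' NF per sample is the geometric mean of the given genes' expression,
#' rescaled so the geometric mean of NF across samples equals 1 (the
#' geNorm convention; normalized expression is then N0 / NF).
#'
#' @param expr numeric matrix, reference genes x samples, values > 0.
#' @param genes_used character vector of row names to use.
#' @return list: `nf` (named per sample), `genes_used`.
#' @export
normalization_factors <- function(expr, genes_used) {
  expr <- as.matrix(expr)
  if (!length(genes_used)) stop("genes_used must be non-empty")
  if (!all(genes_used %in% rownames(expr)))
    stop("unknown reference gene(s): ",
         paste(setdiff(genes_used, rownames(expr)), collapse = ", "))
  sub <- expr[genes_used, , drop = FALSE]
  if (any(sub <= 0)) stop("domain error: expression values must be > 0")
  nf <- exp(colMeans(log(sub)))
  nf <- nf / exp(mean(log(nf)))
  list(nf = nf, genes_used = genes_used)
}

#' Quantify a table of fluorescence curves
#'
#' Convenience wrapper: per (target) a common threshold is placed at the
#' geometric middle of the exponential windows of that target's wells;
#' per well the efficiency, Cq and N0 are computed. Wells whose curve
#' never crosses the threshold are flagged with NA.
#'
#' @param curves long data.frame: well, target, sample, cycle,
#'   fluorescence.
#' @return data.frame: well, target, sample, E, r_squared, threshold, Cq,
#'   N0, flags.
#' @export
quantify_qpcr <- function(curves) {
  stopifnot(all(c("well", "target", "sample", "cycle", "fluorescence") %in%
                  names(curves)))
  wells <- unique(curves[, c("well", "target", "sample")])
  eff <- lapply(seq_len(nrow(wells)), function(i) {
    sel <- curves$well == wells$well[i]
    f <- curves$fluorescence[sel][order(curves$cycle[sel])]
    est <- estimate_efficiency(f)
    list(est = est, f = f - est$baseline)
  })
  thr <- tapply(seq_len(nrow(wells)), wells$target, function(ix) {
    mids <- vapply(ix, function(i) {
      w <- eff[[i]]$est$window
      exp(mean(log(pmax(eff[[i]]$f[w[1]:w[2]], 1e-12))))
    }, numeric(1))
    exp(mean(log(mids)))
  })
  rows <- lapply(seq_len(nrow(wells)), function(i) {
    est <- eff[[i]]$est
    th <- thr[[wells$target[i]]]
    cq <- call_cq(eff[[i]]$f, th)
    n0 <- if (is.na(cq$Cq)) NA_real_ else compute_n0(th, est$E, cq$Cq)
    data.frame(well = wells$well[i], target = wells$target[i],
               sample = wells$sample[i], E = est$E,
               r_squared = est$r_squared, threshold = th, Cq = cq$Cq,
               N0 = n0,
               flags = paste(c(est$flags, cq$flags), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
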