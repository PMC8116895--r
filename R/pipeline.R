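# Pipeline assembly: variant recovery from read pairs, and the composed
# end-to-end run over the synthetic study design.

#' Recover high-confidence amplicon variants from paired-end reads
#'
#' The full read pipeline: merge pairs, filter by length and expected
#' errors, pool-dereplicate with per-sample sizes, UNOISE-style denoise
#' (chimera removal included), greedy 99%-identity clustering, and the
#' high-confidence support filter (>= `min_reads` reads in >=
#' `min_samples` samples).
#'
#' @param read_pairs named list per sample: `list(fwd, rev)` data.frames
#'   with columns `seq`, `qual` (as returned by [simulate_reads()]), or
#'   paths `list(fastq1, fastq2)` readable by [read_fastq()].
#' @param params a [pipeline_params()].
#' @param verbose print per-stage counts.
#' @return list: `abundance` (a `gliadex_abundance` of retained cluster
#'   centroids, with sequences), `centroids` (pre-filter denoised set),
#'   `logs` (per-sample merge/filter counts).
#' @export
recover_variants <- function(read_pairs, params = pipeline_params(),
                             verbose = FALSE) {
  stopifnot(length(read_pairs) >= 1L)
  samples <- names(read_pairs) %||% paste0("S", seq_along(read_pairs))
  seqs <- character(0); sample_of <- character(0)
  logs <- list()
  for (i in seq_along(read_pairs)) {
    rp <- read_pairs[[i]]
    if (!is.null(rp$fastq1)) {
      fwd <- read_fastq(rp$fastq1); rev <- read_fastq(rp$fastq2)
    } else {
      fwd <- rp$fwd; rev <- rp$rev
    }
    merged <- merge_pairs(fwd$seq, fwd$qual, rev$seq, rev$qual)
    fl <- filter_reads(merged, params)
    logs[[samples[i]]] <- fl$log
    if (verbose)
      message(samples[i], ": ", paste(names(fl$log), fl$log,
                                      sep = "=", collapse = " "))
    seqs <- c(seqs, fl$reads$seq)
    sample_of <- c(sample_of, rep(samples[i], nrow(fl$reads)))
  }
  if (!length(seqs)) stop("no reads survived merging and filtering")
  uniq <- dereplicate(seqs, sample_of)
  cent <- denoise(uniq, alpha = params$unoise_alpha)
  cl <- cluster_centroids(cent$seq, cent$size,
                          identity = params$cluster_identity)
  cent_rows <- which(cl$is_centroid)
  counts <- t(vapply(cent_rows, function(ci)
    colSums(cent$sample_counts[cl$cluster == ci, , drop = FALSE]),
    numeric(ncol(cent$sample_counts))))
  if (ncol(cent$sample_counts) == 1L) counts <- matrix(counts, ncol = 1L)
  colnames(counts) <- colnames(cent$sample_counts)
  rownames(counts) <- sprintf("zotu%03d", seq_along(cent_rows))
  abund <- structure(list(counts = counts,
                          unassigned = setNames(numeric(ncol(counts)),
                                                colnames(counts)),
                          ties = 0L, provenance = "raw",
                          sequences = setNames(cent$seq[cent_rows],
                                               rownames(counts))),
                     class = "gliadex_abundance")
  abund <- high_confidence_filter(abund, params$min_reads,
                                  params$min_samples)
  if (verbose)
    message("denoised centroids=", length(cent$seq),
            " clusters=", length(cent_rows),
            " high-confidence=", nrow(abund$counts),
            " chimeras_removed=", cent$n_chimeras_removed)
  list(abundance = abund, centroids = cent, logs = logs)
}

#' Read a run configuration file
#'
#' YAML with keys mirroring [pipeline_params()] plus seeds, design name
#' and output directory; every tunable of the read pipeline defaults to
#' the study's printed value (160, 1.0, 2.0, 0.99, 75, 3).
#'
#' @param path YAML file.
#' @return list of class `gliadex_run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  run_config(params = do.call(pipeline_params, cfg$params %||% list()),
             design = cfg$design %||% "bw208_like",
             design_seed = cfg$design_seed %||% 42L,
             read_seed = cfg$read_seed %||% 1L,
             depth_per_sample = cfg$depth_per_sample %||% 100000L,
             per_base_error = cfg$per_base_error %||% 0.001,
             n_dna_samples = cfg$n_dna_samples %||% 4L,
             expression_seed = cfg$expression_seed %||% 1L,
             qpcr_seed = cfg$qpcr_seed %||% 1L,
             out_dir = cfg$out_dir)
}

#' @rdname read_run_config
#' @param params,design,design_seed,read_seed,depth_per_sample,per_base_error
#'   pipeline and simulation settings.
#' @param n_dna_samples,expression_seed,qpcr_seed,out_dir run settings;
#'   `out_dir = NULL` keeps everything in memory.
#' @export
run_config <- function(params = pipeline_params(), design = "bw208_like",
                       design_seed = 42L, read_seed = 1L,
                       depth_per_sample = 100000L, per_base_error = 0.001,
                       n_dna_samples = 4L, expression_seed = 1L,
                       qpcr_seed = 1L, out_dir = NULL) {
  if (!identical(design, "bw208_like"))
    stop("unknown design: ", design)
  structure(list(params = params, design = design,
                 design_seed = as.integer(design_seed),
                 read_seed = as.integer(read_seed),
                 depth_per_sample = as.integer(depth_per_sample),
                 per_base_error = per_base_error,
                 n_dna_samples = as.integer(n_dna_samples),
                 expression_seed = as.integer(expression_seed),
                 qpcr_seed = as.integer(qpcr_seed), out_dir = out_dir),
            class = "gliadex_run_config")
}

#' Run the composed pipeline on the synthetic study design
#'
#' Executes simulate -> recover -> annotate -> qPCR normalization ->
#' expression aggregation on the configured ground-truth family. Every
#' stage logs its parameters and in/out counts in the returned manifest;
#' outputs are reproducible bit-for-bit given the configured seeds.
#'
#' @param config a [run_config()] (or path to a YAML for
#'   [read_run_config()]).
#' @return list: `family`, `recovery`, `annotation`, `qpcr`,
#'   `expression`, `manifest`.
#' @export
run_pipeline <- function(config = run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "gliadex_run_config"))
  manifest <- list(params = unclass(config$params),
                   seeds = list(design = config$design_seed,
                                reads = config$read_seed,
                                expression = config$expression_seed,
                                qpcr = config$qpcr_seed))

  family <- build_family(bw208_like_design(seed = config$design_seed))
  manifest$family <- list(n_variants = length(family$sequences),
                          n_pseudogenes = sum(family$truth$is_pseudogene))

  ab <- matrix(rep(family$truth$dna_frequency, config$n_dna_samples),
               ncol = config$n_dna_samples,
               dimnames = list(family$truth$variant_id,
                               sprintf("dna%02d", seq_len(config$n_dna_samples))))
  reads <- simulate_reads(family$sequences, ab,
                          read_sim_config(depth_per_sample = config$depth_per_sample,
                                          per_base_error = config$per_base_error,
                                          chimera_rate = 0.005,
                                          seed = config$read_seed))
  recovery <- recover_variants(reads, config$params)
  manifest$recovery <- list(n_reads = config$depth_per_sample * config$n_dna_samples,
                            n_recovered = nrow(recovery$abundance$counts))

  annotation <- if (length(recovery$abundance$sequences))
    annotate_variants(recovery$abundance$sequences,
                      reference_cds = family$template_cds,
                      exemplars = family$exemplars)
  else data.frame(variant_id = character(0), is_pseudogene = logical(0))
  manifest$annotation <- list(n_pseudogenes = sum(annotation$is_pseudogene))

  expr_design <- expression_design(family, seed = config$expression_seed)
  expr <- simulate_expression(expr_design)
  refs <- c(CDC = 80, ADP_RF = 120, RLI = 60)
  wells <- do.call(rbind, lapply(names(refs), function(g)
    data.frame(well = paste0(g, "_", expr$sample_sheet$sample_id), target = g,
               sample = expr$sample_sheet$sample_id,
               n0 = refs[[g]] * 1e-6, stringsAsFactors = FALSE)))
  curves <- simulate_qpcr(qpcr_sim_config(seed = config$qpcr_seed), wells)
  quant <- quantify_qpcr(curves)
  n0 <- with(quant, tapply(N0, list(target, sample), mean))
  gn <- genorm_stability(n0)
  nf <- normalization_factors(n0, gn$stability_order[1:2])
  manifest$qpcr <- list(stability_order = gn$stability_order, V = gn$V)

  agg <- aggregate_abundance(expr$abundance, family$truth,
                             keys = c("genome", "genotype", "n_level"))
  fc <- fold_change(agg, keys = c("genome", "genotype"))
  manifest$expression <- list(n_samples = nrow(expr$sample_sheet))

  res <- list(family = family, recovery = recovery, annotation = annotation,
              qpcr = list(quant = quant, genorm = gn, nf = nf),
              expression = list(design = expr_design, abundance = expr$abundance,
                                sample_sheet = expr$sample_sheet,
                                aggregate = agg, fold_change = fc),
              manifest = manifest)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_family(family, file.path(config$out_dir, "family"))
    write_fasta(recovery$abundance$sequences,
                file.path(config$out_dir, "recovered_variants.fasta"))
    write_tsv(as.data.frame(recovery$abundance$counts),
              file.path(config$out_dir, "abundance_raw.tsv"))
    write_tsv(annotation, file.path(config$out_dir, "annotation.tsv"))
    write_tsv(quant, file.path(config$out_dir, "qpcr_quant.tsv"))
    write_tsv(fc, file.path(config$out_dir, "fold_change.tsv"))
    writeLines(yaml::as.yaml(manifest),
               file.path(config$out_dir, "manifest.yaml"))
  }
  res
}
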