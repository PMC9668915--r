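# End-to-end orchestration: simulate (or load) inputs, trim, pile up
# coverage, window + normalize, run the fold screen, telomere and
# mitochondrial quantification, and the proteomics comparison; write every
# artifact plus a JSON summary. One global seed fans out to per-stage seeds
# through derive_seed(), so each stage is independently re-runnable.

#' Build a pipeline configuration
#'
#' @param outdir Output directory (created if missing).
#' @param seed Global integer seed.
#' @param simulate List of simulation settings (set to NULL to load inputs
#'   from `paths` instead): `genome` (arguments for [genome_spec()]),
#'   `mean_depth`, `read_len`, `planted` ("default", "null", or a
#'   [planted_signal()]), `lfq` (arguments for [lfq_spec()]).
#' @param paths When not simulating: named list with genome (FASTA),
#'   annotation (GFF3/BED), alignments (named character vector of SAM/TSV
#'   paths, one per sample), lfq + design (TSV).
#' @param window_sizes Window sizes to tabulate (default 20/100/500/5000).
#' @param scan_w Window size used by the fold screen (default 5000).
#' @param cutoff,criterion Fold screen settings (see [fold_change_screen()]).
#' @param motif Telomere motif (default TTAGGGTTAGGG).
#' @param w_mito MT window size (default 500).
#' @param trim List: trim3, qmin, min_len for the FASTQ trimming stage.
#' @param proteomics List: fc_cutoff, fdr_level, n_perm, min_valid.
#' @param external_genes Optional character vector (or file of one symbol
#'   per line) of external expression gene symbols for the overlap step.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(outdir, seed = 1L,
                            simulate = list(),
                            paths = NULL,
                            window_sizes = c(20L, 100L, 500L, 5000L),
                            scan_w = 5000L,
                            cutoff = 1.5,
                            criterion = "either",
                            motif = "TTAGGGTTAGGG",
                            w_mito = 500L,
                            trim = list(trim3 = 15L, qmin = 25L, min_len = 20L),
                            proteomics = list(fc_cutoff = 2, fdr_level = 0.05,
                                              n_perm = 250L, min_valid = 2L),
                            external_genes = NULL) {
  structure(list(outdir = outdir, seed = as.integer(seed),
                 simulate = simulate, paths = paths,
                 window_sizes = as.integer(window_sizes),
                 scan_w = as.integer(scan_w), cutoff = cutoff,
                 criterion = criterion, motif = motif,
                 w_mito = as.integer(w_mito), trim = trim,
                 proteomics = proteomics, external_genes = external_genes),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

log_line <- function(log, ...) c(log, sprintf(...))

#' Run the full pipeline
#'
#' Executes simulate/load, trimming, coverage, windowing and normalization,
#' the fold screen with region merging and gene overlap, telomere and
#' mitochondrial quantification, and the proteomics comparison. All tables
#' and tracks are written under `config$outdir`; a deterministic JSON
#' summary (identical bytes for identical config + seed) is written to
#' `summary.json`. When a truth record exists, a scoring block reports the
#' screen's and the proteomics test's sensitivity and false-discovery
#' proportion against the planted truth.
#'
#' @param config A [pipeline_config()] (or path to a YAML file).
#' @return The summary as a list, invisibly; side effect: files in outdir.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  log <- character(0)
  summary <- list(seed = config$seed)

  ## stage: inputs -----------------------------------------------------------
  if (!is.null(config$simulate)) {
    sim_cfg <- config$simulate
    gspec <- do.call(genome_spec, c(sim_cfg$genome %||% list(),
                                    list(seed = derive_seed(config$seed, "genome_spec"))))
    genome <- make_genome(gspec)
    planted <- sim_cfg$planted %||% "default"
    if (identical(planted, "default")) planted <- default_planted_signal(genome)
    if (identical(planted, "null")) planted <- planted_signal()
    sim <- simulate_alignments(genome, planted,
                               mean_depth = sim_cfg$mean_depth %||% 10,
                               read_len = sim_cfg$read_len %||% 100L,
                               seed = derive_seed(config$seed, "alignments"))
    lspec <- do.call(lfq_spec, c(sim_cfg$lfq %||% list(),
                                 list(seed = derive_seed(config$seed, "lfq_spec"))))
    lfq_sim <- simulate_lfq(lspec)
    truth <- sim$truth
    truth$differential <- lfq_sim$truth$differential
    chrom_lengths <- c(setNames(genome$spec$chrom_lengths, genome$spec$chrom_names),
                       setNames(genome$spec$mt_len, genome$spec$mt_name))
    annotation <- genome$annotation
    alignments <- sim$alignments
    lfq <- lfq_sim$lfq; design <- lfq_sim$design
    write_fasta(genome$seq, file.path(config$outdir, "genome.fa"))
    write_annotation_gff3(annotation, file.path(config$outdir, "annotation.gff3"))
    write_genes_bed(annotation, file.path(config$outdir, "genes.bed"))
    for (s in names(alignments)) {
      write_sam(alignments[[s]], chrom_lengths,
                file.path(config$outdir, paste0(s, ".sam")))
      write_fastq(alignments[[s]],
                  file.path(config$outdir, paste0(s, ".fastq")))
    }
    write_lfq_tsv(lfq, file.path(config$outdir, "lfq.tsv"),
                  design, file.path(config$outdir, "design.tsv"))
    write_truth(truth, file.path(config$outdir, "truth.json"))
    log <- log_line(log, "simulate: %d samples, %d chromosomes, %d LFQ proteins",
                    length(alignments), length(chrom_lengths), nrow(lfq))
  } else {
    p <- config$paths
    genome_seq <- read_fasta(p$genome)
    chrom_lengths <- setNames(nchar(genome_seq), names(genome_seq))
    annotation <- read_intervals(p$annotation)
    alignments <- lapply(p$alignments, read_alignments,
                         chrom_lengths = chrom_lengths)
    lfq_in <- read_lfq_tsv(p$lfq, p$design)
    lfq <- lfq_in$lfq; design <- lfq_in$design
    truth <- if (!is.null(p$truth)) read_truth(p$truth) else NULL
    log <- log_line(log, "load: %d samples from disk", length(alignments))
  }
  samples <- names(alignments)

  ## stage: trimming (FASTQ QC mirror; coverage uses true placements) --------
  trim_counts <- purrr::imap(alignments, function(aln, s) {
    tr <- trim_reads(aln[, c("read_id", "seq", "qual")],
                     trim3 = config$trim$trim3, qmin = config$trim$qmin,
                     min_len = config$trim$min_len)
    trim_log(tr)
  })
  summary$trimming <- purrr::imap(trim_counts, function(tl, s)
    list(n_in = tl$n_in, n_kept = tl$n_kept, n_discarded = tl$n_discarded))
  log <- log_line(log, "trim: %s",
                  paste(sprintf("%s %d/%d kept", samples,
                                vapply(trim_counts, `[[`, 0, "n_kept"),
                                vapply(trim_counts, `[[`, 0, "n_in")),
                        collapse = "; "))

  ## stage: coverage + windows ----------------------------------------------
  tracks <- purrr::imap(alignments, function(aln, s)
    compute_coverage(aln, chrom_lengths, sample = s))
  summary$coverage <- purrr::map(tracks, function(tr)
    list(genome_total = tr$genome_total,
         mean_depth = tr$genome_total / sum(as.numeric(chrom_lengths))))
  windows <- list()
  for (w in config$window_sizes) {
    wt <- window_coverage(tracks, w)
    norm <- suppressWarnings(normalize_per_chromosome(wt))
    windows[[as.character(w)]] <- norm
    write_windows_tsv(norm, file.path(config$outdir,
                                      sprintf("windows_w%d.tsv", w)))
  }
  log <- log_line(log, "windows: sizes %s tabulated",
                  paste(config$window_sizes, collapse = ","))

  ## stage: fold screen ------------------------------------------------------
  scan_wt <- windows[[as.character(config$scan_w)]]
  if (is.null(scan_wt)) {
    scan_wt <- suppressWarnings(
      normalize_per_chromosome(window_coverage(tracks, config$scan_w)))
  }
  calls <- fold_change_screen(scan_wt, cutoff = config$cutoff,
                              criterion = config$criterion)
  regions <- merge_regions(calls)
  readr::write_tsv(as_tibble(calls), file.path(config$outdir, "calls.tsv"),
                   progress = FALSE)
  readr::write_tsv(regions, file.path(config$outdir, "regions.tsv"),
                   progress = FALSE)
  if (nrow(calls) > 0) {
    write_calls_bed(regions, file.path(config$outdir, "regions.bed"))
  }
  gene_hits <- overlap_genes(regions, annotation)
  readr::write_tsv(gene_hits, file.path(config$outdir, "region_gene_hits.tsv"),
                   progress = FALSE)
  call_counts <- calls |>
    group_by(.data$sample, .data$direction) |>
    summarise(n = dplyr::n(), .groups = "drop")
  region_counts <- regions |>
    group_by(.data$sample, .data$direction) |>
    summarise(n = dplyr::n(), .groups = "drop")
  summary$screen <- list(
    w = config$scan_w, cutoff = config$cutoff, criterion = config$criterion,
    n_calls = nrow(calls), n_regions = nrow(regions),
    calls_by_sample = as.list(setNames(call_counts$n,
                                       paste(call_counts$sample,
                                             call_counts$direction, sep = "_"))),
    regions_by_sample = as.list(setNames(region_counts$n,
                                         paste(region_counts$sample,
                                               region_counts$direction, sep = "_"))),
    n_gene_hits = nrow(gene_hits))
  log <- log_line(log, "screen: %d calls, %d regions at w=%d",
                  nrow(calls), nrow(regions), config$scan_w)

  if (!is.null(config$external_genes)) {
    ext <- config$external_genes
    if (length(ext) == 1 && file.exists(ext)) ext <- readLines(ext)
    ov <- expression_overlap(unique(gene_hits$symbol), ext)
    readr::write_tsv(ov$membership,
                     file.path(config$outdir, "expression_overlap.tsv"),
                     progress = FALSE)
    summary$expression_overlap <- as.list(ov$counts)
  }

  ## stage: telomere + mitochondria ------------------------------------------
  telo <- count_motif(alignments, motif = config$motif)
  readr::write_tsv(telo, file.path(config$outdir, "telomere_counts.tsv"),
                   progress = FALSE)
  telo_test <- telomere_compare(telo)
  mito <- mito_enrichment(unname(tracks), w = config$w_mito)
  readr::write_tsv(mito$profile, file.path(config$outdir, "mito_profile.tsv"),
                   progress = FALSE)
  telo_tot <- telo |>
    filter(.data$chrom != "unmapped") |>
    group_by(.data$sample) |>
    summarise(per_million = sum(.data$motif_count) / sum(.data$reads) * 1e6,
              .groups = "drop")
  summary$telomere <- list(
    motif = config$motif,
    per_million = as.list(setNames(telo_tot$per_million, telo_tot$sample)),
    anova_p = telo_test$test$p_value)
  summary$mito <- list(
    w = config$w_mito,
    mt_fraction = as.list(setNames(mito$summary$mt_fraction,
                                   mito$summary$sample)),
    anova_p = mito$test$p_value)
  log <- log_line(log, "telomere ANOVA p=%.3g; mito ANOVA p=%.3g",
                  telo_test$test$p_value, mito$test$p_value)

  ## stage: proteomics --------------------------------------------------------
  common <- detect_common(lfq, design)
  dr <- dynamic_range(lfq, design)
  diff <- differential_test(lfq, design,
                            fc_cutoff = config$proteomics$fc_cutoff %||% 2,
                            fdr_level = config$proteomics$fdr_level %||% 0.05,
                            n_perm = config$proteomics$n_perm %||% 250L,
                            min_valid = config$proteomics$min_valid %||% 2L,
                            seed = derive_seed(config$seed, "proteomics"))
  readr::write_tsv(tidy(diff), file.path(config$outdir, "differential.tsv"),
                   progress = FALSE)
  sig <- filter(lfq, .data$protein %in% diff$protein[diff$significant])
  if (nrow(sig) >= 2) {
    cl <- zscore_cluster(sig, design)
    readr::write_tsv(tibble(order = seq_along(cl$order),
                            protein = rownames(cl$z)),
                     file.path(config$outdir, "cluster_order.tsv"),
                     progress = FALSE)
  }
  summary$proteomics <- list(
    venn = as.list(common$counts),
    span_orders = attr(dr, "span_orders"),
    n_significant = sum(diff$significant),
    n_tested = nrow(diff))
  log <- log_line(log, "proteomics: %d/%d significant; span %.2f orders",
                  sum(diff$significant), nrow(diff), attr(dr, "span_orders"))

  ## stage: scoring against truth --------------------------------------------
  if (!is.null(truth)) {
    summary$scoring <- score_run(calls, diff, truth, config$scan_w,
                                 chrom_lengths, samples)
    log <- log_line(log,
                    "scoring: screen sens=%.3f fcr=%.4f; proteomics sens=%.3f fdp=%.3f",
                    summary$scoring$screen$sensitivity,
                    summary$scoring$screen$false_call_rate,
                    summary$scoring$proteomics$sensitivity,
                    summary$scoring$proteomics$fdp)
  }

  writeLines(log, file.path(config$outdir, "run.log"))
  jsonlite::write_json(summary, file.path(config$outdir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       null = "null")
  invisible(summary)
}

# Expand planted intervals into the w-grid and score calls against them.
score_screen_calls <- function(calls, truth, w, chrom_lengths, samples) {
  iv <- truth$planted$intervals
  iv <- iv[iv$direction != "neutral", , drop = FALSE]
  planted <- if (nrow(iv) == 0) {
    tibble(sample = character(), chrom = character(), window = integer(),
           direction = character())
  } else {
    bind_rows(lapply(seq_len(nrow(iv)), function(i) {
      # windows fully inside the planted interval
      w0 <- ceiling(iv$start[i] / w)
      w1 <- floor(iv$end[i] / w) - 1L
      if (w1 < w0) return(NULL)
      tibble(sample = iv$sample[i], chrom = iv$chrom[i],
             window = seq.int(w0, w1), direction = iv$direction[i])
    }))
  }
  n_windows_total <- sum(ceiling(as.numeric(chrom_lengths) / w)) * length(samples)
  hit <- inner_join(planted, as_tibble(calls),
                    by = c("sample", "chrom", "window", "direction"))
  false_calls <- dplyr::anti_join(as_tibble(calls), planted,
                                  by = c("sample", "chrom", "window"))
  list(
    n_planted_windows = nrow(planted),
    sensitivity = if (nrow(planted) > 0) nrow(hit) / nrow(planted) else NA,
    n_false_calls = nrow(false_calls),
    false_call_rate = nrow(false_calls) /
      max(1, n_windows_total - nrow(planted))
  )
}

score_run <- function(calls, diff, truth, w, chrom_lengths, samples) {
  out <- list()
  if (!is.null(truth$planted)) {
    out$screen <- score_screen_calls(calls, truth, w, chrom_lengths, samples)
  }
  if (!is.null(truth$differential)) {
    planted <- truth$differential$protein
    tested <- intersect(planted, diff$protein)
    sig <- diff$protein[diff$significant]
    out$proteomics <- list(
      n_planted = length(planted),
      n_planted_tested = length(tested),
      # sensitivity of the test among planted proteins that passed the
      # min_valid presence filter; _all divides by every planted protein,
      # including those erased by low-abundance censoring before testing
      sensitivity = if (length(tested) > 0)
        length(intersect(sig, tested)) / length(tested) else NA,
      sensitivity_all = if (length(planted) > 0)
        length(intersect(sig, planted)) / length(planted) else NA,
      n_significant = length(sig),
      fdp = length(setdiff(sig, planted)) / max(1, length(sig))
    )
  }
  out
}
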