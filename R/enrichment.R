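# The genome-wide screen: per window, flag the focal sample as enriched or
# depleted at a fold cutoff relative to the other two samples, under the two
# printed criteria — against each other sample simultaneously, or against
# the average of the other two. Calls are merged into regions and
# intersected with genes, exons and external gene lists.

#' Screen normalized windows for fold enrichment / depletion
#'
#' For every window and every focal sample, ratios of normalized coverage
#' are formed against each of the other two samples and against their
#' average, with a pseudocount added to numerator and denominator. A window
#' is called enriched for the focal sample when the chosen criterion holds
#' at `>= cutoff`, depleted at `<= 1/cutoff` (reciprocal, so the screen is
#' symmetric under sample swap).
#'
#' @param wt A per-chromosome-normalized window tibble with exactly three
#'   samples.
#' @param cutoff Fold cutoff (> 1; default 1.5).
#' @param ratio_pseudocount Added to both sides of every ratio; default half
#'   the smallest positive normalized value the table can represent — one
#'   unit of raw coverage over the largest per-sample-per-chromosome total
#'   (prevents infinite folds on zero windows while leaving ratios between
#'   covered windows essentially untouched, and preserving ordering). Falls
#'   back to half the smallest observed positive value when raw totals are
#'   unavailable.
#' @param criterion "either" (default; union of the two criteria, which one
#'   held is recorded), "simultaneous", or "vs_average".
#' @return A tibble of calls: sample (focal), chrom, start, end, window,
#'   direction, fold_vs_each, fold_vs_average, criterion. Attributes carry
#'   the cutoff, the pseudocount used and the number of windows skipped for
#'   absent values.
#' @export
fold_change_screen <- function(wt, cutoff = 1.5, ratio_pseudocount = NULL,
                               criterion = c("either", "simultaneous",
                                             "vs_average")) {
  criterion <- match.arg(criterion)
  stopifnot(inherits(wt, "window_tbl"))
  if (window_mode(wt) != "per_chromosome") {
    abort("screen expects a per-chromosome normalized window table")
  }
  check_that(cutoff > 1, "cutoff", "must be > 1")
  samples <- sort(unique(wt$sample))
  if (length(samples) != 3) abort("screen requires exactly 3 samples")

  wide <- tidyr::pivot_wider(as_tibble(wt)[, c("chrom", "start", "end",
                                               "window", "sample", "value")],
                             names_from = "sample", values_from = "value")
  vals <- as.matrix(wide[, samples])
  ok <- stats::complete.cases(vals)
  n_skipped <- sum(!ok)
  wide <- wide[ok, , drop = FALSE]
  vals <- vals[ok, , drop = FALSE]
  if (is.null(ratio_pseudocount)) {
    if ("raw" %in% names(wt)) {
      totals <- as_tibble(wt) |>
        group_by(.data$sample, .data$chrom) |>
        summarise(total = sum(.data$raw), .groups = "drop") |>
        pull("total")
      ratio_pseudocount <- if (any(totals > 0)) 0.5 / max(totals) else 0
    } else {
      pos <- vals[vals > 0]
      ratio_pseudocount <- if (length(pos)) min(pos) / 2 else 0
    }
  }
  check_that(ratio_pseudocount >= 0, "ratio_pseudocount", "must be >= 0")
  pc <- ratio_pseudocount

  calls <- list()
  for (f in seq_along(samples)) {
    others <- setdiff(seq_along(samples), f)
    vf <- vals[, f] + pc
    r1 <- vf / (vals[, others[1]] + pc)
    r2 <- vf / (vals[, others[2]] + pc)
    ravg <- vf / (rowMeans(vals[, others, drop = FALSE]) + pc)
    enr_sim <- r1 >= cutoff & r2 >= cutoff
    enr_avg <- ravg >= cutoff
    dep_sim <- r1 <= 1 / cutoff & r2 <= 1 / cutoff
    dep_avg <- ravg <= 1 / cutoff
    pick <- function(sim, avg) switch(criterion,
      either = sim | avg, simultaneous = sim, vs_average = avg)
    enr <- pick(enr_sim, enr_avg)
    dep <- pick(dep_sim, dep_avg)
    hit <- enr | dep
    if (!any(hit)) next
    crit_of <- function(sim, avg) dplyr::case_when(
      sim & avg ~ "both", sim ~ "simultaneous", TRUE ~ "vs_average")
    calls[[f]] <- tibble(
      sample = samples[f],
      chrom = wide$chrom[hit], start = wide$start[hit], end = wide$end[hit],
      window = wide$window[hit],
      direction = unname(ifelse(enr[hit], "enriched", "depleted")),
      fold_vs_each = unname(ifelse(enr[hit], pmin(r1, r2)[hit],
                                   pmax(r1, r2)[hit])),
      fold_vs_average = unname(ravg[hit]),
      criterion = unname(ifelse(enr[hit], crit_of(enr_sim, enr_avg)[hit],
                                crit_of(dep_sim, dep_avg)[hit]))
    )
  }
  out <- bind_rows(calls)
  if (nrow(out) == 0) {
    out <- tibble(sample = character(), chrom = character(), start = double(),
                  end = double(), window = integer(), direction = character(),
                  fold_vs_each = double(), fold_vs_average = double(),
                  criterion = character())
  }
  out <- arrange(out, .data$sample, .data$chrom, .data$window)
  structure(out, class = c("enrichment_calls", class(tibble())),
            cutoff = cutoff, ratio_pseudocount = pc, n_skipped = n_skipped,
            w = window_size(wt))
}

#' Merge window calls into regions
#'
#' Maximal runs of consecutive windows sharing focal sample, chromosome and
#' direction become one region; the region is the screen's reporting unit.
#'
#' @param calls Output of [fold_change_screen()].
#' @return A tibble: sample, direction, chrom, start, end, n_windows,
#'   best_fold (most extreme fold_vs_each in the run).
#' @export
merge_regions <- function(calls) {
  if (nrow(calls) == 0) {
    return(tibble(sample = character(), direction = character(),
                  chrom = character(), start = double(), end = double(),
                  n_windows = integer(), best_fold = double()))
  }
  calls |>
    arrange(.data$sample, .data$direction, .data$chrom, .data$window) |>
    group_by(.data$sample, .data$direction, .data$chrom) |>
    mutate(run = cumsum(c(1L, diff(.data$window) != 1L))) |>
    group_by(.data$sample, .data$direction, .data$chrom, .data$run) |>
    summarise(start = min(.data$start), end = max(.data$end),
              n_windows = dplyr::n(),
              best_fold = if (.data$direction[1] == "enriched")
                max(.data$fold_vs_each) else min(.data$fold_vs_each),
              .groups = "drop") |>
    select(-"run") |>
    arrange(.data$sample, .data$chrom, .data$start)
}

#' Overlap regions with gene / exon annotation
#'
#' Half-open interval intersection on both sides; a hit requires at least
#' 1 nt of overlap. Gene-level and exon-level hits are distinguished by the
#' `kind` column. Regions on chromosomes absent from the annotation are
#' skipped with a warning summary.
#'
#' @param regions Tibble from [merge_regions()] (or any tibble with chrom,
#'   start, end).
#' @param annotation Annotation tibble (gene_id, symbol, chrom, start, end,
#'   strand, kind).
#' @return A tibble: region columns plus gene_id, symbol, kind, overlap_nt.
#' @export
overlap_genes <- function(regions, annotation) {
  if (nrow(regions) == 0) {
    return(tibble(sample = character(), direction = character(),
                  chrom = character(), start = double(), end = double(),
                  gene_id = character(), symbol = character(),
                  kind = character(), overlap_nt = double()))
  }
  miss <- setdiff(unique(regions$chrom), unique(annotation$chrom))
  if (length(miss) > 0) {
    warn(sprintf("%d region(s) on chromosomes absent from annotation skipped: %s",
                 sum(regions$chrom %in% miss), paste(miss, collapse = ", ")))
    regions <- filter(regions, !.data$chrom %in% miss)
  }
  r_gr <- GenomicRanges::GRanges(regions$chrom,
                                 IRanges::IRanges(regions$start + 1, regions$end))
  a_gr <- GenomicRanges::GRanges(annotation$chrom,
                                 IRanges::IRanges(annotation$start + 1,
                                                  annotation$end))
  hits <- GenomicRanges::findOverlaps(r_gr, a_gr)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  ov <- GenomicRanges::width(GenomicRanges::pintersect(r_gr[qi], a_gr[si]))
  bind_cols(
    regions[qi, , drop = FALSE],
    tibble(gene_id = annotation$gene_id[si],
           symbol = annotation$symbol[si],
           kind = annotation$kind[si],
           overlap_nt = as.double(ov))
  )
}

#' Per-gene window profile for a list of genes of interest
#'
#' Summarizes normalized window coverage (typically the 20-nt grid) across
#' each gene body for every sample: mean and max normalized window value,
#' the per-sample value relative to the three-sample mean
#' ([gene_sample_vs_mean()], visualization-only), and the focal sample's
#' fold against the mean of the other two samples.
#'
#' @param gene_list Character vector of gene symbols (case-insensitive).
#' @param wt Normalized window tibble (per-chromosome mode, usually w = 20).
#' @param annotation Annotation tibble.
#' @param focal Focal sample name for the fold column (default "ecTrap").
#' @return A tibble: symbol, sample, mean_value, max_value, rel_to_mean,
#'   fold_focal_vs_others; unresolvable symbols in attribute `unresolved`.
#' @export
roi_profile <- function(gene_list, wt, annotation, focal = "ecTrap") {
  genes <- filter(annotation, .data$kind == "gene")
  idx <- match(toupper(gene_list), toupper(genes$symbol))
  unresolved <- gene_list[is.na(idx)]
  resolved <- genes[idx[!is.na(idx)], , drop = FALSE]
  if (nrow(resolved) == 0) abort("no gene symbol could be resolved")
  samples <- sort(unique(wt$sample))
  pos <- wt$value[!is.na(wt$value) & wt$value > 0]
  pc <- if (length(pos)) min(pos) / 2 else 0
  out <- purrr::map_dfr(seq_len(nrow(resolved)), function(i) {
    g <- resolved[i, ]
    sub <- filter(as_tibble(wt), .data$chrom == g$chrom,
                  .data$end > g$start, .data$start < g$end)
    per <- sub |>
      group_by(.data$sample) |>
      summarise(mean_value = mean(.data$value, na.rm = TRUE),
                max_value = max(.data$value, na.rm = TRUE), .groups = "drop") |>
      mutate(symbol = g$symbol)
    if (nrow(per) == 3) {
      per$rel_to_mean <- gene_sample_vs_mean(per$mean_value)
      oth <- mean(per$mean_value[per$sample != focal])
      per$fold_focal_vs_others <-
        (per$mean_value[per$sample == focal] + pc) / (oth + pc)
    } else {
      per$rel_to_mean <- NA_real_
      per$fold_focal_vs_others <- NA_real_
    }
    per
  })
  out <- select(out, "symbol", "sample", "mean_value", "max_value",
                "rel_to_mean", "fold_focal_vs_others")
  attr(out, "unresolved") <- unresolved
  out
}

#' Overlap a screened gene list with an external expression gene list
#'
#' Pure set algebra on case-folded gene symbols: which screened genes appear
#' in the external expression table, which do not, and which external genes
#' were never hit.
#'
#' @param hit_symbols Character vector of gene symbols from the screen.
#' @param external_list Character vector of external gene symbols (non-empty).
#' @return A list: `counts` (one-row tibble: n_hit_in_list, n_hit_not_in_list,
#'   n_list_not_hit) and `membership` (tibble: symbol, in_hits, in_list).
#' @export
expression_overlap <- function(hit_symbols, external_list) {
  if (length(external_list) == 0) abort("external gene list is empty")
  h <- unique(toupper(hit_symbols))
  e <- unique(toupper(external_list))
  universe <- union(h, e)
  membership <- tibble(symbol = sort(universe),
                       in_hits = sort(universe) %in% h,
                       in_list = sort(universe) %in% e)
  counts <- tibble(n_hit_in_list = length(intersect(h, e)),
                   n_hit_not_in_list = length(setdiff(h, e)),
                   n_list_not_hit = length(setdiff(e, h)))
  list(counts = counts, membership = membership)
}

#' Write calls or regions as BED6+ (score = 1000 * min(fold, 10))
#' @param x Calls or regions tibble.
#' @param path Output path.
#' @export
write_calls_bed <- function(x, path) {
  fold <- if ("best_fold" %in% names(x)) x$best_fold else x$fold_vs_each
  fold[x$direction == "depleted"] <- 1 / fold[x$direction == "depleted"]
  lines <- sprintf("%s\t%d\t%d\t%s:%s\t%d\t.",
                   x$chrom, as.integer(x$start), as.integer(x$end),
                   x$sample, x$direction,
                   as.integer(round(1000 * pmin(fold, 10))))
  writeLines(lines, path)
  invisible(path)
}
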