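# Per-base coverage and fixed-width window math. Windows tile each
# chromosome (step = width): the per-chromosome and genome-wide coverage
# fractions only sum to a meaningful total under tiling. The per-base pileup
# is delegated to IRanges::coverage; the windowing and both normalization
# fractions are implemented here.

#' Compute a per-base coverage track from alignments
#'
#' Depth at position p is the number of kept reads whose half-open interval
#' contains p. Reads below the MAPQ floor are excluded and counted.
#'
#' @param aln Alignment tibble (read_id, chrom, start, end, strand, mapq).
#' @param chrom_lengths Named vector of chromosome lengths (the windowing
#'   grid covers every chromosome, covered or not).
#' @param sample Sample identifier stored on the track.
#' @param mapq_min MAPQ floor; default 0 keeps all reads.
#' @return A `coverage_track`: integer depth vectors per chromosome,
#'   per-chromosome totals, genome total, and the excluded-read count.
#' @export
compute_coverage <- function(aln, chrom_lengths, sample = "sample",
                             mapq_min = 0L) {
  unknown <- setdiff(unique(aln$chrom), names(chrom_lengths))
  if (length(unknown) > 0) {
    abort(paste0("alignments reference unknown chromosomes: ",
                 paste(unknown, collapse = ", ")))
  }
  keep <- aln$mapq >= mapq_min
  n_excluded <- sum(!keep)
  aln <- aln[keep, , drop = FALSE]
  if (any(aln$end > chrom_lengths[aln$chrom])) {
    abort("read extends past chromosome end")
  }
  depth <- lapply(names(chrom_lengths), function(chrom) {
    L <- as.integer(chrom_lengths[[chrom]])
    sub <- aln[aln$chrom == chrom, , drop = FALSE]
    if (nrow(sub) == 0) return(integer(L))
    ir <- IRanges::IRanges(start = sub$start + 1L, end = sub$end)
    as.integer(IRanges::coverage(ir, width = L))
  })
  names(depth) <- names(chrom_lengths)
  totals <- vapply(depth, function(d) sum(as.numeric(d)), 0)
  structure(list(sample = sample, depth = depth,
                 chrom_totals = totals, genome_total = sum(totals),
                 n_excluded = n_excluded),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("<coverage_track> sample=%s, %d chromosomes, genome total %.0f\n",
              x$sample, length(x$depth), x$genome_total))
  invisible(x)
}

#' Sum coverage into tiling windows
#'
#' Chromosomes are tiled by disjoint windows `[i*w, min((i+1)*w, L))`; the
#' last window may be short and is flagged. A window's value is the sum of
#' per-base depths inside it, so a read spanning a boundary contributes each
#' overlapped base to its own window.
#'
#' @param tracks A `coverage_track` or a list of them (one per sample).
#' @param w Window width in nt (>= 1).
#' @param drop_short Drop short terminal windows instead of keeping them.
#' @return A window tibble (class `window_tbl`): chrom, start, end, window
#'   (0-based index), sample, raw; attributes `w`, `mode = "raw"`.
#' @export
window_coverage <- function(tracks, w, drop_short = FALSE) {
  check_that(length(w) == 1 && w >= 1, "w", "must be a single value >= 1")
  w <- as.integer(w)
  if (inherits(tracks, "coverage_track")) tracks <- list(tracks)
  out <- bind_rows(lapply(tracks, function(tr) {
    bind_rows(lapply(names(tr$depth), function(chrom) {
      d <- tr$depth[[chrom]]
      L <- length(d)
      n_win <- ceiling(L / w)
      cs <- c(0, cumsum(as.numeric(d)))
      starts <- (seq_len(n_win) - 1L) * w
      ends <- pmin(starts + w, L)
      tibble(chrom = chrom, start = starts, end = ends,
             window = seq_len(n_win) - 1L, sample = tr$sample,
             raw = cs[ends + 1L] - cs[starts + 1L],
             short = ends - starts < w)
    }))
  }))
  if (drop_short) out <- filter(out, !.data$short)
  new_window_tbl(out, w = w, mode = "raw", pseudocount = NA_real_)
}

new_window_tbl <- function(df, w, mode, pseudocount) {
  structure(df, class = c("window_tbl", class(tibble())),
            w = w, mode = mode, pseudocount = pseudocount)
}

#' Window-table metadata
#' @param wt A window tibble.
#' @return Window size, normalization mode, or pseudocount.
#' @export
window_size <- function(wt) attr(wt, "w")

#' @rdname window_size
#' @export
window_mode <- function(wt) attr(wt, "mode")

#' Normalize windows per chromosome
#'
#' The per-chromosome coverage fraction: each window's value is its (raw +
#' pseudocount) coverage divided by the total (raw + pseudocount) coverage of
#' that sample on that chromosome, so values for one sample on one covered
#' chromosome sum to 1. Chromosomes with zero total coverage and zero
#' pseudocount yield absent (NA) values, excluded downstream.
#'
#' @param wt A raw window tibble from [window_coverage()].
#' @param pseudocount Non-negative value added to every window before
#'   forming the fraction (default 0, the fraction as printed).
#' @return The window tibble with a `value` column; mode `per_chromosome`.
#' @export
normalize_per_chromosome <- function(wt, pseudocount = 0) {
  stopifnot(inherits(wt, "window_tbl"))
  if (window_mode(wt) != "raw") abort("input must be a raw window table")
  check_that(pseudocount >= 0, "pseudocount", "must be >= 0")
  out <- wt |>
    group_by(.data$sample, .data$chrom) |>
    mutate(value = {
      num <- .data$raw + pseudocount
      den <- sum(num)
      if (den > 0) num / den else rep(NA_real_, length(num))
    }) |>
    ungroup()
  n_absent <- sum(is.na(out$value))
  if (n_absent > 0) {
    warn(sprintf("%d windows on zero-coverage chromosomes set to NA", n_absent))
  }
  new_window_tbl(out, w = window_size(wt), mode = "per_chromosome",
                 pseudocount = pseudocount)
}

#' Normalize windows genome-wide
#'
#' The genome-wide coverage fraction used for mitochondrial enrichment: each
#' window's (raw + pseudocount) coverage divided by the sample's total raw
#' coverage over the entire genome (all chromosomes, MT included).
#'
#' @inheritParams normalize_per_chromosome
#' @return The window tibble with a `value` column; mode `genome_wide`.
#' @export
normalize_genome_wide <- function(wt, pseudocount = 0) {
  stopifnot(inherits(wt, "window_tbl"))
  if (window_mode(wt) != "raw") abort("input must be a raw window table")
  check_that(pseudocount >= 0, "pseudocount", "must be >= 0")
  out <- wt |>
    group_by(.data$sample) |>
    mutate(value = {
      den <- sum(.data$raw)
      if (den == 0) abort(sprintf("zero genome-wide coverage for sample %s",
                                  .data$sample[1]))
      (.data$raw + pseudocount) / den
    }) |>
    ungroup()
  new_window_tbl(out, w = window_size(wt), mode = "genome_wide",
                 pseudocount = pseudocount)
}

#' Per-sample coverage relative to the three-sample mean
#'
#' For exactly three per-sample values of one gene, returns each value
#' divided by the mean of the three. This is the visualization-only rescaling
#' used for per-gene track plots; it plays no part in the genome-wide screen.
#'
#' @param values Numeric vector of length 3 (per-sample gene coverage, >= 0).
#' @return Ratios of length 3, or all-NA when every value is zero (excluded
#'   from plots).
#' @export
gene_sample_vs_mean <- function(values) {
  check_that(length(values) == 3 && all(values >= 0), "values",
             "need exactly 3 non-negative values")
  m <- mean(values)
  if (m == 0) return(rep(NA_real_, 3))
  values / m
}

#' Serialize a window table as bedGraph-like TSV
#' @param wt Window tibble.
#' @param path Output path.
#' @export
write_windows_tsv <- function(wt, path) {
  out <- mutate(as_tibble(wt), mode = window_mode(wt), w = window_size(wt))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
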