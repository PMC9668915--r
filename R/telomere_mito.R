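# Telomeric repeat quantification in read sequences and mitochondrial
# enrichment from genome-wide-normalized MT windows, with one-way ANOVA
# comparisons across samples.

count_in_seqs <- function(seqs, motif, mode) {
  if (length(seqs) == 0) return(integer(0))
  if (mode == "non_overlapping") {
    stringr::str_count(seqs, stringr::fixed(motif))
  } else {
    stringr::str_count(seqs, stringr::regex(paste0("(?=", motif, ")")))
  }
}

#' Count a telomeric motif in mapped reads, per sample and chromosome
#'
#' Occurrences of the motif (default the 12-mer TTAGGGTTAGGG) are counted in
#' each read's sequence, grouped by the chromosome the read maps to.
#' Non-overlapping mode advances past each match; overlapping mode counts
#' every starting position. With `both_strands` the reverse complement of
#' each read is searched as well (reads come from either strand of a
#' telomeric array). Counts per million mapped reads are reported alongside
#' raw counts.
#'
#' @param alignments Named list of per-sample alignment tibbles carrying a
#'   `seq` column (a single tibble is treated as one sample).
#' @param motif Uppercase ACGT motif.
#' @param mode "non_overlapping" (default) or "overlapping".
#' @param both_strands Also search the reverse complement (default TRUE).
#' @return A tibble: sample, chrom, reads, motif_count, per_million.
#' @export
count_motif <- function(alignments, motif = "TTAGGGTTAGGG",
                        mode = c("non_overlapping", "overlapping"),
                        both_strands = TRUE) {
  mode <- match.arg(mode)
  check_that(nchar(motif) > 0 && grepl("^[ACGT]+$", motif), "motif",
             "must be non-empty uppercase ACGT")
  if (is.data.frame(alignments)) alignments <- list(sample = alignments)
  bind_rows(purrr::imap(alignments, function(aln, s) {
    if (nrow(aln) == 0) {
      return(tibble(sample = s, chrom = character(), reads = integer(),
                    motif_count = integer(), per_million = double()))
    }
    chrom <- ifelse(is.na(aln$chrom) | aln$chrom == "*", "unmapped", aln$chrom)
    cnt <- count_in_seqs(aln$seq, motif, mode)
    if (both_strands) cnt <- cnt + count_in_seqs(revcomp(aln$seq), motif, mode)
    tibble(chrom = chrom, cnt = cnt) |>
      group_by(.data$chrom) |>
      summarise(reads = dplyr::n(), motif_count = sum(.data$cnt),
                .groups = "drop") |>
      mutate(sample = s,
             per_million = ifelse(.data$reads > 0,
                                  .data$motif_count / .data$reads * 1e6, 0)) |>
      select("sample", "chrom", "reads", "motif_count", "per_million")
  }))
}

#' Compare telomere content across samples by one-way ANOVA
#'
#' Per-chromosome per-million motif counts are treated as replicates within
#' each sample. Chromosomes with zero counts in every sample (and unmapped
#' reads) are dropped before testing.
#'
#' @param table Output of [count_motif()].
#' @return A list: `test` (the [anova_oneway()] result) and `matrix` (the
#'   audited input: chrom x sample per-million values).
#' @export
telomere_compare <- function(table) {
  tab <- filter(table, .data$chrom != "unmapped")
  keep <- tab |>
    group_by(.data$chrom) |>
    summarise(any_pos = any(.data$motif_count > 0), .groups = "drop") |>
    filter(.data$any_pos) |>
    pull("chrom")
  tab <- filter(tab, .data$chrom %in% keep)
  wide <- tidyr::pivot_wider(select(tab, "chrom", "sample", "per_million"),
                             names_from = "sample",
                             values_from = "per_million", values_fill = 0)
  if (ncol(wide) < 3 || nrow(wide) < 2) {
    abort("telomere_compare needs >= 2 samples with >= 2 chromosomes each")
  }
  groups <- as.list(wide[, -1, drop = FALSE])
  list(test = anova_oneway(groups), matrix = wide)
}

#' Mitochondrial enrichment by position and sample
#'
#' Tiles the MT chromosome into `w`-nt windows (default 500), normalizes
#' each window by the sample's genome-wide total coverage (the mitochondrial
#' coverage fraction), and summarizes: a positional profile, a per-sample MT
#' summary (sum of the sample's normalized MT windows), and a one-way ANOVA
#' across samples on the window values.
#'
#' @param tracks List of `coverage_track`s, one per sample.
#' @param w Window size (nt).
#' @param mt_name Name of the mitochondrial chromosome.
#' @return A list: `profile` (window tibble restricted to MT), `summary`
#'   (tibble: sample, mt_fraction), `test` (ANOVA result).
#' @export
mito_enrichment <- function(tracks, w = 500L, mt_name = "MT") {
  if (inherits(tracks, "coverage_track")) tracks <- list(tracks)
  missing_mt <- vapply(tracks, function(tr) !(mt_name %in% names(tr$depth)),
                       logical(1))
  if (any(missing_mt)) {
    abort(paste0("samples missing MT chromosome: ",
                 paste(vapply(tracks[missing_mt], `[[`, "", "sample"),
                       collapse = ", ")))
  }
  wt <- window_coverage(tracks, w = w)
  norm <- normalize_genome_wide(wt, pseudocount = 0)
  profile <- filter(as_tibble(norm), .data$chrom == mt_name)
  summary <- profile |>
    group_by(.data$sample) |>
    summarise(mt_fraction = sum(.data$value), .groups = "drop")
  groups <- split(profile$value, profile$sample)
  test <- if (length(groups) >= 2) anova_oneway(groups) else NULL
  list(profile = profile, summary = summary, test = test)
}
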