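# ggplot2 views of the main result types. Figures mirror the analyses:
# positional window profiles, mitochondrial position profiles, proteome
# dynamic range, a volcano of the differential test, a z-score heatmap of
# the clustered significant set, and per-gene relative-coverage tracks.

#' @importFrom ggplot2 ggplot aes geom_line geom_point geom_tile geom_col
#'   geom_hline geom_vline facet_wrap labs scale_fill_gradient2 theme_minimal
#'   autoplot
NULL

#' Plot normalized window values along a chromosome
#'
#' @param wt A window tibble.
#' @param chrom Chromosome to show (default: first).
#' @return A ggplot.
#' @export
plot_window_profile <- function(wt, chrom = NULL) {
  df <- as_tibble(wt)
  chrom <- chrom %||% df$chrom[1]
  df <- filter(df, .data$chrom == !!chrom)
  ycol <- if ("value" %in% names(df)) "value" else "raw"
  ggplot(df, aes(x = (.data$start + .data$end) / 2, y = .data[[ycol]],
                 colour = .data$sample)) +
    geom_line() +
    labs(x = sprintf("position on %s (nt)", chrom),
         y = sprintf("%s window coverage (w=%d, %s)", window_mode(wt),
                     window_size(wt), ycol),
         colour = "sample") +
    theme_minimal()
}

#' @rdname plot_window_profile
#' @param object,... Window tibble and ignored arguments (autoplot method).
#' @export
autoplot.window_tbl <- function(object, ...) plot_window_profile(object)

#' Plot the mitochondrial enrichment profile by position
#'
#' @param mito Result of [mito_enrichment()].
#' @return A ggplot.
#' @export
plot_mito_profile <- function(mito) {
  ggplot(mito$profile, aes(x = .data$window, y = .data$value,
                           colour = .data$sample)) +
    geom_line() + geom_point() +
    labs(x = "MT window index", y = "genome-wide normalized coverage",
         colour = "sample") +
    theme_minimal()
}

#' Plot proteome dynamic range
#'
#' Rank versus log10 median intensity, with reference-list proteins
#' highlighted.
#'
#' @param dr Result of [dynamic_range()].
#' @return A ggplot.
#' @export
plot_dynamic_range <- function(dr) {
  ggplot(dr, aes(x = .data$rank, y = .data$log10_intensity)) +
    geom_point(colour = "grey55", size = 0.6) +
    geom_point(data = filter(dr, .data$in_reference), colour = "darkorange") +
    labs(x = "abundance rank", y = "log10 median LFQ intensity") +
    theme_minimal()
}

#' Volcano plot of a differential proteomics result
#'
#' @param object A `netscan_diff` from [differential_test()].
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.netscan_diff <- function(object, ...) {
  s <- attr(object, "settings")
  df <- mutate(as_tibble(object),
               neg_log_q = -log10(pmax(.data$q_value, 1e-4)))
  ggplot(df, aes(x = .data$log2_fc, y = .data$neg_log_q,
                 colour = .data$significant)) +
    geom_point(size = 0.8) +
    geom_vline(xintercept = c(-log2(s$fc_cutoff), log2(s$fc_cutoff)),
               linetype = 2) +
    geom_hline(yintercept = -log10(s$fdr_level), linetype = 2) +
    labs(x = "log2 fold change", y = "-log10 permutation q") +
    theme_minimal()
}

#' Heatmap of z-scored intensities in cluster leaf order
#'
#' @param cl Result of [zscore_cluster()].
#' @return A ggplot.
#' @export
plot_zscore_heatmap <- function(cl) {
  df <- as_tibble(cl$z, rownames = "protein") |>
    tidyr::pivot_longer(-"protein", names_to = "replicate",
                        values_to = "z") |>
    mutate(protein = factor(.data$protein, levels = rev(rownames(cl$z))))
  ggplot(df, aes(x = .data$replicate, y = .data$protein, fill = .data$z)) +
    geom_tile() +
    scale_fill_gradient2(low = "navy", mid = "white", high = "firebrick") +
    labs(x = NULL, y = NULL, fill = "z") +
    theme_minimal()
}

#' Per-gene relative coverage track
#'
#' Bar track of each sample's gene coverage relative to the three-sample
#' mean (the visualization-only rescaling), one panel per gene.
#'
#' @param profile Result of [roi_profile()].
#' @return A ggplot.
#' @export
plot_gene_track <- function(profile) {
  ggplot(profile, aes(x = .data$sample, y = .data$rel_to_mean,
                      fill = .data$sample)) +
    geom_col() +
    geom_hline(yintercept = 1, linetype = 2) +
    facet_wrap(~symbol) +
    labs(x = NULL, y = "coverage relative to three-sample mean") +
    theme_minimal()
}
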