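# Two-group label-free proteomics: replicate presence intersection,
# dynamic-range ranking, Welch t with permutation-based FDR, and z-scored
# hierarchical clustering of the significant set. Absent measurements are
# NA, never zero, so presence/absence set algebra is well-defined.

split_groups <- function(lfq, design) {
  stopifnot(all(design$replicate %in% names(lfq)))
  groups <- unique(design$group)
  if (length(groups) != 2) abort("design must define exactly 2 groups")
  g1 <- design$replicate[design$group == groups[1]]
  g2 <- design$replicate[design$group == groups[2]]
  if (length(g1) < 2 || length(g2) < 2) abort("each group needs >= 2 replicates")
  list(names = groups, g1 = g1, g2 = g2)
}

#' Replicate presence intersection (Venn counts)
#'
#' A protein is "common" within a group when it is present (non-absent) in
#' every replicate of that group. Reports per-replicate totals, per-group
#' common counts, and the cross-group intersection / unique sets.
#'
#' @param lfq Tibble: `protein` plus one intensity column per replicate
#'   (NA = absent).
#' @param design Tibble: `replicate`, `group`.
#' @return A list: `per_replicate` (replicate, group, n_present), `counts`
#'   (group1_common, group2_common, both_common, only_group1, only_group2),
#'   `common` (named list of protein id vectors).
#' @export
detect_common <- function(lfq, design) {
  gs <- split_groups(lfq, design)
  present <- !is.na(as.matrix(lfq[, design$replicate]))
  per_replicate <- tibble(replicate = design$replicate, group = design$group,
                          n_present = unname(colSums(present)))
  common1 <- lfq$protein[rowSums(present[, gs$g1, drop = FALSE]) == length(gs$g1)]
  common2 <- lfq$protein[rowSums(present[, gs$g2, drop = FALSE]) == length(gs$g2)]
  both <- intersect(common1, common2)
  counts <- tibble(
    !!paste0(gs$names[1], "_common") := length(common1),
    !!paste0(gs$names[2], "_common") := length(common2),
    both_common = length(both),
    !!paste0("only_", gs$names[1]) := length(setdiff(common1, common2)),
    !!paste0("only_", gs$names[2]) := length(setdiff(common2, common1))
  )
  common <- setNames(list(common1, common2, both),
                     c(gs$names, "both"))
  list(per_replicate = per_replicate, counts = counts, common = common)
}

#' Dynamic-range ranking of a proteome
#'
#' Proteins are ranked by descending median of their present replicate
#' intensities (ties broken lexicographically by protein identifier). The
#' span of the proteome is reported in orders of magnitude, together with
#' how many reference-list proteins rank among the top `top_k`.
#'
#' @param lfq LFQ tibble.
#' @param design Design tibble; `group` selects which group's replicates to
#'   use (default: first group in the design). Pass `design = NULL` to use
#'   every intensity column.
#' @param reference_list Character vector of reference protein identifiers.
#' @param top_k Rank threshold for the reference lookup (default 100).
#' @param group Group name to rank (see `design`).
#' @return A tibble (rank, protein, median_intensity, log10_intensity,
#'   in_reference) with attributes `span_orders` and `n_reference_in_top`.
#' @export
dynamic_range <- function(lfq, design = NULL, reference_list = character(),
                          top_k = 100L, group = NULL) {
  cols <- if (is.null(design)) setdiff(names(lfq), "protein") else {
    g <- group %||% design$group[1]
    design$replicate[design$group == g]
  }
  mat <- as.matrix(lfq[, cols])
  med <- apply(mat, 1, function(r) median(r[!is.na(r)]))
  keep <- !is.na(med)
  if (!any(keep)) abort("no protein has a present intensity")
  out <- tibble(protein = lfq$protein[keep], median_intensity = med[keep]) |>
    arrange(dplyr::desc(.data$median_intensity), .data$protein) |>
    mutate(rank = dplyr::row_number(),
           log10_intensity = log10(.data$median_intensity),
           in_reference = toupper(.data$protein) %in% toupper(reference_list)) |>
    select("rank", "protein", "median_intensity", "log10_intensity",
           "in_reference")
  attr(out, "span_orders") <- max(out$log10_intensity) - min(out$log10_intensity)
  attr(out, "n_reference_in_top") <- sum(out$in_reference & out$rank <= top_k)
  out
}

# Row-wise Welch t on a log2 matrix with NAs; returns NA when either side
# has < 2 present values.
welch_t_rows <- function(x1, x2) {
  n1 <- rowSums(!is.na(x1)); n2 <- rowSums(!is.na(x2))
  m1 <- rowMeans(x1, na.rm = TRUE); m2 <- rowMeans(x2, na.rm = TRUE)
  v1 <- (rowSums(x1^2, na.rm = TRUE) - n1 * m1^2) / pmax(n1 - 1, 1)
  v2 <- (rowSums(x2^2, na.rm = TRUE) - n2 * m2^2) / pmax(n2 - 1, 1)
  se <- sqrt(v1 / n1 + v2 / n2)
  t <- (m1 - m2) / se
  t[n1 < 2 | n2 < 2 | se == 0] <- NA_real_
  t
}

#' Two-group differential test with permutation FDR
#'
#' Intensities are log2-transformed; each retained protein (>= `min_valid`
#' present values per group) gets a Welch t statistic between the two
#' groups. The null distribution comes from group-label permutations: every
#' distinct split when their number is <= 1,000 (20 for 3 vs 3, the observed
#' labelling included), otherwise `n_perm` random splits drawn with `seed`.
#' For each observed |t| threshold,
#' `FDR(t) = mean over permutations of #\{p: |t_perm| >= t\} / #\{p: |t_obs| >= t\}`,
#' clipped to [0, 1] and made monotone non-increasing in |t| by a running
#' minimum from the largest statistic. A protein is significant when its
#' q-value is <= `fdr_level` and its signed linear fold change reaches
#' `fc_cutoff`.
#'
#' @param lfq LFQ tibble (`protein` + replicate intensity columns, NA absent).
#' @param design Tibble `replicate`, `group` (exactly two groups, >= 2
#'   replicates each).
#' @param fc_cutoff Fold-change cutoff on the signed linear fold change
#'   (default 2; ratio >= 2 in either direction). With
#'   `fc_scale = "log2"` the cutoff applies to |log2 FC| instead.
#' @param fdr_level Permutation FDR level (default 0.05).
#' @param n_perm Number of random permutations when full enumeration is not
#'   feasible (>= 10).
#' @param seed Seed for random permutations.
#' @param min_valid Minimum present intensities per group (default 2).
#' @param fc_scale "linear" (default) or "log2".
#' @return A `netscan_diff` tibble: protein, mean_log2 per group, log2_fc,
#'   signed_fc, t, q_value, significant. Attributes: group names, number of
#'   permutations, settings. [tidy()] and [glance()] methods apply.
#' @export
differential_test <- function(lfq, design, fc_cutoff = 2.0, fdr_level = 0.05,
                              n_perm = 250L, seed = 1L, min_valid = 2L,
                              fc_scale = c("linear", "log2")) {
  fc_scale <- match.arg(fc_scale)
  if (n_perm < 10) abort("n_perm must be >= 10")
  gs <- split_groups(lfq, design)
  cols <- c(gs$g1, gs$g2)
  mat <- log2(as.matrix(lfq[, cols]))
  rownames(mat) <- lfq$protein
  n1 <- length(gs$g1); n2 <- length(gs$g2)
  present <- !is.na(mat)
  keep <- rowSums(present[, seq_len(n1), drop = FALSE]) >= min_valid &
    rowSums(present[, n1 + seq_len(n2), drop = FALSE]) >= min_valid
  mat <- mat[keep, , drop = FALSE]
  if (nrow(mat) == 0) abort("no protein passes the min_valid filter")

  m1 <- rowMeans(mat[, seq_len(n1), drop = FALSE], na.rm = TRUE)
  m2 <- rowMeans(mat[, n1 + seq_len(n2), drop = FALSE], na.rm = TRUE)
  log2_fc <- m1 - m2
  ratio <- 2^log2_fc
  signed_fc <- ifelse(ratio >= 1, ratio, -1 / ratio)
  t_obs <- welch_t_rows(mat[, seq_len(n1), drop = FALSE],
                        mat[, n1 + seq_len(n2), drop = FALSE])

  # distinct splits: which replicates play group 1. |t| is invariant under a
  # group swap, so swap-equivalent splits are counted once (the split keeping
  # replicate 1 in group 1); the observed labelling is excluded from the null
  # (with it, no q below 2/n_splits would ever be attainable).
  all_splits <- combn(n1 + n2, n1)
  canonical <- if (n1 == n2) {
    all_splits[, all_splits[1, ] == 1L, drop = FALSE]
  } else all_splits
  obs <- seq_len(n1)
  is_obs <- colSums(canonical == obs) == n1
  null_splits <- canonical[, !is_obs, drop = FALSE]
  if (ncol(null_splits) <= 1000) {
    splits <- null_splits
    perm_method <- "exhaustive"
  } else {
    set.seed(derive_seed(seed, "perm"))
    splits <- null_splits[, sample.int(ncol(null_splits), n_perm),
                          drop = FALSE]
    perm_method <- "random"
  }
  t_perm <- apply(splits, 2, function(ix) {
    abs(welch_t_rows(mat[, ix, drop = FALSE],
                     mat[, setdiff(seq_len(n1 + n2), ix), drop = FALSE]))
  })

  abs_t <- abs(t_obs)
  ord <- order(abs_t, decreasing = TRUE, na.last = TRUE)
  q <- rep(NA_real_, length(abs_t))
  valid <- which(!is.na(abs_t))
  tp <- as.vector(t_perm); tp <- tp[!is.na(tp)]
  tp_sorted <- sort(tp)
  n_splits <- ncol(splits)
  obs_sorted <- sort(abs_t[valid])
  for (i in valid) {
    thr <- abs_t[i]
    num <- (length(tp_sorted) -
              findInterval(thr, tp_sorted, left.open = TRUE)) / n_splits
    den <- length(obs_sorted) - findInterval(thr, obs_sorted, left.open = TRUE)
    q[i] <- min(1, max(0, num / den))
  }
  # enforce monotone non-increasing q in |t| (running min from largest |t|)
  q_run <- q
  run_min <- Inf
  for (i in ord) {
    if (is.na(q_run[i])) next
    run_min <- min(run_min, q_run[i])
    q_run[i] <- run_min
  }
  fc_ok <- if (fc_scale == "linear") abs(signed_fc) >= fc_cutoff else
    abs(log2_fc) >= fc_cutoff
  res <- tibble(protein = rownames(mat),
                mean_log2_g1 = m1, mean_log2_g2 = m2,
                log2_fc = log2_fc, signed_fc = signed_fc,
                t = t_obs, q_value = q_run,
                significant = !is.na(q_run) & q_run <= fdr_level & fc_ok)
  structure(res, class = c("netscan_diff", class(tibble())),
            groups = gs$names, n_splits = n_splits,
            perm_method = perm_method,
            settings = list(fc_cutoff = fc_cutoff, fdr_level = fdr_level,
                            min_valid = min_valid, fc_scale = fc_scale,
                            seed = seed))
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @export
tidy.netscan_diff <- function(x, ...) {
  as_tibble(x)
}

#' @export
glance.netscan_diff <- function(x, ...) {
  s <- attr(x, "settings")
  tibble(n_proteins = nrow(x),
         n_significant = sum(x$significant),
         n_up = sum(x$significant & x$signed_fc > 0),
         n_down = sum(x$significant & x$signed_fc < 0),
         fc_cutoff = s$fc_cutoff, fdr_level = s$fdr_level,
         n_splits = attr(x, "n_splits"),
         perm_method = attr(x, "perm_method"))
}

#' Z-score and hierarchically cluster proteins
#'
#' Each protein row is z-scored across its present replicate values
#' (mean 0, sample sd 1); rows with zero spread are flagged and placed last.
#' Agglomerative clustering uses Euclidean distance and average linkage
#' (absent values enter the distance as 0, the row mean, after z-scoring);
#' ties break deterministically by input order.
#'
#' @param lfq LFQ tibble restricted to the proteins of interest (>= 2 rows),
#'   e.g. the significant set of [differential_test()].
#' @param design Optional design; orders columns by group.
#' @return A list: `z` (z-scored matrix in leaf order), `order` (leaf order
#'   indices into the input), `hclust` (the tree), `constant` (protein ids
#'   with zero spread, appended after the tree's leaves).
#' @export
zscore_cluster <- function(lfq, design = NULL) {
  if (nrow(lfq) < 2) abort("need >= 2 proteins to cluster")
  cols <- if (is.null(design)) setdiff(names(lfq), "protein") else
    design$replicate
  mat <- as.matrix(lfq[, cols])
  rownames(mat) <- lfq$protein
  mu <- apply(mat, 1, function(r) mean(r, na.rm = TRUE))
  sdv <- apply(mat, 1, function(r) sd(r, na.rm = TRUE))
  constant <- is.na(sdv) | sdv == 0
  if (all(constant)) abort("all rows constant: nothing to cluster")
  z <- (mat - mu) / ifelse(constant, 1, sdv)
  z[is.na(z)] <- 0
  zc <- z[!constant, , drop = FALSE]
  if (nrow(zc) >= 2) {
    hc <- hclust(dist(zc, method = "euclidean"), method = "average")
    leaf <- hc$order
  } else {
    hc <- NULL
    leaf <- 1L
  }
  ord_ids <- c(rownames(zc)[leaf], rownames(mat)[constant])
  list(z = z[ord_ids, , drop = FALSE],
       order = match(ord_ids, lfq$protein),
       hclust = hc,
       constant = rownames(mat)[constant])
}

#' Write / read an LFQ table and design as TSV
#'
#' First column `protein`, remaining columns intensities; absent values are
#' written as the literal "NA". The design file has columns `replicate`,
#' `group`.
#'
#' @param lfq,design Tibbles as used throughout the module.
#' @param path,design_path Output paths.
#' @export
write_lfq_tsv <- function(lfq, path, design = NULL, design_path = NULL) {
  readr::write_tsv(lfq, path, progress = FALSE)
  if (!is.null(design) && !is.null(design_path)) {
    readr::write_tsv(design, design_path, progress = FALSE)
  }
  invisible(path)
}

#' @rdname write_lfq_tsv
#' @export
read_lfq_tsv <- function(path, design_path = NULL) {
  lfq <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  design <- if (!is.null(design_path)) {
    readr::read_tsv(design_path, show_col_types = FALSE, progress = FALSE)
  }
  list(lfq = lfq, design = design)
}
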