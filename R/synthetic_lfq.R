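# Synthetic label-free quantification (LFQ) tables: a log-normal baseline
# proteome spanning several orders of magnitude, two replicate groups,
# a planted subset of differential proteins, multiplicative replicate noise
# and missingness concentrated at low abundance.

#' Specification for a synthetic LFQ experiment
#'
#' @param n_proteins Number of proteins.
#' @param n_differential Number of proteins with a true group difference.
#' @param effect_size True linear ratio between group means for differential
#'   proteins (> 1; direction split ~50/50).
#' @param cv Replicate coefficient of variation (multiplicative log-normal
#'   noise).
#' @param missing_rate Target overall fraction of absent measurements,
#'   realized through a low-abundance censoring mechanism (never at random
#'   across the intensity range).
#' @param baseline_meanlog,baseline_sdlog Parameters of the log-normal
#'   baseline intensity distribution. The default sdlog spans > 5 orders of
#'   magnitude over a few thousand proteins.
#' @param group_sizes Integer vector of length 2 (replicates per group).
#' @param group_names Names of the two groups.
#' @param seed Integer seed.
#' @return An `lfq_spec` list.
#' @export
lfq_spec <- function(n_proteins = 2000L, n_differential = 126L,
                     effect_size = 4.0, cv = 0.15, missing_rate = 0.10,
                     baseline_meanlog = log(1e7),
                     baseline_sdlog = 0.9 * log(10),
                     group_sizes = c(3L, 3L),
                     group_names = c("benzonase", "untreated"),
                     seed = 1L) {
  check_that(n_proteins >= 1, "n_proteins", "must be >= 1")
  check_that(n_differential >= 0 && n_differential <= n_proteins,
             "n_differential", "must be in [0, n_proteins]")
  check_that(effect_size > 0, "effect_size", "must be > 0")
  check_that(cv > 0, "cv", "must be > 0")
  check_that(missing_rate >= 0 && missing_rate < 1, "missing_rate",
             "must be in [0, 1)")
  check_that(length(group_sizes) == 2 && all(group_sizes >= 2),
             "group_sizes", "two groups with >= 2 replicates each")
  structure(list(n_proteins = as.integer(n_proteins),
                 n_differential = as.integer(n_differential),
                 effect_size = effect_size, cv = cv,
                 missing_rate = missing_rate,
                 baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog,
                 group_sizes = as.integer(group_sizes),
                 group_names = group_names, seed = as.integer(seed)),
            class = "lfq_spec")
}

#' Simulate an LFQ protein-intensity table
#'
#' Exactly `n_differential` proteins receive a true group-mean linear ratio
#' equal to `effect_size` (applied symmetrically in log space, direction
#' split approximately 50/50). Replicate noise is multiplicative log-normal
#' with the stated CV. Measurements are censored to absent (NA) with a
#' probability that falls off logistically above a low-abundance threshold,
#' so missingness occurs only through the low-abundance mechanism.
#'
#' @param spec An [lfq_spec()].
#' @return A list of class `sim_lfq`: `lfq` (tibble: `protein` plus one
#'   intensity column per replicate, NA = absent), `design` (tibble:
#'   `replicate`, `group`), and `truth` (a [truth_record()] whose
#'   `differential` tibble lists planted proteins with direction and true
#'   ratio).
#' @export
simulate_lfq <- function(spec) {
  stopifnot(inherits(spec, "lfq_spec"))
  set.seed(derive_seed(spec$seed, "lfq"))
  n <- spec$n_proteins
  proteins <- sprintf("P%05d", seq_len(n))
  base <- rlnorm(n, spec$baseline_meanlog, spec$baseline_sdlog)

  diff_idx <- if (spec$n_differential > 0)
    sort(sample.int(n, spec$n_differential)) else integer(0)
  dir_up <- rep(FALSE, n)
  if (length(diff_idx) > 0) {
    up <- sample(c(TRUE, FALSE), length(diff_idx), replace = TRUE)
    dir_up[diff_idx] <- up
  }
  half <- sqrt(spec$effect_size)
  mean1 <- base; mean2 <- base
  if (length(diff_idx) > 0) {
    upi <- diff_idx[dir_up[diff_idx]]
    dni <- setdiff(diff_idx, upi)
    mean1[upi] <- base[upi] * half; mean2[upi] <- base[upi] / half
    mean1[dni] <- base[dni] / half; mean2[dni] <- base[dni] * half
  }

  sdlog <- sqrt(log(1 + spec$cv^2))
  reps1 <- sprintf("%s_rep%d", spec$group_names[1], seq_len(spec$group_sizes[1]))
  reps2 <- sprintf("%s_rep%d", spec$group_names[2], seq_len(spec$group_sizes[2]))
  mat <- cbind(
    vapply(seq_len(spec$group_sizes[1]),
           function(j) mean1 * rlnorm(n, -sdlog^2 / 2, sdlog), numeric(n)),
    vapply(seq_len(spec$group_sizes[2]),
           function(j) mean2 * rlnorm(n, -sdlog^2 / 2, sdlog), numeric(n))
  )
  colnames(mat) <- c(reps1, reps2)

  # low-abundance censoring: probability decays logistically with log10
  # intensity around the missing_rate quantile of the baseline distribution
  if (spec$missing_rate > 0) {
    thr <- quantile(log10(base), probs = spec$missing_rate, names = FALSE)
    pmiss <- plogis((thr - log10(mat)) / 0.3)
    mat[runif(length(mat)) < pmiss] <- NA_real_
  }

  lfq <- as_tibble(mat)
  lfq <- dplyr::bind_cols(tibble(protein = proteins), lfq)
  design <- tibble(replicate = c(reps1, reps2),
                   group = rep(spec$group_names, spec$group_sizes))
  differential <- tibble(
    protein = proteins[diff_idx],
    direction = ifelse(dir_up[diff_idx], "up", "down"),
    true_ratio = spec$effect_size
  )
  truth <- truth_record(differential = differential,
                        params = unclass(spec))
  structure(list(lfq = lfq, design = design, truth = truth),
            class = "sim_lfq")
}
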