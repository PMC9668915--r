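# Read simulator with planted copy-number, mitochondrial and telomeric
# signal. Reads are emitted pre-aligned (the true placement is the
# alignment), which makes coverage oracles exact; mapping is out of scope.

#' Planted signal for a multi-sample simulation
#'
#' @param samples Character vector of sample names (default the three roles
#'   HL60, dHL60, ecTrap).
#' @param intervals Tibble with columns `sample`, `chrom`, `start`, `end`
#'   (0-based half-open) and `multiplier` (> 0): per-base sampling intensity
#'   inside each interval is multiplied by `multiplier`. Intervals for one
#'   sample must not overlap. May be empty (null signal).
#' @param mt_multiplier Named or positional numeric vector, one per sample:
#'   multiplier on the mitochondrial sampling intensity.
#' @param telomere_rate Per-sample expected number of extra telomere-array
#'   reads per million core reads (each such read lies fully inside a
#'   telomeric array and therefore carries the repeat motif).
#' @return A `planted_signal` list with enrichment/depletion direction labels
#'   attached to the intervals (enriched if multiplier >= 1.5, depleted if
#'   <= 1/1.5, neutral otherwise).
#' @export
planted_signal <- function(samples = c("HL60", "dHL60", "ecTrap"),
                           intervals = NULL,
                           mt_multiplier = rep(1, length(samples)),
                           telomere_rate = rep(0, length(samples))) {
  if (is.null(intervals)) {
    intervals <- tibble(sample = character(), chrom = character(),
                        start = integer(), end = integer(),
                        multiplier = double())
  }
  check_that(all(intervals$multiplier > 0), "intervals", "multipliers must be > 0")
  check_that(all(intervals$start >= 0 & intervals$end > intervals$start),
             "intervals", "need 0 <= start < end")
  check_that(length(mt_multiplier) == length(samples) && all(mt_multiplier > 0),
             "mt_multiplier", "one positive value per sample")
  check_that(length(telomere_rate) == length(samples) && all(telomere_rate >= 0),
             "telomere_rate", "one non-negative value per sample")
  # overlap check within sample
  if (nrow(intervals) > 1) {
    by_s <- split(intervals, paste(intervals$sample, intervals$chrom))
    for (d in by_s) {
      d <- d[order(d$start), ]
      if (nrow(d) > 1 && any(d$start[-1] < d$end[-nrow(d)])) {
        abort("invalid `intervals`: overlapping intervals for one sample",
              class = "netscan_validation_error")
      }
    }
  }
  intervals$direction <- dplyr::case_when(
    intervals$multiplier >= 1.5 ~ "enriched",
    intervals$multiplier <= 1 / 1.5 ~ "depleted",
    TRUE ~ "neutral"
  )
  structure(list(samples = samples, intervals = intervals,
                 mt_multiplier = setNames(as.numeric(mt_multiplier), samples),
                 telomere_rate = setNames(as.numeric(telomere_rate), samples)),
            class = "planted_signal")
}

#' Default planted signal used by the demo pipeline
#'
#' Each sample receives one 2.0x enriched interval of two 5,000-nt windows
#' on its own chromosome and one 0.5x depleted interval of one window on the
#' next chromosome; the third sample (ecTrap role) additionally carries a
#' 10x mitochondrial multiplier and the highest telomere-read rate. Planted
#' regions are kept a small fraction of each chromosome so the
#' per-chromosome normalization denominator is only mildly perturbed, as in
#' a genome-scale run where differential regions are a small fraction of a
#' chromosome. Rates emulate the study's qualitative structure: the trap
#' sample enriched for mitochondrial DNA and telomeric repeats relative to
#' the cell samples.
#'
#' @param genome A `synthetic_genome`.
#' @param samples Sample names (three).
#' @return A [planted_signal()].
#' @export
default_planted_signal <- function(genome,
                                   samples = c("HL60", "dHL60", "ecTrap")) {
  spec <- genome$spec
  stopifnot(length(samples) == 3, length(spec$chrom_names) >= 3)
  w <- 5000L
  iv <- list()
  for (i in 1:3) {
    chrom_up <- spec$chrom_names[i]
    chrom_dn <- spec$chrom_names[(i %% 3) + 1L]
    L_up <- spec$chrom_lengths[i]
    L_dn <- spec$chrom_lengths[(i %% 3) + 1L]
    up0 <- as.integer(floor(L_up / (5 * w)) * w)            # ~20% in
    dn0 <- as.integer(floor(L_dn * 13 / (20 * w)) * w)      # ~65% in
    iv[[i]] <- tibble(
      sample = samples[i],
      chrom = c(chrom_up, chrom_dn),
      start = c(up0, dn0),
      end = c(up0 + 2L * w, dn0 + w),
      multiplier = c(2.0, 0.5)
    )
  }
  planted_signal(samples, bind_rows(iv),
                 mt_multiplier = c(1, 1, 10),
                 telomere_rate = c(1000, 5000, 15000))
}

telomere_arrays <- function(genome) {
  spec <- genome$spec
  tl <- spec$telomere_array_len
  bind_rows(lapply(seq_along(spec$chrom_names), function(i) {
    L <- spec$chrom_lengths[i]
    tibble(chrom = spec$chrom_names[i], start = c(0L, L - tl),
           end = c(tl, L), arm = c("p", "q"))
  }))
}

# Simulate 3' quality strings: baseline high quality, a fraction of reads
# with a terminal decay below Q25 (mimicking primer-end degradation that the
# trimming step must remove).
sim_quals <- function(n_reads, read_len, decay_frac) {
  base <- matrix(pmin(40L, pmax(2L, round(rnorm(n_reads * read_len, 36, 2)))),
                 nrow = n_reads)
  decay <- runif(n_reads) < decay_frac
  if (any(decay)) {
    dlen <- sample(10:30, sum(decay), replace = TRUE)
    idx <- which(decay)
    for (k in seq_along(idx)) {
      d <- dlen[k]
      tailq <- round(seq(24, 8, length.out = d))
      base[idx[k], (read_len - d + 1L):read_len] <- tailq
    }
  }
  vapply(seq_len(n_reads), function(i) int_to_qual(base[i, ]), "")
}

sim_reads_one_chrom <- function(chrom, L, rate, read_len, intervals) {
  max_start <- L - read_len
  if (max_start < 0) return(integer(0))
  # partition [0, max_start] start positions by multiplier
  brk <- sort(unique(c(0L, max_start + 1L,
                       pmin(intervals$start, max_start + 1L),
                       pmin(intervals$end, max_start + 1L))))
  starts <- integer(0)
  for (j in seq_len(length(brk) - 1L)) {
    s0 <- brk[j]; s1 <- brk[j + 1L]
    if (s1 <= s0) next
    mult <- 1
    hit <- which(intervals$start <= s0 & intervals$end >= s1)
    if (length(hit)) mult <- intervals$multiplier[hit[1L]]
    n <- rpois(1L, rate * (s1 - s0) * mult)
    if (n > 0) starts <- c(starts, s0 + sample.int(s1 - s0, n, replace = TRUE) - 1L)
  }
  starts
}

#' Simulate aligned reads for multiple samples
#'
#' Reads of fixed length are placed uniformly at random along each
#' chromosome; the per-base sampling intensity is multiplied inside planted
#' intervals and on the mitochondrial chromosome by the sample's multiplier.
#' Extra motif-bearing reads are drawn fully inside telomeric arrays at the
#' sample's telomere rate. Sequences come from the reference (reverse
#' complement on minus-strand reads); qualities include a configurable
#' fraction of reads with 3' decay below Q25.
#'
#' @param genome A `synthetic_genome` from [make_genome()].
#' @param planted A [planted_signal()]; defaults to no signal.
#' @param mean_depth Target mean coverage depth; scalar or one value per
#'   sample.
#' @param read_len Read length in nt (>= 20).
#' @param seed Integer seed.
#' @param q_decay_frac Fraction of reads given a 3' quality decay.
#' @return A list of class `sim_reads`: `alignments` (named list of per-sample
#'   tibbles with read_id, chrom, start, end, strand, mapq, seq, qual; 0-based
#'   half-open), and `truth` (a [truth_record()]).
#' @export
simulate_alignments <- function(genome, planted = planted_signal(),
                                mean_depth = 10, read_len = 100L,
                                seed = 1L, q_decay_frac = 0.2) {
  stopifnot(inherits(genome, "synthetic_genome"),
            inherits(planted, "planted_signal"))
  check_that(all(mean_depth > 0), "mean_depth", "must be > 0")
  check_that(read_len >= 20, "read_len", "must be >= 20")
  samples <- planted$samples
  depth <- rep_len(mean_depth, length(samples))
  chrom_len <- c(setNames(genome$spec$chrom_lengths, genome$spec$chrom_names),
                 setNames(genome$spec$mt_len, genome$spec$mt_name))
  bad <- dplyr::anti_join(planted$intervals,
                          tibble(chrom = names(chrom_len)), by = "chrom")
  if (nrow(bad) > 0 ||
      any(planted$intervals$end > chrom_len[planted$intervals$chrom])) {
    abort("planted interval outside genome bounds")
  }
  set.seed(derive_seed(seed, "reads"))
  arrays <- telomere_arrays(genome)
  aln <- list()
  telo_added <- setNames(integer(length(samples)), samples)
  for (si in seq_along(samples)) {
    s <- samples[si]
    per_chrom <- list()
    for (chrom in names(chrom_len)) {
      L <- chrom_len[[chrom]]
      mult_mt <- if (chrom == genome$spec$mt_name) planted$mt_multiplier[[s]] else 1
      iv <- filter(planted$intervals, .data$sample == s, .data$chrom == !!chrom)
      starts <- sim_reads_one_chrom(chrom, L, depth[si] / read_len * mult_mt,
                                    read_len, iv)
      if (length(starts) == 0) next
      per_chrom[[chrom]] <- tibble(chrom = chrom, start = starts)
    }
    core <- bind_rows(per_chrom)
    if (nrow(core) == 0) {
      core <- tibble(chrom = character(), start = integer())
    }
    n_core <- nrow(core)
    # planted telomeric reads, fully inside an array so each carries the motif
    n_telo <- rpois(1L, planted$telomere_rate[[s]] / 1e6 * n_core)
    if (n_telo > 0) {
      pick <- arrays[sample.int(nrow(arrays), n_telo, replace = TRUE), ]
      avail <- pick$end - pick$start - read_len
      tstart <- pick$start + vapply(avail, function(a)
        if (a > 0) sample.int(a, 1L) - 1L else 0L, 0L)
      core <- bind_rows(core, tibble(chrom = pick$chrom, start = tstart))
    }
    telo_added[s] <- n_telo
    core <- mutate(core,
                   end = .data$start + read_len,
                   strand = sample(c("+", "-"), dplyr::n(), replace = TRUE),
                   mapq = 60L,
                   read_id = sprintf("%s_r%06d", s, dplyr::row_number()))
    seqs <- substring(genome$seq[core$chrom], core$start + 1L, core$end)
    minus <- core$strand == "-"
    if (any(minus)) seqs[minus] <- revcomp(seqs[minus])
    core$seq <- unname(seqs)
    core$qual <- sim_quals(nrow(core), read_len, q_decay_frac)
    aln[[s]] <- select(core, "read_id", "chrom", "start", "end",
                       "strand", "mapq", "seq", "qual")
  }
  truth <- truth_record(planted, genome,
                        params = list(mean_depth = depth, read_len = read_len,
                                      seed = seed, q_decay_frac = q_decay_frac,
                                      telomere_reads_added = as.list(telo_added)))
  structure(list(alignments = aln, truth = truth), class = "sim_reads")
}
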