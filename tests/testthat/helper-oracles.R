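# Independent brute-force oracles and tiny fixture builders. These stay
# deliberately naive (per-position loops, explicit enumerations) so they are
# independent of the vectorized implementation paths they check.

# O(reads x length) pileup: count read-interval membership per position.
oracle_coverage <- function(aln, L) {
  depth <- integer(L)
  for (i in seq_len(nrow(aln))) {
    for (p in seq(aln$start[i] + 1L, aln$end[i])) depth[p] <- depth[p] + 1L
  }
  depth
}

# Windowed sums by explicit loop, short terminal window included.
oracle_windows <- function(depth, w) {
  L <- length(depth)
  n <- ceiling(L / w)
  vapply(seq_len(n), function(i) {
    lo <- (i - 1L) * w + 1L
    hi <- min(i * w, L)
    sum(depth[lo:hi])
  }, numeric(1))
}

# Motif occurrences by explicit position scan.
oracle_motif <- function(seq, motif, overlapping = FALSE) {
  n <- nchar(seq); m <- nchar(motif)
  count <- 0L; p <- 1L
  while (p + m - 1L <= n) {
    if (substr(seq, p, p + m - 1L) == motif) {
      count <- count + 1L
      p <- p + if (overlapping) 1L else m
    } else p <- p + 1L
  }
  count
}

oracle_revcomp <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(map[strsplit(s, "")[[1]]]), collapse = "")
}

# Average-linkage agglomeration from a distance matrix, recording merge
# heights; naive O(n^3).
oracle_average_linkage_heights <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA); bestd <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i >= j) next
        dd <- mean(d[clusters[[i]], clusters[[j]]])
        if (dd < bestd) { bestd <- dd; best <- c(i, j) }
      }
    }
    heights <- c(heights, bestd)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# Build a normalized window table directly from a matrix of per-window
# normalized values (windows x samples) on one chromosome, plus raw values
# scaled so pseudocount defaults stay negligible.
make_norm_windows <- function(values, w = 100L, chrom = "chrA",
                              raw_scale = 1e6) {
  samples <- colnames(values)
  df <- dplyr::bind_rows(lapply(samples, function(s) {
    tibble::tibble(chrom = chrom,
                   start = (seq_len(nrow(values)) - 1L) * w,
                   end = seq_len(nrow(values)) * w,
                   window = seq_len(nrow(values)) - 1L,
                   sample = s,
                   raw = values[, s] * raw_scale,
                   short = FALSE,
                   value = values[, s])
  }))
  structure(df, class = c("window_tbl", class(tibble::tibble())),
            w = w, mode = "per_chromosome", pseudocount = 0)
}

# Build a coverage_track directly from named depth vectors.
make_track <- function(depths, sample = "s") {
  totals <- vapply(depths, function(d) sum(as.numeric(d)), 0)
  structure(list(sample = sample, depth = lapply(depths, as.integer),
                 chrom_totals = totals, genome_total = sum(totals),
                 n_excluded = 0L),
            class = "coverage_track")
}

# Small three-sample simulation used across module tests.
small_sim <- function(seed, chrom_kb = 100L, planted = NULL, depth = 10,
                      telomere_rate = rep(0, 3), mt_multiplier = c(1, 1, 1)) {
  lens <- setNames(rep(chrom_kb * 1000L, 3), c("chr1", "chr2", "chr3"))
  g <- make_genome(genome_spec(chrom_lengths = lens, seed = seed))
  ps <- planted_signal(intervals = planted, telomere_rate = telomere_rate,
                       mt_multiplier = mt_multiplier)
  sim <- simulate_alignments(g, ps, mean_depth = depth, seed = seed + 1L)
  cl <- c(lens, setNames(g$spec$mt_len, g$spec$mt_name))
  tracks <- lapply(names(sim$alignments), function(s)
    compute_coverage(sim$alignments[[s]], cl, sample = s))
  list(genome = g, sim = sim, chrom_lengths = cl, tracks = tracks)
}

# Random telomere-motif-bearing reads: fragments of a long perfect repeat
# at random phase, optionally reverse-complemented, embedded in random
# flanking sequence.
random_telomere_reads <- function(n, read_len = 100L, seed = 1L) {
  set.seed(seed)
  array_seq <- strrep("TTAGGG", 40)
  vapply(seq_len(n), function(i) {
    k <- sample.int(read_len, 1L)  # telomeric portion length
    off <- sample.int(6L, 1L)
    telo <- substr(array_seq, off, off + k - 1L)
    flank_len <- read_len - nchar(telo)
    flank <- paste(sample(c("A", "C", "G", "T"), flank_len, replace = TRUE),
                   collapse = "")
    s <- paste0(telo, flank)
    if (runif(1) < 0.5) s <- oracle_revcomp(s)
    s
  }, "")
}
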