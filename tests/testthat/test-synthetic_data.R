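# Generator contracts: telomeric array construction, determinism, planted
# coverage signal, depth calibration, LFQ effect sizes, truth round-trips.

test_that("autosomes carry exact telomeric arrays and MT is present", {
  g <- make_genome(genome_spec(seed = 4))
  for (chrom in g$spec$chrom_names) {
    s <- g$seq[[chrom]]
    expect_identical(substr(s, 1, 600), strrep("TTAGGG", 100))
    # 3' array is TTAGGG on the minus strand
    expect_identical(substr(s, nchar(s) - 599, nchar(s)), strrep("CCCTAA", 100))
  }
  expect_true("MT" %in% names(g$seq))
  expect_equal(nchar(g$seq[["MT"]]), 2000L)
  expect_identical(g$telomere_3prime, "minus")
})

test_that("genome generation is deterministic and validates its spec", {
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  write_fasta(make_genome(genome_spec(seed = 9))$seq, f1)
  write_fasta(make_genome(genome_spec(seed = 9))$seq, f2)
  expect_identical(readLines(f1), readLines(f2))

  expect_error(genome_spec(mt_len = 400), "mt_len")
  expect_error(genome_spec(telomere_array_len = 601), "telomere_array_len")
  expect_error(genome_spec(gc_fraction = 1.2), "gc_fraction")
})

test_that("annotation places >= 10 non-overlapping genes per autosome outside arrays", {
  g <- make_genome(genome_spec(seed = 12))
  ann <- g$annotation
  genes <- dplyr::filter(ann, kind == "gene")
  for (chrom_i in g$spec$chrom_names) {
    gc <- dplyr::arrange(dplyr::filter(genes, chrom == chrom_i), start)
    expect_gte(nrow(gc), 10)
    expect_true(all(gc$start[-1] >= gc$end[-nrow(gc)]))  # non-overlapping
    L <- g$spec$chrom_lengths[[which(g$spec$chrom_names == chrom_i)]]
    expect_true(all(gc$start >= 600 & gc$end <= L - 600))
    # every gene has >= 1 exon inside its body
    for (i in seq_len(nrow(gc))) {
      ex <- dplyr::filter(ann, kind == "exon", symbol == gc$symbol[i])
      expect_gte(nrow(ex), 1)
      expect_true(all(ex$start >= gc$start[i] & ex$end <= gc$end[i]))
    }
  }
})

test_that("realized depth matches the target and the brute-force pileup", {
  lens <- c(chrA = 50000L)
  g <- make_genome(genome_spec(chrom_lengths = lens, seed = 2))
  sim <- simulate_alignments(g, planted_signal(samples = "s1"),
                             mean_depth = 10, seed = 31)
  aln <- sim$alignments$s1
  sub <- aln[aln$chrom == "chrA", ]
  depth <- oracle_coverage(sub, 50000L)
  expect_gte(mean(depth), 9.5)
  expect_lte(mean(depth), 10.5)
  # the package pileup equals the oracle
  tr <- compute_coverage(aln, c(lens, MT = 2000L), sample = "s1")
  expect_identical(tr$depth$chrA, depth)
})

test_that("mean realized/requested depth ratio is calibrated over 20 seeds", {
  lens <- c(chrA = 50000L)
  g <- make_genome(genome_spec(chrom_lengths = lens, seed = 2))
  ratios <- vapply(1:20, function(s) {
    sim <- simulate_alignments(g, planted_signal(samples = "s1"),
                               mean_depth = 8, seed = 100 + s)
    aln <- sim$alignments$s1
    sub <- aln[aln$chrom == "chrA", ]
    sum(as.numeric(sub$end - sub$start)) / 50000 / 8
  }, numeric(1))
  expect_gte(mean(ratios), 0.98)
  expect_lte(mean(ratios), 1.02)
})

test_that("planted MT multiplier shifts MT depth by the planted ratio", {
  lens <- c(chrA = 50000L)
  g <- make_genome(genome_spec(chrom_lengths = lens, seed = 6))
  ps <- planted_signal(samples = c("a", "b"), mt_multiplier = c(10, 1))
  sim <- simulate_alignments(g, ps, mean_depth = 10, seed = 77)
  mt_mean <- vapply(sim$alignments, function(aln) {
    sub <- aln[aln$chrom == "MT", ]
    mean(oracle_coverage(sub, 2000L))
  }, numeric(1))
  expect_gte(mt_mean[["a"]] / mt_mean[["b"]], 8)
  expect_lte(mt_mean[["a"]] / mt_mean[["b"]], 12)
})

test_that("planted intervals multiply local coverage and are bounds-checked", {
  lens <- c(chrA = 50000L)
  g <- make_genome(genome_spec(chrom_lengths = lens, seed = 6))
  iv <- tibble::tibble(sample = "s1", chrom = "chrA",
                       start = 10000L, end = 20000L, multiplier = 3)
  sim <- simulate_alignments(g, planted_signal("s1", iv), mean_depth = 10,
                             seed = 13)
  d <- oracle_coverage(sim$alignments$s1[sim$alignments$s1$chrom == "chrA", ],
                       50000L)
  inside <- mean(d[11000:19000]); outside <- mean(d[c(1000:9000, 21000:49000)])
  expect_gt(inside / outside, 2.5)
  expect_lt(inside / outside, 3.5)

  bad <- tibble::tibble(sample = "s1", chrom = "chrA",
                        start = 49000L, end = 51000L, multiplier = 2)
  expect_error(simulate_alignments(g, planted_signal("s1", bad)),
               "outside genome")
  expect_error(planted_signal("s1", dplyr::mutate(iv, multiplier = -1)),
               "multiplier")
})

test_that("read simulation is deterministic per seed", {
  lens <- c(chrA = 50000L)
  g <- make_genome(genome_spec(chrom_lengths = lens, seed = 6))
  s1 <- simulate_alignments(g, planted_signal("s1"), mean_depth = 5, seed = 42)
  s2 <- simulate_alignments(g, planted_signal("s1"), mean_depth = 5, seed = 42)
  expect_identical(s1$alignments, s2$alignments)
})

test_that("LFQ generator plants the stated effect size and is deterministic", {
  # null construction: every true ratio is 1
  null <- simulate_lfq(lfq_spec(n_proteins = 50, n_differential = 0, seed = 1))
  expect_equal(nrow(null$truth$differential), 0)

  s1 <- simulate_lfq(lfq_spec(n_proteins = 100, n_differential = 10, seed = 3))
  s2 <- simulate_lfq(lfq_spec(n_proteins = 100, n_differential = 10, seed = 3))
  expect_identical(s1$lfq, s2$lfq)

  # Monte-Carlo: realized group-mean ratios of planted proteins center on 4
  ratios <- unlist(lapply(1:200, function(s) {
    sim <- simulate_lfq(lfq_spec(n_proteins = 40, n_differential = 8,
                                 effect_size = 4, cv = 0.15,
                                 missing_rate = 0, seed = s))
    mat <- as.matrix(sim$lfq[, -1])
    g1 <- sim$design$replicate[sim$design$group == sim$design$group[1]]
    g2 <- setdiff(sim$design$replicate, g1)
    idx <- match(sim$truth$differential$protein, sim$lfq$protein)
    up <- sim$truth$differential$direction == "up"
    r <- rowMeans(mat[idx, g1, drop = FALSE]) /
      rowMeans(mat[idx, g2, drop = FALSE])
    ifelse(up, r, 1 / r)
  }))
  expect_gte(mean(ratios), 3.4)
  expect_lte(mean(ratios), 4.7)
})

test_that("LFQ missingness is concentrated at low abundance", {
  sim <- simulate_lfq(lfq_spec(n_proteins = 2000, missing_rate = 0.15,
                               n_differential = 0, seed = 8))
  mat <- as.matrix(sim$lfq[, -1])
  observed <- rowSums(!is.na(mat)) > 0   # fully censored rows have no rank
  m <- mat[observed, , drop = FALSE]
  base_rank <- rank(rowMeans(m, na.rm = TRUE))
  miss_frac <- rowMeans(is.na(m))
  n <- nrow(m)
  low <- miss_frac[base_rank <= n / 5]; high <- miss_frac[base_rank > 4 * n / 5]
  expect_gt(mean(low), 10 * max(mean(high), 1e-6))
})

test_that("truth records round-trip losslessly through JSON", {
  lens <- c(chrA = 50000L)
  g <- make_genome(genome_spec(chrom_lengths = lens, seed = 6))
  iv <- tibble::tibble(sample = "s1", chrom = "chrA",
                       start = 1000L, end = 3000L, multiplier = 2)
  sim <- simulate_alignments(g, planted_signal("s1", iv), mean_depth = 2,
                             seed = 4)
  path <- tempfile(fileext = ".json")
  write_truth(sim$truth, path)
  back <- read_truth(path)
  expect_equal(back$planted$intervals, sim$truth$planted$intervals)
  expect_equal(back$planted$mt_multiplier, sim$truth$planted$mt_multiplier)
  expect_equal(back$genome$chrom_lengths$chrA, 50000L)
  # truth consistency: planted intervals lie within the genome
  expect_true(all(back$planted$intervals$end <=
                    unlist(back$genome$chrom_lengths)[back$planted$intervals$chrom]))

  lsim <- simulate_lfq(lfq_spec(n_proteins = 30, n_differential = 5, seed = 2))
  write_truth(lsim$truth, path)
  lback <- read_truth(path)
  expect_equal(lback$differential, lsim$truth$differential)
  expect_true(all(lback$differential$protein %in% lsim$lfq$protein))
})
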