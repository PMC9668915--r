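# Coverage pileup, window tiling and the two normalization fractions,
# checked against brute-force per-base oracles and hand arithmetic.

test_that("pileup definition: depth counts half-open read membership", {
  aln0 <- tibble::tibble(read_id = character(), chrom = character(),
                         start = integer(), end = integer(),
                         strand = character(), mapq = integer())
  tr0 <- compute_coverage(aln0, c(chrA = 100L))
  expect_identical(tr0$depth$chrA, integer(100))
  expect_equal(tr0$genome_total, 0)

  aln1 <- tibble::tibble(read_id = "r", chrom = "chrA", start = 0L, end = 20L,
                         strand = "+", mapq = 60L)
  tr1 <- compute_coverage(aln1, c(chrA = 100L))
  expect_identical(tr1$depth$chrA, c(rep(1L, 20), rep(0L, 80)))
  expect_equal(tr1$chrom_totals[["chrA"]], 20)

  expect_error(compute_coverage(
    tibble::tibble(read_id = "r", chrom = "chrA", start = 95L, end = 105L,
                   strand = "+", mapq = 60L), c(chrA = 100L)),
    "past chromosome end")
})

test_that("pileup and MAPQ filtering equal the brute-force oracle", {
  set.seed(41)
  for (rep in 1:5) {
    L <- sample(200:500, 1)
    n <- 100
    start <- sample(0:(L - 30), n, replace = TRUE)
    aln <- tibble::tibble(read_id = sprintf("r%d", 1:n), chrom = "chrA",
                          start = start, end = start + sample(5:30, n, TRUE),
                          strand = "+", mapq = sample(c(0L, 30L, 60L), n, TRUE))
    aln$end <- pmin(aln$end, L)
    tr <- compute_coverage(aln, c(chrA = L))
    expect_identical(tr$depth$chrA, oracle_coverage(aln, L))
    trq <- compute_coverage(aln, c(chrA = L), mapq_min = 30)
    expect_identical(trq$depth$chrA, oracle_coverage(aln[aln$mapq >= 30, ], L))
    expect_equal(trq$n_excluded, sum(aln$mapq < 30))
  }
})

test_that("window sums follow the tiling definition incl. boundary splits", {
  tr <- make_track(list(chrA = rep(2L, 100)))
  wt <- window_coverage(tr, 20)
  expect_equal(wt$raw, rep(40, 5))
  expect_equal(wt$start, seq(0, 80, by = 20))

  # single read (15,25): 5 bases in window 0, 5 in window 1
  aln <- tibble::tibble(read_id = "r", chrom = "chrA", start = 15L, end = 25L,
                        strand = "+", mapq = 60L)
  wt2 <- window_coverage(compute_coverage(aln, c(chrA = 100L)), 20)
  expect_equal(wt2$raw[1:2], c(5, 5))

  expect_error(window_coverage(tr, 0), "w")
})

test_that("window sums equal the brute-force oracle on random tracks", {
  set.seed(7)
  for (rep in 1:10) {
    L <- sample(80:200, 1)
    d <- sample(0:5, L, replace = TRUE)
    tr <- make_track(list(chrX = d))
    for (w in c(7L, 20L, sample(3:40, 1))) {
      wt <- window_coverage(tr, w)
      expect_equal(wt$raw, oracle_windows(d, w))
      expect_true(all(wt$end - wt$start <= w))
      # short terminal window flagged, tiling covers [0, L) disjointly
      expect_equal(wt$start[-1], wt$end[-nrow(wt)])
      expect_equal(wt$end[nrow(wt)], L)
    }
  }
})

test_that("refinement: 20-nt windows grouped in blocks sum to 5000-nt windows", {
  set.seed(8)
  d <- sample(0:8, 20000, replace = TRUE)
  tr <- make_track(list(chrA = d))
  w20 <- window_coverage(tr, 20)
  w5000 <- window_coverage(tr, 5000)
  grouped <- rowsum(w20$raw, w20$window %/% 250)  # sorts groups numerically
  expect_equal(as.numeric(grouped), w5000$raw)
})

test_that("per-chromosome normalization is the printed fraction", {
  tr <- make_track(list(chrA = c(rep(1L, 10), rep(3L, 10), rep(6L, 10))))
  wt <- normalize_per_chromosome(window_coverage(tr, 10))
  expect_equal(wt$value, c(0.1, 0.3, 0.6))

  # uniform coverage, 5 windows -> each 0.2
  tru <- make_track(list(chrA = rep(4L, 50)))
  expect_equal(normalize_per_chromosome(window_coverage(tru, 10))$value,
               rep(0.2, 5))
})

test_that("per-chromosome values conserve to 1 and are scale invariant", {
  set.seed(9)
  depths <- list(chrA = sample(0:6, 300, TRUE), chrB = sample(0:6, 143, TRUE))
  tr <- make_track(depths, sample = "s1")
  for (w in c(10L, 33L, 100L)) {
    for (pc in c(0, 0.5)) {
      wt <- normalize_per_chromosome(window_coverage(tr, w), pseudocount = pc)
      sums <- tapply(wt$value, wt$chrom, sum)
      expect_true(all(abs(sums - 1) < 1e-9))
    }
  }
  # multiplying one sample's raw coverage by 7 leaves the fraction unchanged
  tr7 <- make_track(lapply(depths, function(d) d * 7L), sample = "s1")
  w1 <- normalize_per_chromosome(window_coverage(tr, 25))
  w7 <- normalize_per_chromosome(window_coverage(tr7, 25))
  expect_equal(w1$value, w7$value)

  # zero-coverage chromosome yields absent values, with a warning
  trz <- make_track(list(chrA = rep(2L, 40), chrZ = rep(0L, 40)))
  expect_warning(wz <- normalize_per_chromosome(window_coverage(trz, 10)),
                 "zero-coverage")
  expect_true(all(is.na(wz$value[wz$chrom == "chrZ"])))
  expect_error(normalize_per_chromosome(window_coverage(trz, 10), -1),
               "pseudocount")
})

test_that("genome-wide normalization divides by the sample's genome total", {
  # MT window raw 50 over genome total 10000 -> 0.005
  tr <- make_track(list(chr1 = rep(1L, 9950), MT = rep(50L, 1)))
  wt <- normalize_genome_wide(window_coverage(tr, 500))
  mt_val <- wt$value[wt$chrom == "MT"]
  expect_equal(mt_val, 50 / 10000)

  # doubling only non-MT coverage halves every MT normalized value
  hand <- make_track(list(chr1 = rep(2L, 1000), MT = rep(4L, 100)))
  hand2 <- make_track(list(chr1 = rep(4L, 1000), MT = rep(4L, 100)))
  v1 <- normalize_genome_wide(window_coverage(hand, 50))
  v2 <- normalize_genome_wide(window_coverage(hand2, 50))
  r <- v2$value[v2$chrom == "MT"] / v1$value[v1$chrom == "MT"]
  # denominator grows from 2400 to 4400 while MT numerator is fixed
  expect_equal(unique(round(r, 10)), round(2400 / 4400, 10))

  # all-zero MT with positive genome total -> MT windows all 0
  trz <- make_track(list(chr1 = rep(1L, 100), MT = rep(0L, 100)))
  wz <- normalize_genome_wide(window_coverage(trz, 10))
  expect_true(all(wz$value[wz$chrom == "MT"] == 0))

  empty <- make_track(list(chr1 = rep(0L, 100)))
  expect_error(normalize_genome_wide(window_coverage(empty, 10)),
               "zero genome-wide")
})

test_that("genome-wide normalization is invariant only under genome-uniform scaling", {
  depths <- list(chrA = rep(3L, 200), MT = rep(6L, 100))
  tr <- make_track(depths)
  tr_uniform <- make_track(lapply(depths, function(d) d * 5L))
  tr_partial <- make_track(list(chrA = depths$chrA * 5L, MT = depths$MT))
  v0 <- normalize_genome_wide(window_coverage(tr, 50))$value
  expect_equal(normalize_genome_wide(window_coverage(tr_uniform, 50))$value, v0)
  expect_false(isTRUE(all.equal(
    normalize_genome_wide(window_coverage(tr_partial, 50))$value, v0)))
})

test_that("gene-vs-mean rescaling follows the three-sample fraction", {
  expect_equal(gene_sample_vs_mean(c(4, 4, 4)), c(1, 1, 1))
  expect_equal(gene_sample_vs_mean(c(2, 1, 0)), c(2, 1, 0))
  expect_equal(gene_sample_vs_mean(c(6, 3, 3)), c(1.5, 0.75, 0.75))
  expect_true(all(is.na(gene_sample_vs_mean(c(0, 0, 0)))))
  expect_error(gene_sample_vs_mean(c(1, 2)), "values")
})
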