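# The 1.5-fold screen, region merging, annotation overlap and gene-list
# algebra, including the planted-signal recovery property.

three_sample_values <- function(mat) {
  colnames(mat) <- c("HL60", "dHL60", "ecTrap")
  make_norm_windows(mat)
}

test_that("identical samples yield zero calls at any cutoff above 1", {
  m <- matrix(rep(c(0.2, 0.3, 0.5), 3), ncol = 3)
  for (cutoff in c(1.1, 1.5, 3)) {
    expect_equal(nrow(fold_change_screen(three_sample_values(m),
                                         cutoff = cutoff)), 0)
  }
})

test_that("a clear 3-fold window is called under both criteria", {
  m <- matrix(c(0.3, 0.35, 0.1, 0.35, 0.1, 0.3), ncol = 3, byrow = FALSE)
  # window 1: focal ecTrap? construct explicitly: values 0.3 vs 0.1, 0.1
  m <- cbind(c(0.3, 0.25), c(0.1, 0.25), c(0.1, 0.25))
  calls <- fold_change_screen(three_sample_values(m))
  hit <- dplyr::filter(calls, sample == "HL60", window == 0)
  expect_equal(hit$direction, "enriched")
  expect_equal(hit$fold_vs_each, 3, tolerance = 1e-4)
  expect_equal(hit$fold_vs_average, 3, tolerance = 1e-4)
  expect_equal(hit$criterion, "both")
  # and the mirrored depletions for the other samples at the same window
  dep <- dplyr::filter(calls, window == 0, direction == "depleted")
  expect_setequal(dep$sample, c("dHL60", "ecTrap"))
})

test_that("raising the cutoff yields a subset of calls (monotonicity)", {
  set.seed(15)
  m <- matrix(runif(90, 0.5, 2), ncol = 3)
  m <- sweep(m, 2, colSums(m), "/")
  wt <- three_sample_values(m)
  c15 <- fold_change_screen(wt, cutoff = 1.5, ratio_pseudocount = 1e-6)
  c20 <- fold_change_screen(wt, cutoff = 2.0, ratio_pseudocount = 1e-6)
  key <- function(x) paste(x$sample, x$window, x$direction)
  expect_true(all(key(c20) %in% key(c15)))
})

test_that("calls for a focal sample ignore the labelling of the other two", {
  set.seed(16)
  m <- matrix(runif(60, 0.1, 1), ncol = 3)
  m <- sweep(m, 2, colSums(m), "/")
  wt1 <- three_sample_values(m)
  m_swapped <- m[, c(1, 3, 2)]
  wt2 <- three_sample_values(m_swapped)
  f1 <- dplyr::filter(fold_change_screen(wt1), sample == "HL60")
  f2 <- dplyr::filter(fold_change_screen(wt2), sample == "HL60")
  expect_equal(f1$window, f2$window)
  expect_equal(f1$fold_vs_each, f2$fold_vs_each)
  expect_equal(f1$direction, f2$direction)
})

test_that("screen validates sample count and criterion choices narrow calls", {
  m <- cbind(c(0.3, 0.25), c(0.1, 0.25))
  colnames(m) <- c("a", "b")
  expect_error(fold_change_screen(make_norm_windows(m)), "3 samples")

  # a window enriched vs the average but not vs each simultaneously
  m3 <- cbind(c(0.30), c(0.22), c(0.08))
  wt <- three_sample_values(m3)
  both <- fold_change_screen(wt, criterion = "either")
  sim <- fold_change_screen(wt, criterion = "simultaneous")
  avg <- fold_change_screen(wt, criterion = "vs_average")
  h <- function(x) dplyr::filter(x, sample == "HL60", direction == "enriched")
  expect_equal(nrow(h(both)), 1)
  expect_equal(unname(h(both)$criterion), "vs_average")
  expect_equal(nrow(h(sim)), 0)
  expect_equal(nrow(h(avg)), 1)
})

test_that("regions are maximal same-direction runs (run-length oracle)", {
  expect_equal(nrow(merge_regions(fold_change_screen(
    three_sample_values(matrix(rep(0.5, 6), ncol = 3))))), 0)

  set.seed(17)
  for (rep in 1:10) {
    n <- 40
    dirs <- sample(c("enriched", "depleted", NA), n, replace = TRUE,
                   prob = c(.3, .3, .4))
    keep <- !is.na(dirs)
    calls <- tibble::tibble(
      sample = "ecTrap", chrom = "chr1",
      start = (seq_len(n) - 1) * 100, end = seq_len(n) * 100,
      window = seq_len(n) - 1L,
      direction = dirs,
      fold_vs_each = ifelse(dirs == "enriched", runif(n, 1.5, 3),
                            runif(n, 0.2, 0.66)),
      fold_vs_average = 1, criterion = "both")[keep, ]
    regions <- merge_regions(calls)
    # oracle: run-length encoding over the window grid
    lab <- rep("none", n); lab[keep] <- dirs[keep]
    r <- rle(lab)
    expected <- sum(r$values != "none")
    expect_equal(nrow(regions), expected)
    expect_equal(sum(regions$n_windows), sum(keep))
  }
})

test_that("adjacent same-focal windows merge into one region", {
  calls <- tibble::tibble(sample = "ecTrap", chrom = "chr1",
                          start = c(0, 100), end = c(100, 200),
                          window = 0:1, direction = "enriched",
                          fold_vs_each = c(1.6, 2.1), fold_vs_average = 1.8,
                          criterion = "both")
  reg <- merge_regions(calls)
  expect_equal(nrow(reg), 1)
  expect_equal(reg$n_windows, 2L)
  expect_equal(reg$best_fold, 2.1)
  expect_equal(c(reg$start, reg$end), c(0, 200))
})

test_that("region-gene overlap matches brute-force base membership", {
  ann <- tibble::tibble(gene_id = c("g1", "g2"), symbol = c("G1", "G2"),
                        chrom = "chr1", start = c(100L, 400L),
                        end = c(200L, 500L), strand = "+", kind = "gene")
  inside <- tibble::tibble(sample = "s", direction = "enriched",
                           chrom = "chr1", start = 120, end = 180)
  hit <- overlap_genes(inside, ann)
  expect_equal(hit$symbol, "G1")
  expect_equal(hit$overlap_nt, 60)

  between <- dplyr::mutate(inside, start = 210, end = 390)
  expect_equal(nrow(overlap_genes(between, ann)), 0)

  straddle <- dplyr::mutate(inside, start = 150, end = 260)
  hs <- overlap_genes(straddle, ann)
  base_overlap <- sum(150:259 %in% 100:199)  # 0-based membership count
  expect_equal(hs$overlap_nt, base_overlap)

  expect_warning(overlap_genes(dplyr::mutate(inside, chrom = "chrZ"), ann),
                 "absent from annotation")
})

test_that("expression-list overlap equals brute-force set algebra", {
  ident <- expression_overlap(letters[1:10], LETTERS[1:10])
  expect_equal(unlist(ident$counts, use.names = FALSE), c(10, 0, 0))
  disj <- expression_overlap(letters[1:4], c("x1", "x2", "x3"))
  expect_equal(unlist(disj$counts, use.names = FALSE), c(0, 4, 3))
  expect_error(expression_overlap(letters, character(0)), "empty")

  set.seed(18)
  universe <- sprintf("GENE%04d", 1:1000)
  h <- sample(universe, 100); e <- sample(universe, 100)
  ov <- expression_overlap(h, e)
  expect_equal(ov$counts$n_hit_in_list, length(intersect(toupper(h), toupper(e))))
  expect_equal(ov$counts$n_hit_not_in_list, length(setdiff(toupper(h), toupper(e))))
  expect_equal(ov$counts$n_list_not_hit, length(setdiff(toupper(e), toupper(h))))
})

test_that("ROI profiles report unit fold on flat data and recover planted folds", {
  # flat windows: every gene fold is 1
  m <- matrix(0.02, nrow = 50, ncol = 3)
  colnames(m) <- c("HL60", "dHL60", "ecTrap")
  wt <- make_norm_windows(m, w = 100L, chrom = "chr1")
  ann <- tibble::tibble(gene_id = "g1", symbol = "G1", chrom = "chr1",
                        start = 500L, end = 1500L, strand = "+", kind = "gene")
  prof <- roi_profile("G1", wt, ann)
  expect_equal(unique(prof$fold_focal_vs_others), 1)
  expect_equal(prof$rel_to_mean, rep(1, 3))
  attr_unres <- attr(roi_profile(c("G1", "NOPE"), wt, ann), "unresolved")
  expect_equal(attr_unres, "NOPE")
  expect_error(roi_profile("NOPE", wt, ann), "resolved")

  # planted 2x interval covering a gene, small relative to the chromosome
  iv <- tibble::tibble(sample = "ecTrap", chrom = "chr1",
                       start = 40000L, end = 42000L, multiplier = 2)
  fx <- small_sim(seed = 61, planted = iv)
  w20 <- suppressWarnings(normalize_per_chromosome(
    window_coverage(fx$tracks, 20)))
  gene_ann <- tibble::tibble(gene_id = "roi1", symbol = "ROI1", chrom = "chr1",
                             start = 40200L, end = 41800L, strand = "+",
                             kind = "gene")
  pr <- roi_profile("ROI1", w20, gene_ann, focal = "ecTrap")
  fold <- unique(pr$fold_focal_vs_others)
  expect_gte(fold, 1.7)
  expect_lte(fold, 2.3)
})

test_that("planted multiplier-2 intervals of five windows are recovered", {
  # headline recovery property: 5-window (25 kb) intervals at w = 5000,
  # depth 10, one per sample on its own chromosome; chromosomes large
  # enough (150 kb) that a planted interval stays a modest fraction of its
  # normalization denominator
  iv <- tibble::tibble(sample = c("HL60", "dHL60", "ecTrap"),
                       chrom = c("chr1", "chr2", "chr3"),
                       start = 20000L, end = 45000L, multiplier = 2)
  res <- vapply(1:20, function(s) {
    fx <- small_sim(seed = 300 + s, chrom_kb = 150L, planted = iv)
    norm <- suppressWarnings(normalize_per_chromosome(
      window_coverage(fx$tracks, 5000)))
    calls <- fold_change_screen(norm)
    sc <- netscan:::score_screen_calls(calls, fx$sim$truth, 5000,
                                       fx$chrom_lengths,
                                       names(fx$sim$alignments))
    c(sc$sensitivity, sc$false_call_rate)
  }, numeric(2))
  expect_gte(mean(res[1, ]), 0.95)
  expect_lte(mean(res[2, ]), 0.02)
})
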