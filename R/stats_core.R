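# Self-contained implementations of the named tests used across the package
# (one-way ANOVA, Mann-Whitney U, Spearman rank correlation), so results are
# fully specified here. Library routines serve only as cross-checks in tests.

new_test_result <- function(name, statistic, p_value, group_sizes,
                            method = NULL, estimate = NULL, flag = NULL) {
  tibble(
    test = name,
    statistic = statistic,
    p_value = p_value,
    n = list(group_sizes),
    method = method %||% NA_character_,
    estimate = estimate %||% NA_real_,
    flag = flag %||% NA_character_
  )
}

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA: between/within sums of squares,
#' F statistic, p from the F distribution. Degenerate input in which both the
#' between- and within-group sums of squares are zero (all values identical)
#' is reported as F = 0, p = 1 and flagged.
#'
#' @param groups A list of numeric vectors, one per group (each of length
#'   >= 2, at least two groups).
#' @return A one-row tibble with `statistic` (F), `p_value`, group sizes in
#'   `n`, and `flag` ("degenerate" when applicable).
#' @examples
#' anova_oneway(list(c(0, 1, 2), c(10, 11, 12)))
#' @export
anova_oneway <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  groups <- lapply(groups, as.numeric)
  sizes <- lengths(groups)
  if (any(sizes < 2)) abort("each group needs >= 2 values")
  k <- length(groups)
  n <- sum(sizes)
  grand <- mean(unlist(groups))
  means <- vapply(groups, mean, 0)
  ss_between <- sum(sizes * (means - grand)^2)
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  df1 <- k - 1L
  df2 <- n - k
  if (ss_within == 0 && ss_between == 0) {
    return(new_test_result("anova_oneway", 0, 1, sizes, method = "F",
                           flag = "degenerate"))
  }
  if (ss_within == 0) {
    # perfectly separated groups: F is infinite, p -> 0
    return(new_test_result("anova_oneway", Inf, 0, sizes, method = "F"))
  }
  f <- (ss_between / df1) / (ss_within / df2)
  p <- pf(f, df1, df2, lower.tail = FALSE)
  new_test_result("anova_oneway", f, p, sizes, method = "F")
}

# Exact Mann-Whitney null: enumerate all C(n+m, n) placements of x among the
# pooled ranks and tabulate U. Used for small samples without ties.
mw_exact_p <- function(u_obs, n, m) {
  ranks <- seq_len(n + m)
  sets <- combn(n + m, n)
  u_all <- apply(sets, 2, function(ix) sum(ranks[ix]) - n * (n + 1) / 2)
  # two-sided: double the smaller tail, capped at 1
  p_le <- mean(u_all <= u_obs)
  p_ge <- mean(u_all >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

#' Mann-Whitney U test
#'
#' Rank-sum test for two independent samples. Exact p by full enumeration of
#' rank assignments when `min(n, m) <= 8` and there are no ties; otherwise a
#' normal approximation with tie correction and continuity correction. The
#' method actually used is recorded in the `method` column.
#'
#' @param x,y Numeric vectors.
#' @param two_sided Two-sided test (default) or one-sided greater-x.
#' @return One-row tibble: U statistic, p-value, group sizes, method.
#' @export
mann_whitney <- function(x, y, two_sided = TRUE) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 1 || length(y) < 1) abort("x and y must be non-empty")
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  has_ties <- anyDuplicated(pooled) > 0
  if (!has_ties && min(n, m) <= 8 && choose(n + m, n) <= 50000) {
    p <- mw_exact_p(u, n, m)
    if (!two_sided) p <- mean_tail_ge(u, n, m)
    return(new_test_result("mann_whitney", u, p, c(n, m), method = "exact"))
  }
  mu <- n * m / 2
  ties <- table(pooled)
  tie_corr <- sum(ties^3 - ties) / ((n + m) * (n + m - 1))
  sigma2 <- n * m / 12 * ((n + m + 1) - tie_corr)
  z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
  p <- if (two_sided) 2 * pnorm(abs(z), lower.tail = FALSE) else
    pnorm(z, lower.tail = FALSE)
  p <- min(1, p)
  new_test_result("mann_whitney", u, p, c(n, m), method = "normal_approx")
}

mean_tail_ge <- function(u_obs, n, m) {
  ranks <- seq_len(n + m)
  sets <- combn(n + m, n)
  u_all <- apply(sets, 2, function(ix) sum(ranks[ix]) - n * (n + 1) / 2)
  mean(u_all >= u_obs)
}

#' Spearman rank correlation
#'
#' Rho computed on mid-ranks. For n <= 7 with no ties the p-value is exact,
#' by enumerating all n! orderings of one vector; otherwise the usual
#' t-distribution approximation on `rho * sqrt((n-2)/(1-rho^2))`.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return One-row tibble with `estimate` (rho), `statistic`, `p_value`.
#' @export
spearman <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y) || length(x) < 3) {
    abort("x and y must have equal length >= 3")
  }
  n <- length(x)
  if (sd(x) == 0 || sd(y) == 0) {
    return(new_test_result("spearman", NA_real_, NA_real_, n,
                           method = "undefined", flag = "constant input"))
  }
  rx <- rank(x); ry <- rank(y)
  rho <- suppressWarnings(stats::cor(rx, ry))
  has_ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  if (n <= 7 && !has_ties) {
    perms <- perms_all(n)
    rhos <- apply(perms, 1, function(p) stats::cor(rx, ry[p]))
    p_val <- mean(abs(rhos) >= abs(rho) - 1e-12)
    return(new_test_result("spearman", rho, p_val, n, method = "exact",
                           estimate = rho))
  }
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  p_val <- 2 * pt(abs(tstat), n - 2, lower.tail = FALSE)
  new_test_result("spearman", tstat, p_val, n, method = "t_approx",
                  estimate = rho)
}

# All permutations of 1..n as rows (n <= 8 in practice).
perms_all <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- perms_all(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    for (j in seq_len(nrow(sub))) {
      out[row, ] <- c(i, rest[sub[j, ]])
      row <- row + 1L
    }
  }
  out
}
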