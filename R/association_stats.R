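# The small statistics toolbox the cohort comparisons rely on, implemented
# once with explicit contracts: continuity-corrected Mann-Whitney U test
# (normal approximation with tie correction; exact enumeration for small
# samples), two-sided Fisher's exact 2x2 test by hypergeometric enumeration,
# Spearman correlation with average ranks, Wherry-adjusted r-squared, and
# Bonferroni / Benjamini-Hochberg p-value adjustment.

.test_result <- function(statistic, p, method, n, p_adjusted = NA_real_) {
  structure(list(statistic = statistic, p = p, p_adjusted = p_adjusted,
                 method = method, n = n), class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.6g, p = %.6g (n = %s)\n",
              x$method, x$statistic, x$p, paste(x$n, collapse = "+")))
  invisible(x)
}

#' Two-sided Mann-Whitney U test with continuity correction
#'
#' Rank-sum test of two independent samples. The default is the normal
#' approximation with tie correction and a 0.5 continuity correction (the
#' large-cohort setting the package's comparisons use). With `exact = TRUE`
#' (small samples only) the null distribution of U is enumerated over all
#' group assignments and the two-sided p-value is
#' `P(|U - mu_U| >= |u_obs - mu_U|)`.
#'
#' @param x,y Numeric vectors (each non-empty).
#' @param exact Use exact enumeration (requires `length(x) + length(y)` at
#'   most 14).
#' @return A `test_result` with `statistic` = U for `x` and the two-sided p.
#'   Swapping `x` and `y` leaves the p-value unchanged.
#' @export
mann_whitney_cc <- function(x, y, exact = FALSE) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0L || length(y) == 0L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (exact) {
    if (N > 14L) stop("exact mode supported only for n1 + n2 <= 14",
                      call. = FALSE)
    combos <- utils::combn(N, n1)
    us <- apply(combos, 2L, function(idx) {
      sum(r[idx]) - n1 * (n1 + 1) / 2
    })
    p <- mean(abs(us - mu) >= abs(u - mu) - 1e-9)
    return(.test_result(u, p, "Mann-Whitney U (exact)", c(n1, n2)))
  }
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
  if (sigma2 <= 0) {
    # all observations tied: no evidence either way
    return(.test_result(u, 1, "Mann-Whitney U (normal approx., cc)",
                        c(n1, n2)))
  }
  z <- (abs(u - mu) - 0.5) / sqrt(sigma2)
  z <- max(z, 0)
  p <- min(1, 2 * stats::pnorm(-z))
  .test_result(u, p, "Mann-Whitney U (normal approx., cc)", c(n1, n2))
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact p-value by hypergeometric enumeration with the two-sided
#' probability method: the p-value sums the probabilities of all tables
#' (with the observed margins) whose probability does not exceed that of the
#' observed table (up to a small relative tolerance).
#'
#' @param table A 2x2 matrix (or coercible) of non-negative integer counts.
#' @return A `test_result` with `statistic` = sample odds ratio and the
#'   two-sided exact p.
#' @export
fisher_exact_2x2 <- function(table) {
  m <- matrix(as.numeric(table), nrow = 2L)
  if (any(is.na(m)) || any(m < 0) || any(m != round(m))) {
    stop("table must be 2x2 with non-negative integer counts", call. = FALSE)
  }
  a <- m[1L, 1L]
  r1 <- sum(m[1L, ]); r2 <- sum(m[2L, ])
  c1 <- sum(m[, 1L]); c2 <- sum(m[, 2L])
  n <- r1 + r2
  if (min(r1, r2, c1, c2) == 0) {
    # a zero margin admits only the observed table
    or <- (m[1, 1] * m[2, 2]) / (m[1, 2] * m[2, 1])
    return(.test_result(or, 1, "Fisher exact (two-sided)", n))
  }
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(support, r1, r2, c1)
  p_obs <- stats::dhyper(a, r1, r2, c1)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  p <- min(1, p)
  or <- (m[1, 1] * m[2, 2]) / (m[1, 2] * m[2, 1])
  .test_result(or, p, "Fisher exact (two-sided)", n)
}

#' Spearman rank correlation
#'
#' Spearman's rho computed as the Pearson correlation of average ranks, with
#' a two-sided p-value from the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))`.
#'
#' @param x,y Numeric vectors of equal length >= 3; neither may be constant.
#' @return A `test_result` with `statistic` = rho.
#' @export
spearman <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for a constant vector", call. = FALSE)
  }
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  .test_result(rho, p, "Spearman rank correlation (t approx.)", n)
}

#' Squared Pearson correlation
#' @param x,y Numeric vectors of equal length >= 3; neither constant.
#' @return r-squared in [0, 1].
#' @export
pearson_r2 <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for a constant vector", call. = FALSE)
  }
  stats::cor(x, y)^2
}

#' Wherry-adjusted r-squared
#'
#' The Wherry shrinkage adjustment
#' `1 - (1 - r2) * (n - 1) / (n - k - 1)` for a linear model with `k`
#' predictors fitted on `n` observations. (The literature carries several
#' variants; this formula is the one this package pins down.)
#'
#' @param r2 Unadjusted r-squared in [0, 1].
#' @param n Number of observations; must exceed `k + 1`.
#' @param k Number of predictors.
#' @return Adjusted r-squared (can be negative).
#' @export
adjusted_r2 <- function(r2, n, k) {
  stopifnot(r2 >= 0, r2 <= 1)
  if (n <= k + 1) stop("need n > k + 1", call. = FALSE)
  1 - (1 - r2) * (n - 1) / (n - k - 1)
}

#' Adjust p-values for multiple testing
#'
#' Bonferroni (`min(1, m * p)`) or Benjamini-Hochberg step-up with
#' monotonicity enforcement; adjusted values are mapped back to the input
#' order.
#'
#' @param ps Numeric vector of p-values in [0, 1].
#' @param method `"bonferroni"` or `"bh"`.
#' @return Numeric vector of adjusted p-values, aligned with `ps`.
#' @export
p_adjust <- function(ps, method = c("bonferroni", "bh")) {
  method <- match.arg(method)
  if (any(is.na(ps)) || any(ps < 0) || any(ps > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  m <- length(ps)
  if (m == 0L) return(numeric(0))
  if (method == "bonferroni") return(pmin(1, m * ps))
  ord <- order(ps, decreasing = TRUE)  # step-up from the largest p
  adj <- numeric(m)
  running_min <- 1
  for (idx in seq_along(ord)) {
    i <- ord[idx]
    rank_i <- m - idx + 1L
    running_min <- min(running_min, m / rank_i * ps[i])
    adj[i] <- running_min
  }
  adj
}
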