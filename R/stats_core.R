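# Classical test battery used in the validation analysis.  Conventions are
# fixed to match how screening studies in this field print their numbers:
# Mann-Whitney reports min(U1, U2); chi-squared applies the Yates continuity
# correction by default; Spearman's p uses the t-approximation.

# dot-prefixed formals so that metadata passed through ... (n, method,
# u1, ...) can never partially match a positional parameter
new_test_result <- function(.statistic_name, .statistic, .p_value, ...) {
  structure(c(list(statistic_name = .statistic_name,
                   statistic = unname(.statistic),
                   p_value = unname(.p_value)),
              list(...)),
            class = "cog_test_result")
}

#' @export
print.cog_test_result <- function(x, ...) {
  cat(sprintf("%s = %.4g, p = %.4g\n", x$statistic_name, x$statistic,
              x$p_value))
  invisible(x)
}

#' Spearman rank correlation
#'
#' Rho is the Pearson correlation of mid-ranks.  The two-sided p-value uses
#' the t-approximation with n - 2 degrees of freedom, the convention of the
#' analysis stacks this validation literature uses; for very small samples
#' (`n <= exact_n`, no ties) an exact permutation p over all n! orderings is
#' computed instead.
#'
#' @param x,y Numeric vectors of equal length (n >= 3).
#' @param exact_n Use the exact permutation distribution when `n` is at most
#'   this and there are no ties (default 0: never).
#' @return A `cog_test_result` with `statistic_name = "rho"`.
#' @export
spearman_rho <- function(x, y, exact_n = 0L) {
  stopifnot(length(x) == length(y))
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: constant vector")
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  ties <- anyDuplicated(x) > 0L || anyDuplicated(y) > 0L
  if (n <= exact_n && !ties) {
    perms <- permutations_of(n)
    rho_null <- apply(perms, 1L, function(p) stats::cor(rx, ry[p]))
    p <- mean(abs(rho_null) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- if (abs(rho) >= 1) 0 else 2 * stats::pt(-abs(tstat), df = n - 2)
    method <- "t-approximation"
  }
  new_test_result("rho", rho, p, n = n, method = method, sided = "two")
}

permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- permutations_of(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

#' Mann-Whitney U test
#'
#' Computes both U statistics (mid-rank ties, so U1 + U2 = n1 * n2 holds
#' exactly) and reports the smaller, the convention under which this
#' field's printed U values are below n1 * n2 / 2.  The two-sided p-value
#' uses the normal approximation with tie correction and 0.5 continuity
#' correction.
#'
#' @param x,y Numeric vectors (both nonempty).
#' @return A `cog_test_result` with fields `u1`, `u2`; `statistic` is
#'   `min(u1, u2)`.
#' @export
mann_whitney_u <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) stop("both samples must be nonempty")
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = FALSE, correct = TRUE))
  u1 <- unname(wt$statistic)               # wilcoxon W for x == U for x
  u2 <- length(x) * length(y) - u1
  new_test_result("U", min(u1, u2), wt$p.value, u1 = u1, u2 = u2,
                  n1 = length(x), n2 = length(y),
                  method = "normal approximation, tie + continuity corrected",
                  sided = "two")
}

check_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("need a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab)))
    stop("cells must be non-negative integers")
  tab
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p by the probability-mass rule: the sum of hypergeometric
#' probabilities of tables no more probable than the observed one (with a
#' small relative tolerance on the comparison).
#'
#' @param tab 2x2 matrix of counts.
#' @return A `cog_test_result`; `statistic` is the conditional odds ratio
#'   estimate.
#' @export
fisher_2x2 <- function(tab) {
  tab <- check_2x2(tab)
  ft <- stats::fisher.test(tab)
  new_test_result("odds ratio", unname(ft$estimate), ft$p.value,
                  method = "probability-mass two-sided", sided = "two")
}

#' Chi-squared test for a 2x2 table
#'
#' Applies the Yates continuity correction by default,
#' chi2 = N (|ad - bc| - N/2)^2 / (r1 r2 c1 c2), with 1 degree of freedom.
#'
#' @param tab 2x2 matrix of counts; no margin may be zero.
#' @param yates Apply the continuity correction (default `TRUE`).
#' @return A `cog_test_result` with `statistic_name = "chi-squared"`.
#' @export
chi2_2x2 <- function(tab, yates = TRUE) {
  tab <- check_2x2(tab)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("undefined test: zero margin")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = yates))
  new_test_result("chi-squared", ct$statistic, ct$p.value, df = 1L,
                  yates = yates, sided = "two")
}

#' Two-sample t-test
#'
#' Student's pooled-variance test by default; set `var_equal = FALSE` for
#' Welch.
#'
#' @param x,y Numeric vectors with at least 2 values each.
#' @param var_equal Pool the variances (default `TRUE`).
#' @return A `cog_test_result` with `statistic_name = "t"`.
#' @export
two_sample_t <- function(x, y, var_equal = TRUE) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L) stop("need n >= 2 per sample")
  if (stats::var(c(x - mean(x), y - mean(y))) == 0)
    stop("degenerate: zero pooled variance")
  tt <- stats::t.test(x, y, var.equal = var_equal)
  new_test_result("t", tt$statistic, tt$p.value, df = unname(tt$parameter),
                  pooled = var_equal, sided = "two")
}

#' Shapiro-Wilk normality test
#'
#' Used in the pipeline as an advisory gate (alpha 0.05) for parametric vs
#' non-parametric group comparisons.
#'
#' @param x Numeric vector, 3 <= n <= 5000.
#' @return A `cog_test_result` with `statistic_name = "W"`.
#' @export
shapiro_wilk <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 3L || length(x) > 5000L) stop("need 3 <= n <= 5000")
  if (stats::sd(x) == 0) stop("degenerate: constant vector")
  st <- stats::shapiro.test(x)
  new_test_result("W", st$statistic, st$p.value, n = length(x))
}

#' Proportional difference in median scores
#'
#' `|median_a - median_b| / (observed_max - observed_min)`: the group
#' median gap as a fraction of the observed score range, used to put score
#' differences on instruments with different scales on a common footing.
#'
#' @param median_a,median_b Group medians.
#' @param observed_max,observed_min Observed score range (max > min).
#' @return The fraction in `[0, 1]` (not a percentage).
#' @export
proportional_median_difference <- function(median_a, median_b,
                                           observed_max, observed_min) {
  if (observed_max <= observed_min)
    stop("undefined: observed range must be positive")
  abs(median_a - median_b) / (observed_max - observed_min)
}
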