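#' Incidence of a current type
#'
#' The number of cells detected with a current divided by the total number of
#' cells studied for that current type, reported as an integer percentage
#' rounded half away from zero (this rounding reproduces every printed
#' incidence pair: 47/59 -> 80, 9/41 -> 22, 6/41 -> 15, 9/64 -> 14,
#' 11/14 -> 79).
#'
#' @param detected Number of cells with the current (0 <= detected <= total).
#' @param total Total number of cells studied (>= 1).
#' @return An object of class `incidence_record`: `detected`, `total`,
#'   `percent`.
#' @examples
#' incidence(47, 59)$percent  # 80
#' @export
incidence <- function(detected, total) {
  if (!is.numeric(total) || total < 1) stop("`total` must be >= 1")
  if (!is.numeric(detected) || detected < 0) stop("`detected` must be >= 0")
  if (detected > total) stop("`detected` cannot exceed `total`")
  pct <- as.integer(floor(100 * detected / total + 0.5))
  structure(list(detected = as.integer(detected), total = as.integer(total),
                 percent = pct),
            class = "incidence_record")
}

#' @export
print.incidence_record <- function(x, ...) {
  cat(sprintf("%d of %d cells (%d%%)\n", x$detected, x$total, x$percent))
  invisible(x)
}

#' Mean and standard error of the mean
#'
#' SEM = sample SD (n - 1 denominator) / sqrt(n). For a single value the SEM
#' is reported as 0 with a warning.
#'
#' @param values Numeric vector of measurements (non-empty).
#' @return Named list `mean`, `sem`, `n`.
#' @export
mean_sem <- function(values) {
  if (length(values) == 0) stop("empty sample")
  if (any(!is.finite(values))) stop("values must be finite")
  n <- length(values)
  if (n == 1) {
    warning("single measurement: SEM reported as 0")
    return(list(mean = values, sem = 0, n = 1L))
  }
  list(mean = mean(values), sem = stats::sd(values) / sqrt(n), n = n)
}

# Exact permutation distribution of the U statistic for pooled midranks r
# with n_a labels in group a: enumerate all C(n, n_a) assignments.
.u_exact_dist <- function(r, n_a) {
  idx <- utils::combn(length(r), n_a)
  colSums(matrix(r[idx], nrow = n_a)) - n_a * (n_a + 1) / 2
}

#' Mann-Whitney U test
#'
#' Rank-sum test of two independent samples. U is computed from the rank sum
#' of the first sample with midrank ties,
#' \eqn{U = R_a - n_a(n_a+1)/2}. For small samples (all label assignments
#' enumerable, up to C(16,8) = 12870 combinations by default) the two-sided
#' p-value is exact: the permutation probability of a U at least as far from
#' its null mean \eqn{n_a n_b/2} as observed. Larger samples use the normal
#' approximation with tie correction and continuity correction. When every
#' pooled value is identical the p-value is exactly 1.
#'
#' @param a,b Numeric samples (non-empty).
#' @param alternative Only `"two_sided"` is implemented (the comparison
#'   reported with the recordings).
#' @param alpha Significance level for the `significant` flag (default .05).
#' @param group_a,group_b Labels carried into the result.
#' @param exact Force (`TRUE`) or forbid (`FALSE`) exact enumeration;
#'   `NULL` decides by enumeration size.
#' @return An object of class `comparison_result`: `u_statistic`, `p_value`,
#'   `n_a`, `n_b`, `significant`, `method`, group labels.
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))  # U = 0, exact p = 1/3
#' @export
mann_whitney_u <- function(a, b, alternative = "two_sided", alpha = 0.05,
                           group_a = "a", group_b = "b", exact = NULL) {
  if (!identical(alternative, "two_sided"))
    stop("only the two-sided alternative is implemented")
  if (length(a) == 0 || length(b) == 0) stop("both samples must be non-empty")
  n_a <- length(a); n_b <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)   # midranks
  u <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  mu <- n_a * n_b / 2
  n <- n_a + n_b
  if (is.null(exact)) exact <- choose(n, n_a) <= 20000
  if (exact) {
    dist <- .u_exact_dist(r, n_a)
    p <- mean(abs(dist - mu) >= abs(u - mu) - 1e-9)
    method <- "exact permutation"
  } else {
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n_a * n_b / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (abs(u - mu) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-max(z, 0)))
    }
    method <- "normal approximation"
  }
  structure(
    list(group_a = group_a, group_b = group_b, n_a = n_a, n_b = n_b,
         u_statistic = u, p_value = p, significant = p < alpha,
         alpha = alpha, method = method),
    class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf(
    "<comparison_result> %s (n=%d) vs %s (n=%d): U = %g, p = %.4g (%s)%s\n",
    x$group_a, x$n_a, x$group_b, x$n_b, x$u_statistic, x$p_value, x$method,
    if (x$significant) " *" else ""))
  invisible(x)
}
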