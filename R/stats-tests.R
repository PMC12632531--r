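#' Exact two-tailed binomial test
#'
#' Exact two-tailed p-value for observing `k` successes in `n` trials under
#' a reference success probability `p0`. The default is the small-p-values
#' convention: the p-value sums `P(X = i)` over all outcomes `i` whose
#' point probability does not exceed `P(X = k)` (with a small relative
#' tolerance for floating-point ties). The doubling convention
#' (`2 * min(P(X <= k), P(X >= k))`, capped at 1) is available via
#' `method = "doubling"`.
#'
#' @param k number of successes (0..n).
#' @param n number of trials.
#' @param p0 reference proportion, strictly between 0 and 1.
#' @param method `"small_p"` (default) or `"doubling"`.
#' @return a single p-value in `[0, 1]`.
#' @examples
#' binomial_two_tailed(5, 5, 0.5)  # 0.0625
#' @export
binomial_two_tailed <- function(k, n, p0, method = c("small_p", "doubling")) {
  method <- match.arg(method)
  stopifnot(length(k) == 1, length(n) == 1, length(p0) == 1)
  if (!is.finite(p0) || p0 <= 0 || p0 >= 1) stop("`p0` must be in (0, 1)", call. = FALSE)
  if (k < 0 || k > n || n < 1 || k != round(k) || n != round(n))
    stop("need integer 0 <= k <= n", call. = FALSE)
  if (method == "doubling") {
    p <- 2 * min(pbinom(k, n, p0), 1 - pbinom(k - 1, n, p0))
    return(min(1, p))
  }
  pk <- dbinom(k, n, p0)
  probs <- dbinom(0:n, n, p0)
  min(1, sum(probs[probs <= pk * (1 + 1e-7)]))
}

#' Correlation coefficients with significance tests
#'
#' Product-moment (Pearson) and rank (Spearman) correlation with two-sided
#' p-values from the t transform on `n - 2` degrees of freedom. Spearman
#' uses average ranks for ties.
#'
#' @param x,y numeric vectors of equal length, n >= 3, finite, each with
#'   nonzero variance.
#' @return a tibble with columns `estimate`, `statistic`, `p.value`, `n`,
#'   `method`.
#' @examples
#' pearson_test(1:10, (1:10)^2)
#' @export
pearson_test <- function(x, y) {
  ok_pairs(x, y)
  r <- cor_pm(x, y)
  cor_result(r, length(x), "pearson")
}

#' @rdname pearson_test
#' @export
spearman_test <- function(x, y) {
  ok_pairs(x, y)
  r <- cor_pm(rank(x), rank(y))
  cor_result(r, length(x), "spearman")
}

ok_pairs <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have the same length", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 pairs", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("inputs must be finite", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance in `x` or `y`", call. = FALSE)
  invisible(TRUE)
}

cor_pm <- function(x, y) {
  xc <- x - mean(x); yc <- y - mean(y)
  sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
}

cor_result <- function(r, n, method) {
  r <- max(-1, min(1, r))
  tstat <- if (abs(r) == 1) Inf * sign(r) else r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  tibble::tibble(estimate = r, statistic = tstat, p.value = p, n = n, method = method)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D` is the supremum distance between the two empirical CDFs. The p-value
#' is exact (lattice-path counting over all interleavings) when the smaller
#' sample has at most `exact_max` observations and there are no cross-sample
#' ties; otherwise the asymptotic Kolmogorov series with a finite-sample
#' continuity correction is used.
#'
#' @param a,b numeric samples, both nonempty.
#' @param exact_max largest size of the smaller sample for which the exact
#'   enumeration is used.
#' @return a tibble with `statistic` (D), `p.value`, `n_a`, `n_b`, `exact`.
#' @examples
#' ks_two_sample(rnorm(20), rnorm(20, 2))
#' @export
ks_two_sample <- function(a, b, exact_max = 10) {
  a <- as.numeric(a); b <- as.numeric(b)
  stopifnot(length(a) >= 1, length(b) >= 1, all(is.finite(a)), all(is.finite(b)))
  n1 <- length(a); n2 <- length(b)
  pooled <- sort(unique(c(a, b)))
  d <- max(abs(ecdf_at(a, pooled) - ecdf_at(b, pooled)))
  ties <- anyDuplicated(c(unique(a), unique(b))) > 0
  exact <- min(n1, n2) <= exact_max && !ties
  p <- if (exact) ks_exact_p(n1, n2, d) else ks_asymp_p(n1, n2, d)
  tibble::tibble(statistic = d, p.value = p, n_a = n1, n_b = n2, exact = exact)
}

ecdf_at <- function(x, q) {
  vapply(q, function(v) mean(x <= v), numeric(1))
}

# exact P(D >= d): count monotone lattice paths (i, j) -> (n1, n2) that keep
# |i/n1 - j/n2| < d throughout; complement over all C(n1+n2, n1) orderings
ks_exact_p <- function(n1, n2, d) {
  tol <- 1e-9
  cnt <- matrix(0, n1 + 1, n2 + 1)
  cnt[1, 1] <- 1
  for (i in 0:n1) {
    for (j in 0:n2) {
      if (i == 0 && j == 0) next
      if (abs(i / n1 - j / n2) >= d - tol) { cnt[i + 1, j + 1] <- 0; next }
      acc <- 0
      if (i > 0) acc <- acc + cnt[i, j + 1]
      if (j > 0) acc <- acc + cnt[i + 1, j]
      cnt[i + 1, j + 1] <- acc
    }
  }
  inside <- cnt[n1 + 1, n2 + 1]
  total <- choose(n1 + n2, n1)
  max(0, min(1, 1 - inside / total))
}

ks_asymp_p <- function(n1, n2, d) {
  en <- sqrt(n1 * n2 / (n1 + n2))
  lambda <- (en + 0.12 + 0.11 / en) * d
  if (lambda < 1e-3) return(1)
  j <- 1:100
  p <- 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * lambda^2))
  max(0, min(1, p))
}
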