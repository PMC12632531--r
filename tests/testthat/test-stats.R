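test_that("exact binomial two-tailed p-values", {
  expect_equal(binomial_two_tailed(5, 5, 0.5), 0.0625)
  expect_equal(binomial_two_tailed(0, 1, 0.5), 1)
  # at the distribution mode the small-p p-value is 1
  expect_equal(binomial_two_tailed(10, 20, 0.5), 1)
  # enumeration oracle
  expect_equal(binomial_two_tailed(2, 26, 0.27), oracle_binom(2, 26, 0.27),
               tolerance = 1e-12)
  # agreement with the reference implementation across a fuzz grid
  set.seed(3)
  for (rep in 1:25) {
    n <- sample(2:40, 1); k <- sample(0:n, 1); p0 <- runif(1, 0.05, 0.95)
    expect_equal(binomial_two_tailed(k, n, p0),
                 stats::binom.test(k, n, p0)$p.value, tolerance = 1e-9,
                 info = sprintf("k=%d n=%d p0=%.3f", k, n, p0))
  }
  expect_error(binomial_two_tailed(2, 5, 1.2), "p0")
  # doubling variant is bounded by twice the one-sided tail
  expect_lte(binomial_two_tailed(5, 5, 0.5, method = "doubling"), 0.0625 + 1e-12)
})

test_that("correlation estimates and p-values", {
  x <- 1:10
  expect_equal(pearson_test(x, 2 * x + 1)$estimate, 1)
  expect_equal(spearman_test(x, exp(-x))$estimate, -1)
  set.seed(9)
  for (rep in 1:20) {
    n <- sample(4:10, 1)
    a <- rnorm(n); b <- rnorm(n)
    r_direct <- sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    res <- pearson_test(a, b)
    expect_equal(res$estimate, r_direct, tolerance = 1e-12)
    ref <- stats::cor.test(a, b)
    expect_equal(res$p.value, ref$p.value, tolerance = 1e-9)
    refs <- stats::cor.test(a, b, method = "spearman", exact = FALSE)
    expect_equal(spearman_test(a, b)$estimate, unname(refs$estimate),
                 tolerance = 1e-12)
  }
  expect_error(pearson_test(1:5, rep(2, 5)), "variance")
})

test_that("Deming regression closed form", {
  x <- 1:10
  f <- deming_fit(x, 2 * x + 1)
  expect_equal(f$slope, 2, tolerance = 1e-9)
  expect_equal(f$intercept, 1, tolerance = 1e-9)
  # exchanging axes inverts the slope at lambda = 1
  set.seed(11)
  a <- rnorm(20); b <- 1.7 * a + rnorm(20, 0, 0.4)
  f1 <- deming_fit(a, b); f2 <- deming_fit(b, a)
  expect_equal(f1$slope, 1 / f2$slope, tolerance = 1e-9)
  # matches the numeric minimiser of the orthogonal criterion
  o <- oracle_deming(a, b)
  expect_equal(f1$slope, o$slope, tolerance = 1e-6)
  expect_equal(f1$intercept, o$intercept, tolerance = 1e-6)
  expect_lte(f1$residual_ss, o$value + 1e-8)
  # lambda -> Inf approaches OLS of y on x
  ols <- unname(stats::coef(stats::lm(b ~ a)))
  fbig <- deming_fit(a, b, lambda = 1e8)
  expect_equal(fbig$slope, ols[2], tolerance = 1e-4)
  expect_equal(tidy(f1)$term, c("(Intercept)", "slope"))
  expect_error(deming_fit(rep(1, 5), rep(2, 5)), "degenerate")
})

test_that("two-sample KS statistic and p-value", {
  expect_equal(ks_two_sample(1:5, 1:5)$statistic, 0)
  expect_equal(ks_two_sample(1:5, 11:15)$statistic, 1)
  set.seed(21)
  for (rep in 1:15) {
    a <- rnorm(sample(3:9, 1)); b <- rnorm(sample(3:9, 1), 0.5)
    res <- ks_two_sample(a, b)
    expect_equal(res$statistic, oracle_ks_D(a, b), tolerance = 1e-12)
    ref <- suppressWarnings(stats::ks.test(a, b))
    expect_equal(res$p.value, ref$p.value, tolerance = 1e-9)
  }
  # asymptotic branch agrees with the reference implementation closely
  set.seed(22)
  a <- rnorm(60); b <- rnorm(80, 0.3)
  res <- ks_two_sample(a, b)
  expect_false(res$exact)
  ref <- suppressWarnings(stats::ks.test(a, b))
  expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(res$p.value, ref$p.value, tolerance = 0.02)
})

test_that("binomial test type-I error stays near nominal under the null", {
  set.seed(77)
  n <- 26; p0 <- 0.27
  ks <- rbinom(3000, n, p0)
  pv <- vapply(unique(ks), function(k) binomial_two_tailed(k, n, p0), numeric(1))
  rej <- sum(table(factor(ks, levels = unique(ks))) * (pv < 0.05)) / length(ks)
  expect_lte(rej, 0.05 + 0.02)
})
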