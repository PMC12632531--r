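# Independent brute-force oracles used to validate the package's
# statistical and signal primitives.

# exhaustive scan for the spike threshold: second derivative everywhere,
# SD over the pre-window, first exceedance after the stimulus
oracle_threshold <- function(vm, fs, stim_index, peak_index, pre_window,
                             k = 5) {
  dt <- 1 / fs
  n <- length(vm)
  d2 <- rep(NA_real_, n)
  for (i in 2:(n - 1)) d2[i] <- (vm[i + 1] - 2 * vm[i] + vm[i - 1]) / dt^2
  sigma <- stats::sd(d2[pre_window[pre_window >= 2 & pre_window <= n - 1]])
  for (i in (stim_index + 1L):peak_index) {
    if (!is.na(d2[i]) && d2[i] > k * sigma) return(list(vm = vm[i], index = i))
  }
  list(vm = NA_real_, index = NA_integer_)
}

# exact two-tailed binomial by literal enumeration of all n + 1 outcomes
oracle_binom <- function(k, n, p0) {
  pk <- dbinom(k, n, p0)
  total <- 0
  for (i in 0:n) {
    pi <- dbinom(i, n, p0)
    if (pi <= pk * (1 + 1e-7)) total <- total + pi
  }
  min(1, total)
}

# two-sample KS D by evaluating both ECDFs at every pooled point
oracle_ks_D <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  dmax <- 0
  for (p in pts) {
    d <- abs(mean(a <= p) - mean(b <= p))
    if (d > dmax) dmax <- d
  }
  dmax
}

# Deming fit by direct numeric minimisation of the weighted orthogonal
# residual sum of squares
oracle_deming <- function(x, y, lambda = 1) {
  obj <- function(par) sum((y - par[1] - par[2] * x)^2) / (lambda + par[2]^2)
  ols <- stats::coef(stats::lm(y ~ x))
  fit <- stats::optim(c(ols[[1]], ols[[2]]), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  fit2 <- stats::optim(fit$par, obj, method = "BFGS",
                       control = list(reltol = 1e-14, maxit = 5000))
  list(intercept = fit2$par[1], slope = fit2$par[2], value = fit2$value)
}

# exact optimal 2-cluster 1-D k-means by brute force over contiguous
# splits of the sorted data
oracle_kmeans2 <- function(x) {
  xs <- sort(x)
  n <- length(xs)
  best <- Inf; bj <- 1
  for (j in 1:(n - 1)) {
    c1 <- xs[1:j]; c2 <- xs[(j + 1):n]
    cost <- sum((c1 - mean(c1))^2) + sum((c2 - mean(c2))^2)
    if (cost < best) { best <- cost; bj <- j }
  }
  list(split = bj, cost = best,
       means = c(mean(xs[1:bj]), mean(xs[(bj + 1):n])))
}
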