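#' Hartigan's dip statistic
#'
#' The dip of a sample is the smallest sup-norm distance between its
#' empirical CDF and any unimodal CDF (one that rises convexly to a mode,
#' possibly carries an atom there, and falls off concavely). Large values
#' indicate departure from unimodality; the statistic is the basis of the
#' dip test used to establish that extracellular spike-waveform durations
#' are bimodal before splitting units into putative interneurons and
#' principal cells.
#'
#' The statistic is computed exactly (to numerical precision) by bisection
#' on the band half-width: a distance `d` is attainable iff a unimodal CDF
#' fits inside the `d`-band around the ECDF, which reduces to convex /
#' concave envelope checks over every candidate mode position.
#'
#' @param x numeric vector, at least 4 finite values.
#' @return the dip statistic, a single number in `[0, 0.25]`. For a sample
#'   of `n` distinct values it is at least `1/(2n)`.
#' @examples
#' dip_statistic(c(rep(0, 50), rep(1, 50))) # 0.25, the maximal dip
#' @seealso [dip_test()]
#' @export
dip_statistic <- function(x) {
  x <- as.numeric(x)
  if (anyNA(x) || any(!is.finite(x))) stop("`x` must be finite", call. = FALSE)
  if (length(x) < 4) stop("dip statistic needs at least 4 observations", call. = FALSE)
  .dip_stat_cpp(x)
}

#' Dip test of unimodality
#'
#' Tests the null hypothesis that the sample comes from a unimodal
#' distribution, using [dip_statistic()] with a bootstrap null of uniform
#' samples of the same size (the least-favourable unimodal null
#' recommended for the test).
#'
#' @param x numeric sample (n >= 4).
#' @param n_boot number of uniform bootstrap samples for the null.
#' @param null_dips optional pre-computed vector of null dip statistics for
#'   samples of the same size, e.g. from [dip_null()]; when supplied the
#'   bootstrap is skipped. The null distribution depends only on `n`, so it
#'   can be shared across many tests.
#' @return an object of class `"dip_test"`: a list with `statistic`,
#'   `p_value`, `n`, `n_boot`.
#' @examples
#' set.seed(1)
#' dip_test(c(rnorm(100, 0), rnorm(100, 4)), n_boot = 200)
#' @export
dip_test <- function(x, n_boot = 2000, null_dips = NULL) {
  stat <- dip_statistic(x)
  if (is.null(null_dips)) null_dips <- dip_null(length(x), n_boot)
  p <- (sum(null_dips >= stat) + 1) / (length(null_dips) + 1)
  structure(
    list(statistic = stat, p_value = p, n = length(x), n_boot = length(null_dips)),
    class = "dip_test"
  )
}

#' Null distribution of the dip statistic
#'
#' Dip statistics of `n_boot` uniform(0,1) samples of size `n`, computed
#' with R's current RNG stream (so `set.seed()` makes it reproducible).
#'
#' @param n sample size.
#' @param n_boot number of bootstrap replicates.
#' @return numeric vector of length `n_boot`.
#' @export
dip_null <- function(n, n_boot = 2000) {
  stopifnot(n >= 4, n_boot >= 1)
  .dip_null_cpp(as.integer(n), as.integer(n_boot))
}

#' @export
print.dip_test <- function(x, ...) {
  cat("Hartigan dip test of unimodality\n")
  cat(sprintf("  dip = %.5f, n = %d, bootstrap p = %.4g (%d uniform replicates)\n",
              x$statistic, x$n, x$p_value, x$n_boot))
  invisible(x)
}

#' @rdname dip_test
#' @param ... unused.
#' @export
tidy.dip_test <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p.value = x$p_value,
                 n = x$n, n.boot = x$n_boot,
                 method = "Hartigan dip test (uniform bootstrap)")
}

#' @rdname dip_test
#' @export
glance.dip_test <- function(x, ...) tidy.dip_test(x)
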