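#' Deming (errors-in-variables) regression
#'
#' Fits a straight line when both variables carry measurement error,
#' minimising the weighted orthogonal residual sum of squares
#' \eqn{\sum (y_i - a - b x_i)^2 / (\lambda + b^2)} for a given error
#' variance ratio \eqn{\lambda = \sigma^2_y / \sigma^2_x}. With the default
#' `lambda = 1` this is orthogonal regression, the convention used for the
#' PSP-versus-spike-threshold correlation figures. The closed-form solution
#' is
#' \deqn{b = \frac{s_{yy} - \lambda s_{xx} +
#'   \sqrt{(s_{yy}-\lambda s_{xx})^2 + 4 \lambda s_{xy}^2}}{2 s_{xy}},
#'   \quad a = \bar y - b \bar x.}
#'
#' @param x,y numeric vectors, n >= 3, not all points identical.
#' @param lambda ratio of the error variance of `y` to that of `x`
#'   (positive; `1` gives orthogonal regression).
#' @return an object of class `"deming_fit"` with elements `slope`,
#'   `intercept`, `lambda`, `n`, `residual_ss` (the minimised criterion).
#' @examples
#' f <- deming_fit(1:10, 2 * (1:10) + 1)
#' tidy(f)
#' @export
deming_fit <- function(x, y, lambda = 1) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("`x` and `y` must have the same length", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 points", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y)) || !is.finite(lambda) || lambda <= 0)
    stop("inputs must be finite and `lambda` positive", call. = FALSE)
  n <- length(x)
  sxx <- sum((x - mean(x))^2) / n
  syy <- sum((y - mean(y))^2) / n
  sxy <- sum((x - mean(x)) * (y - mean(y))) / n
  if (sxx == 0 && syy == 0) stop("degenerate input: all points identical", call. = FALSE)
  if (abs(sxy) < .Machine$double.eps * (sxx + syy)) {
    # no covariance: vertical or horizontal principal direction
    slope <- if (syy > lambda * sxx) Inf else 0
  } else {
    t0 <- syy - lambda * sxx
    slope <- (t0 + sqrt(t0^2 + 4 * lambda * sxy^2)) / (2 * sxy)
  }
  intercept <- if (is.finite(slope)) mean(y) - slope * mean(x) else NA_real_
  rss <- if (is.finite(slope)) {
    sum((y - intercept - slope * x)^2) / (lambda + slope^2)
  } else {
    sum((x - mean(x))^2)
  }
  structure(
    list(slope = slope, intercept = intercept, lambda = lambda, n = n,
         residual_ss = rss),
    class = "deming_fit"
  )
}

#' @export
print.deming_fit <- function(x, ...) {
  cat(sprintf("Deming regression (lambda = %g, n = %d)\n", x$lambda, x$n))
  cat(sprintf("  y = %.6g + %.6g x\n", x$intercept, x$slope))
  invisible(x)
}

#' @rdname deming_fit
#' @param ... unused.
#' @export
tidy.deming_fit <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", "slope"),
    estimate = c(x$intercept, x$slope)
  )
}

#' @rdname deming_fit
#' @export
glance.deming_fit <- function(x, ...) {
  tibble::tibble(lambda = x$lambda, n = x$n, residual_ss = x$residual_ss)
}
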