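#' Mean, SD and confidence band of a sample
#'
#' Mean, standard deviation (n-1 denominator) and the Student-t
#' confidence band `mean +/- t(1 - alpha/2, n - 1) * SD / sqrt(n)` used
#' for replicate measurements throughout the pipeline. A sample of one
#' returns the mean with `NA` SD and band.
#'
#' @param values Numeric vector, n >= 1, finite.
#' @param alpha Significance level in (0, 1); default 0.05.
#' @return A list of class `sample_summary` with elements `n`, `mean`,
#'   `sd`, `ci_lo`, `ci_hi`, `alpha`.
#' @examples
#' mean_sd_ci(c(1, 2, 3, 4))
#' @export
mean_sd_ci <- function(values, alpha = 0.05) {
  values <- as.numeric(values)
  if (length(values) == 0L) {
    stop("need at least one value", call. = FALSE)
  }
  if (any(!is.finite(values))) {
    stop("values must be finite", call. = FALSE)
  }
  stop_if_not_scalar_num(alpha, "alpha", 0, strict = TRUE)
  if (alpha >= 1) {
    stop("'alpha' must be in (0, 1)", call. = FALSE)
  }
  n <- length(values)
  m <- mean(values)
  if (n == 1L) {
    return(structure(
      list(n = n, mean = m, sd = NA_real_, ci_lo = NA_real_,
        ci_hi = NA_real_, alpha = alpha),
      class = "sample_summary"
    ))
  }
  s <- sd(values)
  half <- qt(1 - alpha / 2, df = n - 1) * s / sqrt(n)
  structure(
    list(n = n, mean = m, sd = s, ci_lo = m - half, ci_hi = m + half,
      alpha = alpha),
    class = "sample_summary"
  )
}

#' @export
print.sample_summary <- function(x, ...) {
  cat(sprintf(
    "n = %d, mean = %.6g, sd = %s, %.0f%% CI [%s, %s]\n",
    x$n, x$mean, format(x$sd), 100 * (1 - x$alpha),
    format(x$ci_lo), format(x$ci_hi)
  ))
  invisible(x)
}

#' Two-sided t-test p-value for two replicate samples
#'
#' Welch (unequal-variance) two-sided t-test by default; a pooled-
#' variance Student test is available via `var_equal = TRUE`. Degenerate
#' zero-variance cases follow a documented convention: both samples
#' constant with equal means give p = 1, with different means p = 0.
#'
#' @param a,b Numeric vectors, each with n >= 2.
#' @param var_equal Use the pooled-variance test instead of Welch.
#' @return The p-value in `[0, 1]`.
#' @examples
#' t_test_p(rnorm(4), rnorm(4))
#' @export
t_test_p <- function(a, b, var_equal = FALSE) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L) {
    stop("each sample needs at least 2 values", call. = FALSE)
  }
  if (any(!is.finite(a)) || any(!is.finite(b))) {
    stop("samples must be finite", call. = FALSE)
  }
  if (var(a) == 0 && var(b) == 0) {
    return(if (mean(a) == mean(b)) 1 else 0)
  }
  t.test(a, b, var.equal = var_equal)$p.value
}

#' Significance flag at the 0.05 level
#'
#' @param p P-value(s).
#' @return Logical: `p < 0.05`.
#' @export
is_significant <- function(p) {
  p < 0.05
}
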