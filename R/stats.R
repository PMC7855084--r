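#' Coefficient of determination between paired series
#'
#' The square of the Pearson correlation between paired observations.
#'
#' @param x,y Numeric vectors of equal length (>= 3), each with non-zero
#'   variance. `NA` pairs are dropped.
#' @return r-squared in `[0, 1]`.
#' @examples
#' r_squared(1:10, 2 * (1:10) + rnorm(10, sd = 0.1))
#' @export
r_squared <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) abort("At least 3 complete pairs are required.")
  if (var(x) <= 0 || var(y) <= 0) abort("Both series need non-zero variance.")
  cor(x, y)^2
}

#' Bland-Altman agreement analysis
#'
#' Computes the per-pair means `(x + y) / 2` and differences `x - y` of two
#' measurement series, the mean difference (bias), and the 95% limits of
#' agreement `mean +/- 1.96 sd` of the differences (sample standard
#' deviation, n - 1 denominator). The sign convention is
#' `difference = x - y`; pass the 2D estimate as `x` and the reference (3D
#' estimate or ground truth) as `y` so that systematic 2D underestimation
#' appears as a negative bias.
#'
#' @param x,y Numeric vectors of equal length (>= 2).
#' @param conf_mult Multiplier for the limits of agreement (1.96 for 95%).
#' @return An object of class `bland_altman` with [tidy()], [glance()] and
#'   [autoplot()] methods: a list with `pairs` (tibble of `mean`, `diff`),
#'   `mean_difference`, `loa_low`, `loa_high`, `sd_difference`, `n`.
#' @examples
#' ba <- bland_altman(rnorm(50, 10), rnorm(50, 10))
#' glance(ba)
#' @export
bland_altman <- function(x, y, conf_mult = 1.96) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 2) abort("At least 2 complete pairs are required.")
  d <- x - y
  md <- mean(d)
  s <- sd(d)
  structure(
    list(
      pairs = tibble(mean = (x + y) / 2, diff = d),
      mean_difference = md,
      sd_difference = s,
      loa_low = md - conf_mult * s,
      loa_high = md + conf_mult * s,
      conf_mult = conf_mult,
      n = length(x)
    ),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "<bland_altman> n = %d, bias = %.3f, 95%% limits [%.3f, %.3f]\n",
    x$n, x$mean_difference, x$loa_low, x$loa_high
  ))
  invisible(x)
}

#' @rdname bland_altman
#' @param x A `bland_altman` object.
#' @param ... Unused.
#' @export
tidy.bland_altman <- function(x, ...) x$pairs

#' @rdname bland_altman
#' @export
glance.bland_altman <- function(x, ...) {
  tibble(n = x$n, mean_difference = x$mean_difference,
         sd_difference = x$sd_difference,
         loa_low = x$loa_low, loa_high = x$loa_high)
}

#' @rdname bland_altman
#' @param object A `bland_altman` object.
#' @export
autoplot.bland_altman <- function(object, ...) {
  ggplot2::ggplot(object$pairs, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = object$mean_difference) +
    ggplot2::geom_hline(
      yintercept = c(object$loa_low, object$loa_high), linetype = "dotted"
    ) +
    ggplot2::labs(
      x = "Mean of the two methods",
      y = "Difference between methods",
      title = sprintf("Bland-Altman: bias %.2f, limits [%.2f, %.2f]",
                      object$mean_difference, object$loa_low, object$loa_high)
    ) +
    ggplot2::theme_minimal()
}

#' Student's t tests used in the agreement analysis
#'
#' A thin, uniformly shaped wrapper over [stats::t.test()] for the three
#' variants used here: paired two-tailed (estimated vs set values),
#' one-sample two-tailed (estimates vs a known ground-truth value), and
#' two-sample two-tailed with pooled variance (2D vs 3D ensemble means,
#' the classical equal-variance form).
#'
#' @param a Numeric vector.
#' @param b Second vector (paired/two-sample) or the null value
#'   (one-sample).
#' @param kind `"paired"`, `"one_sample"` or `"two_sample"`.
#' @return A one-row tibble: `statistic`, `df`, `p_value`, `estimate`,
#'   `test_kind`.
#' @examples
#' t_tests(rnorm(10, 1), 0, kind = "one_sample")
#' @export
t_tests <- function(a, b, kind = c("paired", "one_sample", "two_sample")) {
  kind <- match.arg(kind)
  if (kind == "paired") {
    if (length(a) != length(b)) abort("Paired test needs equal lengths.")
    if (length(a) < 2) abort("At least 2 pairs are required.")
    if (sd(a - b) == 0 && mean(a - b) == 0) {
      # identical series: no evidence of any difference
      return(tibble(statistic = 0, df = length(a) - 1, p_value = 1,
                    estimate = 0, test_kind = kind))
    }
  }
  ht <- switch(kind,
    paired = t.test(a, b, paired = TRUE),
    one_sample = {
      if (length(b) != 1) abort("One-sample test needs a single null value.")
      if (length(a) < 2) abort("At least 2 observations are required.")
      t.test(a, mu = b)
    },
    two_sample = {
      if (length(a) < 2 || length(b) < 2) abort("At least 2 observations per group.")
      t.test(a, b, var.equal = TRUE)
    }
  )
  tibble(
    statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p_value = ht$p.value,
    estimate = unname(ht$estimate[1]),
    test_kind = kind
  )
}
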