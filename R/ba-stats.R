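#' Bland-Altman agreement analysis
#'
#' Compares two methods measuring the same quantity on paired subjects.
#' Differences are taken first argument minus second (`d = a - b`, the
#' "a compared to b" direction); the bias is the mean difference
#' (accuracy), and the 95% limits of agreement are
#' `bias +/- 1.96 * SD(d)` (precision), with the sample (n - 1) standard
#' deviation.
#'
#' @param a,b Numeric vectors of paired measurements, equal length >= 2,
#'   no missing pairs.
#' @return An object of class `bland_altman`: bias, `sd_diff`, `loa_low`,
#'   `loa_high`, `n`, plus the per-pair differences and means for plotting.
#'   Use [generics::tidy()] / [generics::glance()] for tibble output and
#'   [ggplot2::autoplot()] for the agreement plot.
#' @examples
#' set.seed(1)
#' a <- rnorm(30, 820, 100)
#' ba <- bland_altman(a + rnorm(30, -20, 90), a)
#' tidy(ba)
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b)) {
    stop("`a` and `b` must have equal length", call. = FALSE)
  }
  if (length(a) < 2) stop("at least 2 pairs are required", call. = FALSE)
  if (any(!is.finite(a)) || any(!is.finite(b))) {
    stop("pairs must be complete and finite", call. = FALSE)
  }
  d <- a - b
  bias <- mean(d)
  sd_diff <- stats::sd(d)
  structure(
    list(
      bias = bias,
      sd_diff = sd_diff,
      loa_low = bias - 1.96 * sd_diff,
      loa_high = bias + 1.96 * sd_diff,
      n = length(d),
      differences = d,
      means = (a + b) / 2
    ),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, digits = 4, ...) {
  cat("Bland-Altman agreement (n =", x$n, ")\n")
  cat("  bias:", signif(x$bias, digits), "\n")
  cat("  SD of differences:", signif(x$sd_diff, digits), "\n")
  cat("  95% LOA:", signif(x$loa_low, digits), "to", signif(x$loa_high, digits), "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.bland_altman <- function(x, ...) {
  tibble::tibble(
    bias = x$bias, sd_diff = x$sd_diff,
    loa_low = x$loa_low, loa_high = x$loa_high, n = x$n
  )
}

#' @exportS3Method generics::glance
glance.bland_altman <- function(x, ...) tidy(x)

#' Bland-Altman plot
#'
#' Scatter of per-pair differences against per-pair means with horizontal
#' lines at the bias and the 95% limits of agreement.
#'
#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @param object A [bland_altman()] fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @rdname bland_altman
#' @exportS3Method ggplot2::autoplot
autoplot.bland_altman <- function(object, ...) {
  df <- tibble::tibble(mean = object$means, difference = object$differences)
  ggplot2::ggplot(df, ggplot2::aes(x = mean, y = difference)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_hline(yintercept = object$bias, linetype = "solid") +
    ggplot2::geom_hline(
      yintercept = c(object$loa_low, object$loa_high), linetype = "dashed"
    ) +
    ggplot2::labs(
      x = "Mean of methods", y = "Difference (first - second)",
      title = sprintf("Bland-Altman: bias %.3g, 95%% LOA [%.3g, %.3g]",
                      object$bias, object$loa_low, object$loa_high)
    ) +
    ggplot2::theme_minimal()
}

#' Paired two-tailed t test
#'
#' Thin wrapper over [stats::t.test()] with the degenerate cases handled
#' explicitly: all differences zero gives `t = 0, p = 1`; zero variance
#' with a non-zero mean difference is reported with `p = 0` and a
#' `degenerate` flag (the t statistic is unbounded).
#'
#' @param a,b Paired numeric vectors, length >= 2.
#' @return A one-row tibble: `t`, `df`, `p_two_tailed`, `mean_difference`,
#'   `degenerate`.
#' @export
paired_t_test <- function(a, b) {
  if (length(a) != length(b)) {
    stop("`a` and `b` must have equal length", call. = FALSE)
  }
  if (length(a) < 2) stop("at least 2 pairs are required", call. = FALSE)
  d <- a - b
  n <- length(d)
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) {
      return(tibble::tibble(t = 0, df = n - 1, p_two_tailed = 1,
                            mean_difference = 0, degenerate = FALSE))
    }
    return(tibble::tibble(t = sign(mean(d)) * Inf, df = n - 1, p_two_tailed = 0,
                          mean_difference = mean(d), degenerate = TRUE))
  }
  fit <- stats::t.test(a, b, paired = TRUE)
  tibble::tibble(
    t = unname(fit$statistic),
    df = unname(fit$parameter),
    p_two_tailed = fit$p.value,
    mean_difference = mean(d),
    degenerate = FALSE
  )
}

#' Cohort summary statistics
#'
#' Mean, SD, median, 95% confidence interval and range, with the CI under
#' the normal approximation `mean +/- 1.96 * sd / sqrt(n)` (the data are
#' assumed normally distributed; the 1.96 multiplier, not the
#' t-quantile, reproduces the reporting convention this package follows).
#'
#' @param values Numeric vector, length >= 2.
#' @return A one-row tibble: `n`, `mean`, `sd`, `median`, `ci_low`,
#'   `ci_high`, `min`, `max`.
#' @export
summarize_cohort <- function(values) {
  if (length(values) < 2) stop("at least 2 values are required", call. = FALSE)
  if (any(!is.finite(values))) stop("values must be finite", call. = FALSE)
  m <- mean(values)
  s <- stats::sd(values)
  half <- 1.96 * s / sqrt(length(values))
  tibble::tibble(
    n = length(values), mean = m, sd = s, median = stats::median(values),
    ci_low = m - half, ci_high = m + half,
    min = min(values), max = max(values)
  )
}
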