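# Bland-Altman method agreement with the interchangeability rule used to
# validate the algorithmic counts against manual reference counts.

#' Bland-Altman comparison of algorithmic and reference counts
#'
#' Computes the bias (mean of algorithm - reference differences), precision
#' (SD of the differences), limits of agreement (bias +/- `conf` * SD),
#' percent bias (bias over the grand mean of the pairwise means, x100), and
#' a proportional-trend test (two-sided regression of differences on
#' pairwise means). The two methods are declared interchangeable when the
#' absolute percent bias is below `bias_limit_pct` and there is no tendency
#' of the difference to grow with the mean (trend p >= `alpha`). With zero
#' spread in the differences the trend test is skipped and reported as
#' no-trend.
#'
#' @param data A data frame of paired counts.
#' @param algo,ref Columns (tidy-eval) holding the algorithmic and reference
#'   series. The reference may be a single observer or the mean of two
#'   observers (see [observer_mean()]).
#' @param conf Multiplier for the limits of agreement.
#' @param bias_limit_pct Interchangeability bound on |percent bias|.
#' @param alpha Significance level of the trend test.
#' @return An object of class `"bland_altman"`; see [glance.bland_altman()]
#'   and [tidy.bland_altman()].
#' @export
bland_altman <- function(data, algo, ref, conf = 1.96,
                         bias_limit_pct = 10, alpha = 0.05) {
  a <- dplyr::pull(data, {{ algo }})
  r <- dplyr::pull(data, {{ ref }})
  if (length(a) != length(r)) stop("paired series must have equal length",
                                   call. = FALSE)
  n <- length(a)
  if (n < 3) stop("need at least 3 pairs", call. = FALSE)
  diffs <- a - r
  means <- (a + r) / 2
  bias <- mean(diffs)
  precision <- stats::sd(diffs)
  grand <- mean(means)
  percent_bias <- if (bias == 0) 0 else if (grand == 0) NA_real_ else
    100 * bias / grand
  if (precision > 0 && stats::sd(means) > 0) {
    fit <- stats::lm(diffs ~ means)
    cf <- summary(fit)$coefficients
    trend_slope <- cf[2, 1]
    trend_p <- cf[2, 4]
  } else {
    trend_slope <- NA_real_
    trend_p <- NA_real_  # zero spread: no trend can exist
  }
  no_trend <- is.na(trend_p) || trend_p >= alpha
  interchangeable <- !is.na(percent_bias) &&
    abs(percent_bias) < bias_limit_pct && no_trend
  structure(list(
    n = n, bias = bias, precision = precision,
    loa_low = bias - conf * precision, loa_high = bias + conf * precision,
    percent_bias = percent_bias,
    trend_slope = trend_slope, trend_p = trend_p, no_trend = no_trend,
    interchangeable = interchangeable,
    conf = conf, bias_limit_pct = bias_limit_pct, alpha = alpha,
    pairs = tibble::tibble(algo = a, ref = r, mean = means, diff = diffs)),
    class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "<bland_altman> n = %d\n  bias %.4g (%.4g%% of grand mean), precision %.4g\n  limits of agreement [%.4g, %.4g]\n  trend p = %s; %sinterchangeable\n",
    x$n, x$bias, x$percent_bias, x$precision, x$loa_low, x$loa_high,
    ifelse(is.na(x$trend_p), "- (no spread)", format(x$trend_p, digits = 3)),
    if (x$interchangeable) "" else "NOT "))
  invisible(x)
}

#' Per-pair Bland-Altman table
#' @param x A `bland_altman` object.
#' @param ... Unused.
#' @return Tibble with `algo`, `ref`, `mean`, `diff`.
#' @export
tidy.bland_altman <- function(x, ...) x$pairs

#' One-row Bland-Altman summary
#' @param x A `bland_altman` object.
#' @param ... Unused.
#' @return Tibble with `n`, `bias`, `precision`, `loa_low`, `loa_high`,
#'   `percent_bias`, `trend_slope`, `trend_p`, `interchangeable`.
#' @export
glance.bland_altman <- function(x, ...) {
  tibble::tibble(n = x$n, bias = x$bias, precision = x$precision,
                 loa_low = x$loa_low, loa_high = x$loa_high,
                 percent_bias = x$percent_bias,
                 trend_slope = x$trend_slope, trend_p = x$trend_p,
                 interchangeable = x$interchangeable)
}

#' Bland-Altman plot
#' @param object A `bland_altman` object.
#' @param ... Unused.
#' @return A ggplot: differences against pairwise means with bias and
#'   limits of agreement.
#' @export
autoplot.bland_altman <- function(object, ...) {
  ggplot2::ggplot(object$pairs, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$bias, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "Mean of methods", y = "Algorithm - reference",
                  title = sprintf("Bias %.3g [%.3g, %.3g]", object$bias,
                                  object$loa_low, object$loa_high)) +
    ggplot2::theme_minimal()
}

#' Element-wise mean of two observers
#'
#' The reference series for the agreement analysis when two manual counts
#' are available.
#'
#' @param obs1,obs2 Equal-length numeric vectors.
#' @return Element-wise mean.
#' @export
observer_mean <- function(obs1, obs2) {
  if (length(obs1) != length(obs2)) stop("observer series must have equal length",
                                         call. = FALSE)
  (obs1 + obs2) / 2
}

#' Agreement analysis per cell class from a counts table
#'
#' @param data Data frame with columns `cell_class`, `algo_count`, and
#'   either `ref_count` or both `obs1_count` and `obs2_count` (averaged via
#'   [observer_mean()]).
#' @param ... Passed to [bland_altman()].
#' @return A tibble with one glance row per cell class.
#' @export
agreement_by_class <- function(data, ...) {
  if (!"ref_count" %in% names(data)) {
    data <- dplyr::mutate(data, ref_count = observer_mean(.data$obs1_count,
                                                          .data$obs2_count))
  }
  data |>
    dplyr::group_by(.data$cell_class) |>
    dplyr::group_modify(function(d, key) {
      glance(bland_altman(d, "algo_count", "ref_count", ...))
    }) |>
    dplyr::ungroup()
}
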