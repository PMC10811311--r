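#' Bland-Altman agreement between measured and expected lung weight index
#'
#' For paired series the differences are `d_i = measured_i - expected_i`
#' (so a negative bias means the measured index falls below the model's
#' expectation). The analysis reports
#' \itemize{
#'   \item bias = mean(d), with 95% CI `bias +/- t * sd/sqrt(n)`;
#'   \item limits of agreement `bias +/- 1.96 * sd` (fixed 1.96 multiplier,
#'     not a t quantile), each with 95% CI `LOA +/- t * sd * sqrt(3/n)`;
#' }
#' where `sd` is the sample SD of the differences (n-1 denominator) and `t`
#' the two-sided t quantile on n-1 degrees of freedom.
#'
#' @param data Data frame holding the paired series.
#' @param measured,expected Unquoted column names (tidy evaluation) of the
#'   measured and expected indices, in g/kg.
#' @param conf_level Confidence level for the CIs (default 0.95).
#' @return An `lwi_agreement` object with fields `bias`, `bias_ci`,
#'   `loa_upper`, `loa_upper_ci`, `loa_lower`, `loa_lower_ci`, `sd_diff`,
#'   `n`, and `$data` (pair means and differences, ready for plotting).
#'   [tidy()] returns one row per quantity with its CI; [autoplot()] draws
#'   the Bland-Altman plot.
#' @examples
#' pairs <- simulate_paired_lwi(n = 36, seed = 3)
#' ba <- bland_altman(pairs, measured_lwi_g_per_kg, expected_lwi_g_per_kg)
#' tidy(ba)
#' @export
bland_altman <- function(data, measured, expected, conf_level = 0.95) {
  if (!is.data.frame(data)) abort("`data` must be a data frame.")
  m <- eval_tidy(enquo(measured), data)
  e <- eval_tidy(enquo(expected), data)
  if (!is.numeric(m) || !is.numeric(e)) {
    abort("`measured` and `expected` must be numeric columns.")
  }
  if (length(m) != length(e)) {
    abort("`measured` and `expected` must have equal length.")
  }
  n <- length(m)
  if (n < 3) abort("Bland-Altman analysis requires at least 3 pairs.")
  if (anyNA(m) || anyNA(e)) abort("Paired series contain missing values.")

  d <- m - e
  est <- agreement_intervals(n = n, bias = mean(d), sd_diff = sd(d),
                             conf_level = conf_level)
  structure(
    list(
      bias = est$estimate[est$quantity == "bias"],
      bias_ci = c(est$conf.low[est$quantity == "bias"],
                  est$conf.high[est$quantity == "bias"]),
      loa_upper = est$estimate[est$quantity == "loa_upper"],
      loa_upper_ci = c(est$conf.low[est$quantity == "loa_upper"],
                       est$conf.high[est$quantity == "loa_upper"]),
      loa_lower = est$estimate[est$quantity == "loa_lower"],
      loa_lower_ci = c(est$conf.low[est$quantity == "loa_lower"],
                       est$conf.high[est$quantity == "loa_lower"]),
      sd_diff = sd(d),
      n = n,
      conf_level = conf_level,
      data = tibble(pair_mean = (m + e) / 2, difference = d)
    ),
    class = "lwi_agreement"
  )
}

#' Bland-Altman intervals from summary statistics
#'
#' Computes the bias and limits of agreement with their confidence
#' intervals from `n`, the mean difference and its SD alone — the same
#' formulas [bland_altman()] applies to raw pairs. Useful to reconstruct
#' published agreement intervals from reported summaries.
#'
#' @param n Number of pairs (>= 3).
#' @param bias Mean difference, g/kg.
#' @param sd_diff Sample SD of the differences, g/kg (>= 0).
#' @param conf_level Confidence level.
#' @return A tibble with columns `quantity` (`bias`, `loa_lower`,
#'   `loa_upper`), `estimate`, `conf.low`, `conf.high`.
#' @examples
#' agreement_intervals(n = 36, bias = -0.26, sd_diff = 2.07)
#' @export
agreement_intervals <- function(n, bias, sd_diff, conf_level = 0.95) {
  n <- check_count(n, "n", min = 3L)
  check_number(bias, "bias")
  check_number(sd_diff, "sd_diff")
  if (sd_diff < 0) abort("`sd_diff` must be >= 0.")
  tq <- qt(1 - (1 - conf_level) / 2, df = n - 1)
  se_bias <- sd_diff / sqrt(n)
  se_loa <- sd_diff * sqrt(3 / n)
  loa_up <- bias + 1.96 * sd_diff
  loa_lo <- bias - 1.96 * sd_diff
  tibble(
    quantity = c("bias", "loa_lower", "loa_upper"),
    estimate = c(bias, loa_lo, loa_up),
    conf.low = c(bias - tq * se_bias, loa_lo - tq * se_loa, loa_up - tq * se_loa),
    conf.high = c(bias + tq * se_bias, loa_lo + tq * se_loa, loa_up + tq * se_loa)
  )
}

#' @export
print.lwi_agreement <- function(x, ...) {
  cat("<lwi_agreement> n = ", x$n, " pairs\n", sep = "")
  cat(sprintf("  bias      %6.2f g/kg [%.2f, %.2f]\n", x$bias, x$bias_ci[1], x$bias_ci[2]))
  cat(sprintf("  upper LOA %6.2f g/kg [%.2f, %.2f]\n", x$loa_upper, x$loa_upper_ci[1], x$loa_upper_ci[2]))
  cat(sprintf("  lower LOA %6.2f g/kg [%.2f, %.2f]\n", x$loa_lower, x$loa_lower_ci[1], x$loa_lower_ci[2]))
  invisible(x)
}

#' @describeIn bland_altman Bias and LOAs with their CIs, one row each.
#' @param x,object An `lwi_agreement`.
#' @param ... Unused.
#' @export
tidy.lwi_agreement <- function(x, ...) {
  agreement_intervals(x$n, x$bias, x$sd_diff, x$conf_level)
}

#' @describeIn bland_altman One-row summary (n, bias, sd of differences).
#' @export
glance.lwi_agreement <- function(x, ...) {
  tibble(n = x$n, bias = x$bias, sd_diff = x$sd_diff,
         loa_lower = x$loa_lower, loa_upper = x$loa_upper)
}

#' @describeIn bland_altman Bland-Altman plot: pair means vs differences,
#'   with the bias (solid) and LOA (dashed) reference lines.
#' @export
autoplot.lwi_agreement <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$pair_mean, y = .data$difference)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$bias) +
    ggplot2::geom_hline(yintercept = c(object$loa_lower, object$loa_upper),
                        linetype = "dashed") +
    ggplot2::labs(x = "Mean of measured and expected LWI (g/kg)",
                  y = "Measured - expected LWI (g/kg)")
}
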