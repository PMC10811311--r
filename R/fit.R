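new_lwi_fit <- function(model, a_ci, b_ci, band_upper, band_lower,
                        rmse_log10, mae_log10, n, residuals, engine,
                        data, bw_range) {
  structure(
    list(
      model = model, a_ci = a_ci, b_ci = b_ci,
      band_upper = band_upper, band_lower = band_lower,
      rmse_log10 = rmse_log10, mae_log10 = mae_log10,
      n = n, residuals = residuals, engine = engine,
      data = data, bw_range = bw_range
    ),
    class = "lwi_fit"
  )
}

#' Fit the exponential lung weight index model
#'
#' Fits `LWI = a * 10^(b * BW)` to a cohort. The default engine regresses
#' `log10(LWI)` on body weight by ordinary least squares, so `a` is the
#' back-transformed intercept and `b` the slope; residual summaries
#' (`rmse_log10`, `mae_log10`) are on the log10 scale, the scale on which
#' the noise in these data is close to homoscedastic. 95% confidence
#' intervals for `a` and `b` come from the standard linear-regression
#' covariance (t quantiles), with `a`'s interval back-transformed.
#'
#' The confidence band curves are parameter-wise: the upper band pairs the
#' upper confidence bounds of `a` and `b`, the lower band the lower bounds.
#' This is a band on the fitted curve's parameters, not a pointwise
#' prediction interval, and is recorded as such in the object.
#'
#' `engine = "nls"` instead minimizes squared error on the natural g/kg
#' scale via [stats::nls()] (started from the log-linear solution, with
#' asymptotic CIs). It is provided for sensitivity analysis; residual
#' summaries are still reported on the log10 scale for comparability.
#'
#' @param data Cohort data frame with columns `body_weight_kg` and
#'   `lung_weight_g` (the [simulate_cohort()] schema); >= 3 rows, all
#'   weights > 0, body weight not constant.
#' @param engine `"log10"` (default) or `"nls"`.
#' @param conf_level Confidence level for parameter intervals.
#' @return An object of class `lwi_fit`: point model, parameter CIs, band
#'   models, log10-scale RMSE/MAE, per-animal log10 residuals, and the
#'   fitted data. Supports [tidy()], [glance()], [autoplot()], and the
#'   prediction functions.
#' @examples
#' cohort <- simulate_cohort(n = 141, seed = 1)
#' fit <- fit_lwi(cohort)
#' tidy(fit)
#' glance(fit)
#' @export
fit_lwi <- function(data, engine = c("log10", "nls"), conf_level = 0.95) {
  engine <- match.arg(engine)
  check_cohort(data, min_rows = 3L)
  check_number(conf_level, "conf_level", positive = TRUE)
  if (conf_level >= 1) abort("`conf_level` must be in (0, 1).")

  bw <- data$body_weight_kg
  lwi <- data$lung_weight_g / data$body_weight_kg
  if (var(bw) == 0) {
    abort("Singular fit: body weight has zero variance across the cohort.")
  }

  log_lwi <- log10(lwi)
  ols <- lm(log_lwi ~ bw)

  if (engine == "log10") {
    est <- coef(ols)
    ci <- confint(ols, level = conf_level)
    a <- 10^est[[1]]
    b <- est[[2]]
    a_ci <- 10^ci[1, ]
    b_ci <- ci[2, ]
  } else {
    start <- list(a = 10^coef(ols)[[1]], b = coef(ols)[[2]])
    # scaleOffset keeps the convergence test meaningful on (near-)exact fits
    nfit <- nls(lwi ~ a * 10^(b * bw), start = start,
                control = stats::nls.control(maxiter = 200, scaleOffset = 1))
    est <- coef(nfit)
    ci <- suppressMessages(stats::confint.default(nfit, level = conf_level))
    a <- est[["a"]]
    b <- est[["b"]]
    a_ci <- ci["a", ]
    b_ci <- ci["b", ]
  }

  model <- lwi_model(a, b)
  resid_log10 <- log_lwi - log10(predict_lwi(model, bw))
  new_lwi_fit(
    model = model,
    a_ci = unname(a_ci),
    b_ci = unname(b_ci),
    band_upper = lwi_model(max(a_ci), max(b_ci)),
    band_lower = lwi_model(min(a_ci), min(b_ci)),
    rmse_log10 = sqrt(mean(resid_log10^2)),
    mae_log10 = mean(abs(resid_log10)),
    n = nrow(data),
    residuals = unname(resid_log10),
    engine = engine,
    data = tibble(body_weight_kg = bw, lwi_g_per_kg = lwi),
    bw_range = range(bw)
  )
}

#' @export
print.lwi_fit <- function(x, ...) {
  cat("<lwi_fit> (engine: ", x$engine, ", n = ", x$n, ")\n", sep = "")
  cat("  point: ", format(x$model), "\n", sep = "")
  cat(sprintf("  a = %.4g g/kg [%.4g, %.4g];  b = %.4g /kg [%.4g, %.4g]\n",
              x$model$a, x$a_ci[1], x$a_ci[2],
              x$model$b, x$b_ci[1], x$b_ci[2]))
  cat(sprintf("  RMSE(log10) = %.4g, MAE(log10) = %.4g\n",
              x$rmse_log10, x$mae_log10))
  invisible(x)
}

#' @describeIn fit_lwi Parameter estimates and confidence bounds, one row per
#'   parameter.
#' @param x,object An `lwi_fit`.
#' @param ... Unused.
#' @export
tidy.lwi_fit <- function(x, ...) {
  tibble(
    term = c("a", "b"),
    estimate = c(x$model$a, x$model$b),
    conf.low = c(x$a_ci[1], x$b_ci[1]),
    conf.high = c(x$a_ci[2], x$b_ci[2])
  )
}

#' @describeIn fit_lwi One-row model summary (n, log10-scale RMSE and MAE).
#' @export
glance.lwi_fit <- function(x, ...) {
  tibble(
    n = x$n,
    rmse_log10 = x$rmse_log10,
    mae_log10 = x$mae_log10,
    engine = x$engine
  )
}

#' @describeIn fit_lwi Scatter of the fitted cohort with the point curve and
#'   parameter-wise confidence band.
#' @export
autoplot.lwi_fit <- function(object, ...) {
  grid <- tibble(body_weight_kg = seq(object$bw_range[1], object$bw_range[2],
                                      length.out = 200))
  grid$fit <- predict_lwi(object$model, grid$body_weight_kg)
  grid$upper <- predict_lwi(object$band_upper, grid$body_weight_kg)
  grid$lower <- predict_lwi(object$band_lower, grid$body_weight_kg)
  p <- ggplot2::ggplot(grid, ggplot2::aes(x = .data$body_weight_kg)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         fill = "grey80", alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fit), linetype = "dashed") +
    ggplot2::labs(x = "Body weight (kg)", y = "Lung weight index (g/kg)")
  if (!is.null(object$data)) {
    p <- p + ggplot2::geom_point(
      data = object$data,
      ggplot2::aes(x = .data$body_weight_kg, y = .data$lwi_g_per_kg)
    )
  }
  p
}

#' Split a cohort into training and validation sets
#'
#' Random disjoint, exhaustive partition. The training size is
#' `floor(n * train_fraction)`, which reproduces the canonical 141/36 split
#' of a 177-animal cohort at 80/20 (and 159/18 at 90/10).
#'
#' @param data Cohort data frame.
#' @param train_fraction Fraction in (0, 1) assigned to training.
#' @param seed Integer seed; required.
#' @return Named list of two tibbles, `train` and `validation`.
#' @examples
#' parts <- split_cohort(simulate_cohort(177, seed = 1), 0.8, seed = 2)
#' vapply(parts, nrow, integer(1))  # 141, 36
#' @export
split_cohort <- function(data, train_fraction = 0.8, seed) {
  if (!is.data.frame(data)) abort("`data` must be a data frame.")
  check_number(train_fraction, "train_fraction")
  if (train_fraction <= 0 || train_fraction >= 1) {
    abort("`train_fraction` must be strictly between 0 and 1.")
  }
  seed <- check_seed(seed)
  n <- nrow(data)
  n_train <- floor(n * train_fraction)
  if (n_train < 1 || n_train >= n) {
    abort("Cohort too small: both the training and validation part must be non-empty.")
  }
  idx <- withr::with_seed(seed, sample.int(n, n_train))
  list(
    train = as_tibble(data[sort(idx), , drop = FALSE]),
    validation = as_tibble(data[setdiff(seq_len(n), sort(idx)), , drop = FALSE])
  )
}

#' Out-of-sample residual summaries of a model on a cohort
#'
#' Residuals are `log10(observed LWI) - log10(predicted LWI)`; RMSE is the
#' root mean square and MAE the mean absolute value of these.
#'
#' @param model An `lwi_model` or `lwi_fit`.
#' @param data Non-empty cohort data frame.
#' @return One-row tibble: `n`, `rmse_log10`, `mae_log10`.
#' @export
evaluate_lwi <- function(model, data) {
  model <- resolve_model(model)
  check_cohort(data, min_rows = 1L)
  lwi <- data$lung_weight_g / data$body_weight_kg
  r <- log10(lwi) - log10(predict_lwi(model, data$body_weight_kg))
  tibble(
    n = nrow(data),
    rmse_log10 = sqrt(mean(r^2)),
    mae_log10 = mean(abs(r))
  )
}

#' k-fold cross-validation of the exponential fit
#'
#' Standard k-fold: animals are randomly assigned to `k` disjoint,
#' exhaustive folds; each fold is held out in turn, the model is fitted on
#' the remainder and evaluated on the held-out fold. `k = nrow(data)` gives
#' leave-one-out.
#'
#' @param data Cohort data frame.
#' @param k Number of folds, between 2 and `nrow(data)`.
#' @param seed Integer seed; required.
#' @inheritParams fit_lwi
#' @return An `lwi_cv` object: `$folds` (per-fold tibble with `fold`,
#'   `n_train`, `n_test`, `rmse_log10`, `mae_log10`) and `$summary`
#'   (one-row tibble of fold means). [tidy()] returns the folds, [glance()]
#'   the summary.
#' @export
cross_validate_lwi <- function(data, k = 5, seed, engine = "log10") {
  check_cohort(data, min_rows = 4L)
  n <- nrow(data)
  k <- check_count(k, "k", min = 2L)
  if (k > n) abort(sprintf("`k` must be <= the cohort size (%d).", n))
  seed <- check_seed(seed)

  fold_id <- withr::with_seed(seed, sample(rep_len(seq_len(k), n)))
  rows <- lapply(seq_len(k), function(f) {
    test <- data[fold_id == f, , drop = FALSE]
    train <- data[fold_id != f, , drop = FALSE]
    fit <- fit_lwi(train, engine = engine)
    metrics <- evaluate_lwi(fit, test)
    tibble(
      fold = f, n_train = nrow(train), n_test = nrow(test),
      rmse_log10 = metrics$rmse_log10, mae_log10 = metrics$mae_log10
    )
  })
  folds <- dplyr::bind_rows(rows)
  structure(
    list(
      folds = folds,
      summary = tibble(
        k = k,
        mean_rmse_log10 = mean(folds$rmse_log10),
        mean_mae_log10 = mean(folds$mae_log10)
      )
    ),
    class = "lwi_cv"
  )
}

#' @export
print.lwi_cv <- function(x, ...) {
  cat("<lwi_cv> ", x$summary$k, "-fold cross-validation\n", sep = "")
  cat(sprintf("  mean RMSE(log10) = %.4g, mean MAE(log10) = %.4g\n",
              x$summary$mean_rmse_log10, x$summary$mean_mae_log10))
  invisible(x)
}

#' @describeIn cross_validate_lwi Per-fold metrics.
#' @param x An `lwi_cv`.
#' @param ... Unused.
#' @export
tidy.lwi_cv <- function(x, ...) x$folds

#' @describeIn cross_validate_lwi Fold means.
#' @export
glance.lwi_cv <- function(x, ...) x$summary
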