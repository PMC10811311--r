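test_that("noiseless cohorts recover the generating parameters exactly", {
  truth <- lwi_model(26.26, -0.011)
  cohort <- simulate_cohort(n = 60, model = truth, sigma_log10 = 0, seed = 8)
  # lm warns that a perfect fit makes its summary unreliable; expected here
  fit <- suppressWarnings(fit_lwi(cohort))
  expect_equal(fit$model$a, 26.26, tolerance = 1e-6)
  expect_equal(fit$model$b, -0.011, tolerance = 1e-9)
  expect_lt(fit$rmse_log10, 1e-12)

  nls_fit <- fit_lwi(cohort, engine = "nls")
  expect_equal(nls_fit$model$a, 26.26, tolerance = 1e-5)
  expect_equal(nls_fit$model$b, -0.011, tolerance = 1e-7)
})

test_that("three points on a curve are interpolated with zero residual", {
  cohort <- on_curve_cohort(c(18, 30, 47), lwi_model(20, -0.008))
  fit <- suppressWarnings(fit_lwi(cohort)) # perfect-fit warning expected
  expect_lt(fit$rmse_log10, 1e-12)
  expect_lt(fit$mae_log10, 1e-12)
})

test_that("degenerate fitting inputs are rejected", {
  cohort <- simulate_cohort(n = 20, seed = 1)
  expect_error(fit_lwi(cohort[1:2, ]), "at least 3")
  bad <- cohort
  bad$lung_weight_g[3] <- -1
  expect_error(fit_lwi(bad), "positive")
  flat <- on_curve_cohort(rep(25, 5), pig_reference_model())
  expect_error(fit_lwi(flat), "variance")
})

test_that("predictions reproduce the published worked values", {
  m <- pig_reference_model()
  expect_equal(predict_lwi(m, 20), 15.82, tolerance = 0.005 / 15.82)
  expect_equal(predict_lwi(m, 40), 9.53, tolerance = 0.005 / 9.53)
  expect_equal(predict_lung_weight(m, 20), 316, tolerance = 1 / 316)
  expect_equal(predict_lung_weight(m, 40), 381, tolerance = 1 / 381)
  flat <- lwi_model(12, 0)
  expect_equal(predict_lung_weight(flat, 33.3), 12 * 33.3)
  expect_error(predict_lwi(m, 0), "body_weight_kg")
  expect_error(predict_lwi(m, -5), "body_weight_kg")
})

test_that("predicted index is strictly decreasing in body weight when b < 0", {
  grid <- seq(16, 52, by = 0.25)
  for (b in c(-0.005, -0.011, -0.02)) {
    pred <- predict_lwi(lwi_model(26, b), grid)
    expect_true(all(diff(pred) < 0))
  }
})

test_that("scaling lung weights scales a and leaves b unchanged", {
  cohort <- simulate_cohort(n = 50, seed = 13)
  fit <- fit_lwi(cohort)
  scaled <- cohort
  scaled$lung_weight_g <- scaled$lung_weight_g * 3
  fit_s <- fit_lwi(scaled)
  expect_equal(fit_s$model$a, 3 * fit$model$a, tolerance = 1e-10)
  expect_equal(fit_s$model$b, fit$model$b, tolerance = 1e-12)
})

test_that("closed-form fit agrees with a brute-force grid search", {
  cohort <- simulate_cohort(n = 20, sigma_log10 = 0.05, seed = 17)
  fit <- fit_lwi(cohort)
  bw <- cohort$body_weight_kg
  log_lwi <- log10(cohort$lung_weight_g / cohort$body_weight_kg)
  grid <- grid_fit_log10(bw, log_lwi,
                         center_loga = log10(fit$model$a),
                         center_b = fit$model$b)
  step_loga <- 2 * 0.01 / 80
  step_b <- 2 * 5e-4 / 80
  expect_lt(abs(grid$loga - log10(fit$model$a)), step_loga)
  expect_lt(abs(grid$b - fit$model$b), step_b)
  # the closed form can only do better than any grid point
  sse_closed <- sum((log_lwi - log10(fit$model$a) - fit$model$b * bw)^2)
  expect_lte(sse_closed, grid$sse + 1e-12)
})

test_that("confidence band brackets the point model across the weight range", {
  cohort <- simulate_cohort(n = 141, seed = 19)
  fit <- fit_lwi(cohort)
  grid <- seq(16, 52, by = 0.5)
  expect_true(all(predict_lwi(fit$band_lower, grid) <=
                    predict_lwi(fit$model, grid)))
  expect_true(all(predict_lwi(fit$model, grid) <=
                    predict_lwi(fit$band_upper, grid)))
  expect_true(all(predict_lwi(pig_reference_fit()$band_lower, grid) <=
                    predict_lwi(pig_reference_model(), grid)))
})

test_that("tidy and glance summarize the fit", {
  fit <- fit_lwi(simulate_cohort(n = 30, seed = 23))
  td <- tidy(fit)
  expect_identical(td$term, c("a", "b"))
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
  gl <- glance(fit)
  expect_identical(gl$n, 30L)
  expect_gte(gl$rmse_log10, gl$mae_log10 * 0)
})

test_that("cohort splits have the canonical sizes and are deterministic", {
  cohort <- simulate_cohort(n = 177, seed = 3)
  p80 <- split_cohort(cohort, 0.8, seed = 31)
  expect_identical(nrow(p80$train), 141L)
  expect_identical(nrow(p80$validation), 36L)
  p90 <- split_cohort(cohort, 0.9, seed = 31)
  expect_identical(nrow(p90$train), 159L)
  expect_identical(nrow(p90$validation), 18L)
  # disjoint, exhaustive, reproducible
  expect_identical(sort(c(p80$train$animal_id, p80$validation$animal_id)),
                   sort(cohort$animal_id))
  expect_identical(split_cohort(cohort, 0.8, seed = 31), p80)
  expect_error(split_cohort(cohort, 1.0, seed = 1), "train_fraction")
  expect_error(split_cohort(cohort, 0, seed = 1), "train_fraction")
  expect_error(split_cohort(cohort[1:1, ], 0.5, seed = 1), "non-empty")
})

test_that("evaluation reproduces hand-computable residual summaries", {
  m <- pig_reference_model()
  on_curve <- on_curve_cohort(c(20, 30, 40), m)
  metrics <- evaluate_lwi(m, on_curve)
  expect_equal(metrics$rmse_log10, 0, tolerance = 1e-12)
  expect_equal(metrics$mae_log10, 0, tolerance = 1e-12)

  # two animals with log10 residuals +0.1 and -0.1
  bw <- c(20, 35)
  pert <- tibble::tibble(
    animal_id = c("p1", "p2"),
    body_weight_kg = bw,
    lung_weight_g = predict_lwi(m, bw) * 10^c(0.1, -0.1) * bw,
    method = "CT"
  )
  metrics <- evaluate_lwi(m, pert)
  expect_equal(metrics$rmse_log10, 0.1)
  expect_equal(metrics$mae_log10, 0.1)
  expect_error(evaluate_lwi(m, pert[0, ]), "at least 1")
})

test_that("large-sample RMSE estimates the generating noise level", {
  cohort <- simulate_cohort(n = 8000, sigma_log10 = 0.068, seed = 29)
  metrics <- evaluate_lwi(pig_reference_model(), cohort)
  expect_equal(metrics$rmse_log10, 0.068, tolerance = 0.005 / 0.068)
})

test_that("cross-validation behaves on noiseless, boundary and noisy cohorts", {
  noiseless <- simulate_cohort(n = 40, sigma_log10 = 0, seed = 5)
  cv0 <- suppressWarnings(cross_validate_lwi(noiseless, k = 5, seed = 7))
  expect_true(all(tidy(cv0)$rmse_log10 < 1e-12))

  loo <- cross_validate_lwi(simulate_cohort(n = 20, seed = 6), k = 20, seed = 8)
  expect_identical(nrow(tidy(loo)), 20L)
  expect_true(all(tidy(loo)$n_test == 1L))

  cohort <- simulate_cohort(n = 141, sigma_log10 = 0.068, seed = 9)
  cv <- cross_validate_lwi(cohort, k = 5, seed = 10)
  train_rmse <- fit_lwi(cohort)$rmse_log10
  expect_equal(glance(cv)$mean_rmse_log10, train_rmse, tolerance = 0.01 / train_rmse)
  expect_error(cross_validate_lwi(cohort, k = 1, seed = 1), "k")
  expect_error(cross_validate_lwi(cohort, k = 200, seed = 1), "k")
})
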