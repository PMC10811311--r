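#' Simulate a synthetic pig cohort
#'
#' Generates a cohort of healthy-pig records with the statistical structure
#' the reference-equation analysis assumes: body weights uniform on
#' `bw_range`, and lung weight index following the exponential model with
#' multiplicative noise, i.e.
#' `log10(LWI_i) = log10(a) + b * BW_i + eps_i`, `eps_i ~ N(0, sigma_log10)`.
#' Lung weight is `LWI_i * BW_i`. Noise is multiplicative (normal on the
#' log10 scale) so generated lung weights are always positive and the
#' residual dispersion is directly comparable to the log10-scale RMSE the
#' model fit reports; the default `sigma_log10 = 0.068` matches the
#' training-cohort residual dispersion of the published reference fit.
#'
#' @param n Number of animals, >= 2.
#' @param bw_range Length-2 numeric, body-weight bounds in kg (low < high).
#'   Defaults to the 16.5-52 kg range over which the reference equation was
#'   derived.
#' @param model Generating `lwi_model`; defaults to [pig_reference_model()].
#' @param sigma_log10 Residual SD on the log10(LWI) scale, >= 0.
#' @param seed Integer seed; required. The generator never touches the
#'   global random state outside this call.
#' @param method Label(s) for the lung-weighing method, recycled to `n`;
#'   carried through unchanged (`"CT"` or `"scale"`).
#' @return A tibble with columns `animal_id`, `body_weight_kg`,
#'   `lung_weight_g`, `method`.
#' @examples
#' cohort <- simulate_cohort(n = 177, seed = 42)
#' head(cohort)
#' @export
simulate_cohort <- function(n,
                            bw_range = c(16.5, 52),
                            model = pig_reference_model(),
                            sigma_log10 = 0.068,
                            seed,
                            method = "CT") {
  n <- check_count(n, "n", min = 2L)
  if (!is.numeric(bw_range) || length(bw_range) != 2L || anyNA(bw_range)) {
    abort("`bw_range` must be a length-2 numeric vector.")
  }
  if (bw_range[1] <= 0 || bw_range[1] >= bw_range[2]) {
    abort("`bw_range` must satisfy 0 < low < high.")
  }
  model <- resolve_model(model)
  check_number(sigma_log10, "sigma_log10")
  if (sigma_log10 < 0) abort("`sigma_log10` must be >= 0.")
  seed <- check_seed(seed)
  if (!all(method %in% c("CT", "scale"))) {
    abort('`method` must be "CT" or "scale".')
  }

  withr::with_seed(seed, {
    bw <- runif(n, bw_range[1], bw_range[2])
    eps <- rnorm(n, mean = 0, sd = sigma_log10)
  })
  lwi <- 10^(log10(model$a) + model$b * bw + eps)
  stopifnot(all(lwi > 0)) # log-scale noise guarantees positivity
  tibble(
    animal_id = sprintf("pig%04d", seq_len(n)),
    body_weight_kg = bw,
    lung_weight_g = lwi * bw,
    method = rep_len(method, n)
  )
}

#' Simulate paired measured vs expected lung weight indices
#'
#' Draws body weights as in [simulate_cohort()] and returns, per animal, the
#' noiseless model prediction ("expected") and a noisy realization
#' ("measured"), the input shape a Bland-Altman agreement analysis takes.
#'
#' @inheritParams simulate_cohort
#' @return A tibble with columns `body_weight_kg`, `expected_lwi_g_per_kg`,
#'   `measured_lwi_g_per_kg`.
#' @examples
#' pairs <- simulate_paired_lwi(n = 36, seed = 7)
#' bland_altman(pairs, measured_lwi_g_per_kg, expected_lwi_g_per_kg)
#' @export
simulate_paired_lwi <- function(n,
                                model = pig_reference_model(),
                                bw_range = c(16.5, 52),
                                sigma_log10 = 0.068,
                                seed) {
  cohort <- simulate_cohort(
    n = n, bw_range = bw_range, model = model,
    sigma_log10 = sigma_log10, seed = seed
  )
  model <- resolve_model(model)
  tibble(
    body_weight_kg = cohort$body_weight_kg,
    expected_lwi_g_per_kg = predict_lwi(model, cohort$body_weight_kg),
    measured_lwi_g_per_kg = cohort$lung_weight_g / cohort$body_weight_kg
  )
}
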