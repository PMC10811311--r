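#' Exponential lung weight index model
#'
#' Constructs the two-parameter exponential model
#' \deqn{LWI(BW) = a \cdot 10^{b \cdot BW}}
#' where `LWI` is the lung weight index in g/kg and `BW` the body weight in
#' kg. `a` (g/kg) is the index extrapolated to zero body weight and `b`
#' (1/kg) is the base-10 exponent coefficient; a negative `b` encodes the
#' allometric decline of relative lung size with growing body mass.
#'
#' @param a Prefactor in g/kg; must be > 0.
#' @param b Exponent coefficient in 1/kg (base-10 exponent per kg).
#' @return An object of class `lwi_model`.
#' @examples
#' m <- lwi_model(26.26, -0.011)
#' predict_lwi(m, c(20, 40))
#' @export
lwi_model <- function(a, b) {
  check_number(a, "a", positive = TRUE)
  check_number(b, "b")
  structure(list(a = a, b = b), class = "lwi_model")
}

#' @export
format.lwi_model <- function(x, ...) {
  sprintf("LWI (g/kg) = %.4g * 10^(%.4g * BW)", x$a, x$b)
}

#' @export
print.lwi_model <- function(x, ...) {
  cat("<lwi_model> ", format(x), "\n", sep = "")
  invisible(x)
}

#' Published reference model for female domestic pigs
#'
#' The reference equation for normal lung weight index in healthy female
#' domestic pigs (White Landrace, 16-50 kg),
#' `LWI = 26.26 * 10^(-0.011 * BW)`, derived from a 141-animal training
#' cohort. `pig_reference_fit()` additionally carries the published
#' parameter-wise 95% confidence band curves
#' (upper `28.84 * 10^(-0.009 * BW)`, lower `23.44 * 10^(-0.013 * BW)`),
#' packaged as an [fit_lwi()]-compatible object so it can be used directly
#' with [error_bounds_curve()] and [predict_lwi()]. Residual summaries are
#' `NA` in the published fit because the underlying cohort is not
#' redistributed.
#'
#' @return `pig_reference_model()`: an `lwi_model`.
#'   `pig_reference_fit()`: an `lwi_fit`.
#' @examples
#' predict_lung_weight(pig_reference_model(), c(20, 40))
#' @export
pig_reference_model <- function() {
  lwi_model(26.26, -0.011)
}

#' @rdname pig_reference_model
#' @export
pig_reference_fit <- function() {
  new_lwi_fit(
    model = pig_reference_model(),
    a_ci = c(23.44, 28.84),
    b_ci = c(-0.013, -0.009),
    band_upper = lwi_model(28.84, -0.009),
    band_lower = lwi_model(23.44, -0.013),
    rmse_log10 = NA_real_,
    mae_log10 = NA_real_,
    n = 141L,
    residuals = NULL,
    engine = "published",
    data = NULL,
    bw_range = c(16.5, 52)
  )
}

resolve_model <- function(model) {
  if (inherits(model, "lwi_fit")) {
    return(model$model)
  }
  if (!inherits(model, "lwi_model")) {
    abort("`model` must be an <lwi_model> or <lwi_fit> object.")
  }
  model
}

#' Predict lung weight index and lung weight
#'
#' `predict_lwi()` evaluates the exponential model at the given body
#' weights; `predict_lung_weight()` multiplies the index by body weight to
#' return the expected absolute lung weight in grams.
#'
#' @param model An `lwi_model` or fitted `lwi_fit` (its point model is used).
#' @param body_weight_kg Numeric vector of body weights in kg, all > 0.
#' @return Numeric vector: g/kg for `predict_lwi()`, g for
#'   `predict_lung_weight()`.
#' @examples
#' predict_lwi(pig_reference_model(), 20)          # ~15.8 g/kg
#' predict_lung_weight(pig_reference_model(), 20)  # ~316 g
#' @export
predict_lwi <- function(model, body_weight_kg) {
  model <- resolve_model(model)
  check_positive_vector(body_weight_kg, "body_weight_kg")
  model$a * 10^(model$b * body_weight_kg)
}

#' @rdname predict_lwi
#' @export
predict_lung_weight <- function(model, body_weight_kg) {
  predict_lwi(model, body_weight_kg) * body_weight_kg
}
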