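#' Damage ratio: measured over expected lung weight
#'
#' Normalizing a measured (edematous) lung weight by the animal's expected
#' normal lung weight — rather than by its body weight — yields a damage
#' measure that is comparable across animals of different size: the same
#' injury gives the same ratio regardless of body weight.
#'
#' @param measured_g Measured lung weight, g (> 0). Vectorized.
#' @param expected_g Expected normal lung weight, g (> 0).
#' @return Unitless ratio `measured_g / expected_g`.
#' @examples
#' damage_ratio(632, 316)  # a doubled 20-kg lung
#' @export
damage_ratio <- function(measured_g, expected_g) {
  check_positive_vector(measured_g, "measured_g")
  check_positive_vector(expected_g, "expected_g")
  measured_g / expected_g
}

#' Apparent excess damage under naive body-weight normalization
#'
#' Two animals suffering the identical relative injury (`damage_factor`
#' times their normal lung weight) show different lung weight indices when
#' the damaged weight is divided by body weight, because the normal index
#' itself falls with body weight. This function computes the two damaged
#' indices from the reference model and returns
#' `(index_1 - index_2) / index_1` — the spurious excess damage attributed
#' to animal 1. The result is algebraically independent of `damage_factor`
#' (it cancels), and is zero under expected-lung-weight normalization.
#'
#' @param bw1_kg,bw2_kg Body weights of the two animals, kg (> 0).
#' @param damage_factor Common multiplicative injury, > 0 (default 2,
#'   a doubling of lung weight).
#' @param model Reference `lwi_model` or `lwi_fit`.
#' @return Signed fraction; positive when the lighter-indexed animal 2 is
#'   made to look less injured than animal 1.
#' @examples
#' naive_normalization_discrepancy(20, 40)  # ~0.40
#' @export
naive_normalization_discrepancy <- function(bw1_kg, bw2_kg, damage_factor = 2,
                                            model = pig_reference_model()) {
  check_number(bw1_kg, "bw1_kg", positive = TRUE)
  check_number(bw2_kg, "bw2_kg", positive = TRUE)
  check_number(damage_factor, "damage_factor", positive = TRUE)
  model <- resolve_model(model)
  idx1 <- damage_factor * predict_lung_weight(model, bw1_kg) / bw1_kg
  idx2 <- damage_factor * predict_lung_weight(model, bw2_kg) / bw2_kg
  (idx1 - idx2) / idx1
}

#' Error in estimated damage from an erroneous expected lung weight
#'
#' If the true injury multiplies the normal lung weight by `true_ratio` but
#' the damage is quantified against `expected_used_g` (e.g. a confidence
#' band curve instead of the true normal weight), the estimated ratio is
#' `measured_g / expected_used_g` and the relative error is
#' `((measured_g / expected_used_g) - true_ratio) / true_ratio`.
#' Negative values mean the damage is underestimated (the expected weight
#' used was too large). The error is invariant to rescaling `measured_g`
#' and `expected_used_g` by a common factor.
#'
#' @param measured_g Measured (damaged) lung weight, g (> 0). Vectorized.
#' @param expected_used_g Expected normal lung weight actually used for
#'   normalization, g (> 0).
#' @param true_ratio True damage ratio, > 0.
#' @return Signed fraction.
#' @examples
#' damage_estimation_error(624, 373, 2)  # ~ -0.16 (underestimation)
#' @export
damage_estimation_error <- function(measured_g, expected_used_g, true_ratio) {
  check_positive_vector(measured_g, "measured_g")
  check_positive_vector(expected_used_g, "expected_used_g")
  check_positive_vector(true_ratio, "true_ratio")
  (measured_g / expected_used_g - true_ratio) / true_ratio
}

#' Maximal damage-quantification error along the confidence band
#'
#' For each body weight on the grid, takes the true damaged lung weight to
#' be `damage_factor` times the point-model prediction and evaluates
#' [damage_estimation_error()] with the upper and lower confidence band
#' curves as the expected weight: the upper band (expected weight too
#' large) gives the maximal underestimation, the lower band the maximal
#' overestimation. Errors are evaluated at the band endpoint curves only,
#' not optimized over the joint parameter confidence region, and their
#' magnitudes are independent of `damage_factor`.
#'
#' @param fit An `lwi_fit` carrying `band_upper`/`band_lower` (e.g.
#'   [fit_lwi()] output or [pig_reference_fit()]).
#' @param bw_grid_kg Body-weight grid, kg. A warning is issued for values
#'   outside 16-52 kg, the validity range of the reference equation; values
#'   are still computed.
#' @param damage_factor True injury multiple, > 0.
#' @return Tibble with columns `bw_kg`, `max_under_frac`,
#'   `max_over_frac` (both magnitudes, >= 0 whenever the band brackets the
#'   point model).
#' @examples
#' error_bounds_curve(pig_reference_fit(), c(20, 40))
#' @export
error_bounds_curve <- function(fit, bw_grid_kg = seq(16, 45, by = 0.5),
                               damage_factor = 2) {
  if (!inherits(fit, "lwi_fit")) {
    abort("`fit` must be an <lwi_fit> with confidence band models.")
  }
  check_positive_vector(bw_grid_kg, "bw_grid_kg")
  check_number(damage_factor, "damage_factor", positive = TRUE)
  if (any(bw_grid_kg < 16 | bw_grid_kg > 52)) {
    warn("Body weights outside 16-52 kg are beyond the reference equation's validity range.")
  }
  true_weight <- damage_factor * predict_lung_weight(fit$model, bw_grid_kg)
  under <- damage_estimation_error(
    true_weight, predict_lung_weight(fit$band_upper, bw_grid_kg), damage_factor
  )
  over <- damage_estimation_error(
    true_weight, predict_lung_weight(fit$band_lower, bw_grid_kg), damage_factor
  )
  tibble(
    bw_kg = bw_grid_kg,
    max_under_frac = abs(under),
    max_over_frac = abs(over)
  )
}

#' Plot maximal normalization errors across body weight
#'
#' @param bounds Output of [error_bounds_curve()].
#' @return A ggplot.
#' @export
plot_error_bounds <- function(bounds) {
  if (!is.data.frame(bounds) ||
      !all(c("bw_kg", "max_under_frac", "max_over_frac") %in% names(bounds))) {
    abort("`bounds` must be the output of error_bounds_curve().")
  }
  long <- tibble(
    bw_kg = rep(bounds$bw_kg, 2),
    error = c(bounds$max_under_frac, bounds$max_over_frac),
    direction = rep(c("underestimation", "overestimation"),
                    each = nrow(bounds))
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$bw_kg, y = .data$error,
                                     colour = .data$direction)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Body weight (kg)", y = "Maximal fractional error",
                  colour = NULL)
}
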