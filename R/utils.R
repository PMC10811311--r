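# internal argument checks; all user-facing errors go through these so the
# offending argument is always named

check_number <- function(x, name, positive = FALSE, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single number.", name))
  }
  if (finite && !is.finite(x)) {
    abort(sprintf("`%s` must be finite.", name))
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be > 0 (got %g).", name, x))
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != as.integer(x)) {
    abort(sprintf("`%s` must be a single whole number.", name))
  }
  if (x < min) {
    abort(sprintf("`%s` must be >= %d (got %d).", name, min, as.integer(x)))
  }
  invisible(as.integer(x))
}

check_seed <- function(seed) {
  if (missing(seed) || is.null(seed)) {
    abort("`seed` is required: all stochastic functions take an explicit seed.")
  }
  check_number(seed, "seed")
  invisible(as.integer(seed))
}

check_positive_vector <- function(x, name) {
  if (!is.numeric(x) || length(x) == 0L) {
    abort(sprintf("`%s` must be a non-empty numeric vector.", name))
  }
  if (anyNA(x) || any(!is.finite(x))) {
    abort(sprintf("`%s` contains missing or non-finite values.", name))
  }
  if (any(x <= 0)) {
    abort(sprintf("`%s` must be strictly positive.", name))
  }
  invisible(x)
}

# cohort tibbles use this fixed schema throughout the package
cohort_columns <- c("animal_id", "body_weight_kg", "lung_weight_g", "method")

check_cohort <- function(data, min_rows = 1L, name = "data") {
  if (!is.data.frame(data)) {
    abort(sprintf("`%s` must be a data frame of pig records.", name))
  }
  missing_cols <- setdiff(c("body_weight_kg", "lung_weight_g"), names(data))
  if (length(missing_cols) > 0) {
    abort(sprintf(
      "`%s` is missing required column(s): %s.",
      name, paste(missing_cols, collapse = ", ")
    ))
  }
  if (nrow(data) < min_rows) {
    abort(sprintf("`%s` must have at least %d rows (got %d).", name, min_rows, nrow(data)))
  }
  check_positive_vector(data$body_weight_kg, paste0(name, "$body_weight_kg"))
  check_positive_vector(data$lung_weight_g, paste0(name, "$lung_weight_g"))
  invisible(data)
}
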