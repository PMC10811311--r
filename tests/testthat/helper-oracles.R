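# Independent oracles used across test files. These deliberately avoid the
# package's vectorized code paths.

# per-voxel loop computation of lung weight (g): the brute-force counterpart
# of lung_weight_ct()
loop_lung_weight <- function(hu, mask, voxel_volume_mm3) {
  total <- 0
  hu <- as.vector(hu)
  mask <- as.vector(mask)
  for (i in seq_along(hu)) {
    if (mask[i]) {
      f <- 1 - hu[i] / (-1000)
      if (f < 0) f <- 0
      if (f > 2) f <- 2
      total <- total + f * voxel_volume_mm3 / 1000
    }
  }
  total
}

# brute-force 2-D grid search minimizing squared log10 error; returns the
# best (log10 a, b) pair on the grid
grid_fit_log10 <- function(bw, log_lwi, center_loga, center_b,
                           span_loga = 0.01, span_b = 5e-4, steps = 81) {
  loga_grid <- seq(center_loga - span_loga, center_loga + span_loga,
                   length.out = steps)
  b_grid <- seq(center_b - span_b, center_b + span_b, length.out = steps)
  best <- c(NA, NA)
  best_sse <- Inf
  for (la in loga_grid) {
    for (b in b_grid) {
      sse <- sum((log_lwi - la - b * bw)^2)
      if (sse < best_sse) {
        best_sse <- sse
        best <- c(la, b)
      }
    }
  }
  list(loga = best[1], b = best[2], sse = best_sse)
}

# a cohort tibble lying exactly on a given model curve
on_curve_cohort <- function(bw, model) {
  lwi <- model$a * 10^(model$b * bw)
  tibble::tibble(
    animal_id = sprintf("pig%04d", seq_along(bw)),
    body_weight_kg = bw,
    lung_weight_g = lwi * bw,
    method = "CT"
  )
}
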