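test_that("tissue fraction follows the linear air-tissue mixture with clamping", {
  cases <- list(
    list(hu = -1000, frac = 0),    # pure gas
    list(hu = 0, frac = 1),        # water-equivalent tissue
    list(hu = -500, frac = 0.5),   # linear midpoint
    list(hu = 1000, frac = 2),     # bone endpoint
    list(hu = -1500, frac = 0),    # clamped below
    list(hu = 1500, frac = 2)      # clamped above
  )
  for (case in cases) {
    expect_equal(tissue_fraction(case$hu), case$frac)
  }
  expect_error(tissue_fraction(NaN), "finite")
  expect_error(tissue_fraction(c(0, Inf)), "finite")
})

test_that("lung weight of uniform volumes matches hand arithmetic", {
  hu0 <- array(0, dim = c(10, 10, 10))
  m <- lung_weight_ct(hu0, voxel_volume_mm3 = 1.8)
  expect_equal(m$lung_weight_g, 1.8)    # 1000 voxels, fraction 1, 0.0018 g each
  expect_equal(m$lung_tissue_volume_ml, 1.8)
  expect_equal(m$lung_gas_volume_ml, 0)
  expect_identical(m$n_voxels, 1000L)

  air <- array(-1000, dim = c(5, 5, 5))
  expect_equal(lung_weight_ct(air, voxel_volume_mm3 = 1.8)$lung_weight_g, 0)
})

test_that("shape mismatch errors and empty masks warn with all-zero output", {
  hu <- array(0, dim = c(4, 4, 4))
  expect_error(lung_weight_ct(hu, mask = array(TRUE, dim = c(4, 4, 2))),
               "dimensions")
  expect_warning(
    m <- lung_weight_ct(hu, mask = array(FALSE, dim = c(4, 4, 4))),
    "Empty"
  )
  expect_equal(m$lung_weight_g, 0)
  expect_identical(m$n_voxels, 0L)
})

test_that("vectorized lung weight equals the per-voxel loop oracle", {
  set.seed(42)
  for (rep in 1:5) {
    hu <- array(runif(6 * 5 * 4, -1200, 1200), dim = c(6, 5, 4))
    mask <- array(runif(6 * 5 * 4) < 0.6, dim = c(6, 5, 4))
    vv <- runif(1, 0.5, 3)
    got <- suppressMessages(lung_weight_ct(hu, mask, vv))
    expect_equal(got$lung_weight_g, loop_lung_weight(hu, mask, vv),
                 tolerance = 1e-9)
  }
})

test_that("phantoms reproduce their analytic weight across random draws", {
  set.seed(7)
  for (rep in 1:50) {
    gf <- runif(1, 0.05, 0.95)
    vv <- runif(1, 0.5, 3)
    jit <- runif(1, 0, 20)
    ph <- make_phantom(c(8, 8, 8), gas_fraction = gf, voxel_volume_mm3 = vv,
                       jitter_sd = jit, seed = rep)
    m <- lung_weight_ct(ph$hu, ph$mask, ph$voxel_volume_mm3)
    expect_equal(m$lung_weight_g, ph$analytic_weight_g, tolerance = 1e-9)
  }
  expect_error(make_phantom(c(4, 4, 4), gas_fraction = 1.2), "gas_fraction")
  expect_equal(make_phantom(c(4, 4, 4), gas_fraction = 1)$analytic_weight_g, 0)
})

test_that("lung weight is additive over disjoint masks", {
  set.seed(3)
  hu <- array(runif(500, -1000, 200), dim = c(10, 10, 5))
  all_mask <- array(TRUE, dim = dim(hu))
  split <- array(runif(500) < 0.5, dim = dim(hu))
  w_all <- lung_weight_ct(hu, all_mask, 1.8)$lung_weight_g
  w_a <- lung_weight_ct(hu, split, 1.8)$lung_weight_g
  w_b <- lung_weight_ct(hu, all_mask & !split, 1.8)$lung_weight_g
  expect_equal(w_all, w_a + w_b, tolerance = 1e-12)
})

test_that("raising a voxel's HU never decreases the weight; doubling voxel volume doubles it", {
  set.seed(4)
  hu <- array(runif(64, -1000, 900), dim = c(4, 4, 4))
  w0 <- lung_weight_ct(hu, voxel_volume_mm3 = 1.8)$lung_weight_g
  hu2 <- hu
  hu2[2, 3, 1] <- min(hu2[2, 3, 1] + 100, 1000)
  expect_gte(lung_weight_ct(hu2, voxel_volume_mm3 = 1.8)$lung_weight_g, w0)
  expect_equal(lung_weight_ct(hu, voxel_volume_mm3 = 3.6)$lung_weight_g, 2 * w0)
})

test_that("lung weight index is weight over body weight with validated inputs", {
  expect_equal(lung_weight_index(316, 20), 15.8)
  expect_equal(lung_weight_index(381, 40), 9.525)
  expect_equal(lung_weight_index(0, 30), 0)
  expect_error(lung_weight_index(316, 0), "body_weight_kg")
  expect_error(lung_weight_index(-10, 20), "lung_weight_g")
})

test_that("NIfTI volumes round-trip through read_ct_volume", {
  hu <- array(round(runif(4 * 4 * 3, -1000, 100)), dim = c(4, 4, 3))
  mask <- array(runif(4 * 4 * 3) < 0.7, dim = c(4, 4, 3))
  hu_path <- tempfile(fileext = ".nii.gz")
  mask_path <- tempfile(fileext = ".nii.gz")
  img <- RNifti::asNifti(hu)
  RNifti::pixdim(img) <- c(1.2, 1.2, 1.25)
  RNifti::writeNifti(img, hu_path)
  RNifti::writeNifti(RNifti::asNifti(mask * 1, reference = img), mask_path)

  vol <- read_ct_volume(hu_path, mask_path)
  expect_equal(vol$hu, hu, ignore_attr = TRUE)
  expect_equal(vol$mask, mask, ignore_attr = TRUE)
  expect_equal(vol$voxel_volume_mm3, 1.2 * 1.2 * 1.25, tolerance = 1e-6)
  expect_equal(
    lung_weight_ct(vol$hu, vol$mask, vol$voxel_volume_mm3)$lung_weight_g,
    lung_weight_ct(hu, mask, vol$voxel_volume_mm3)$lung_weight_g
  )
  # explicit override wins over the header
  vol2 <- read_ct_volume(hu_path, mask_path, voxel_volume_mm3 = 1.8)
  expect_equal(vol2$voxel_volume_mm3, 1.8)
})
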