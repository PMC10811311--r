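#' Tissue fraction of a CT voxel
#'
#' Linear air-tissue mixture model on the Hounsfield scale: a voxel at
#' -1000 HU is pure gas (fraction 0), 0 HU is water-equivalent lung tissue
#' (fraction 1), +1000 HU is bone (fraction 2). The fraction is
#' `1 - hu / -1000`, clamped to `[0, 2]`: values below -1000 HU are treated
#' as pure gas and values above +1000 HU as the bone endpoint.
#'
#' @param hu Numeric vector/array of CT numbers in Hounsfield units; must be
#'   finite.
#' @return Unitless tissue fraction(s), same shape as `hu`.
#' @examples
#' tissue_fraction(c(-1000, -500, 0))
#' @export
tissue_fraction <- function(hu) {
  if (!is.numeric(hu) || length(hu) == 0L) {
    abort("`hu` must be a non-empty numeric vector or array.")
  }
  if (anyNA(hu) || any(!is.finite(hu))) {
    abort("`hu` contains missing or non-finite values.")
  }
  pmin(pmax(1 - hu / (-1000), 0), 2)
}

#' Lung weight from a quantitative CT volume
#'
#' Sums `tissue_fraction(hu) * voxel volume` over the masked voxels, with
#' tissue density taken as 1 g/cm^3 so tissue volume in cm^3 equals tissue
#' weight in grams. The gas volume is the complementary gas fraction
#' (`clamp(-hu/1000, 0, 1)`) summed over the mask. Voxels outside
#' `[-1000, 1000]` HU are clamped to the air/bone endpoints; their count is
#' returned and reported via a message so unexpected scanner values are
#' visible.
#'
#' @param hu 3-D numeric array of Hounsfield units (a matrix or vector also
#'   works; only the mask geometry must match).
#' @param mask Logical array of the same shape, `TRUE` for lung parenchyma
#'   voxels. The mask is the caller's contract: exclusion of airways,
#'   vessels and bone is segmentation, out of scope here. `NULL` masks every
#'   voxel.
#' @param voxel_volume_mm3 Volume per voxel in mm^3 (> 0); 1.8 mm^3 is the
#'   acquisition this formula was validated with.
#' @return One-row tibble: `lung_weight_g`, `lung_gas_volume_ml`,
#'   `lung_tissue_volume_ml`, `n_voxels`, `n_clamped`. An empty mask yields
#'   the all-zero measurement with a warning.
#' @examples
#' hu <- array(-500, dim = c(10, 10, 10))
#' lung_weight_ct(hu, voxel_volume_mm3 = 1.8)
#' @export
lung_weight_ct <- function(hu, mask = NULL, voxel_volume_mm3 = 1.8) {
  if (!is.numeric(hu)) abort("`hu` must be a numeric array.")
  check_number(voxel_volume_mm3, "voxel_volume_mm3", positive = TRUE)
  if (is.null(mask)) {
    mask <- rep(TRUE, length(hu))
  } else {
    if (!is.logical(mask)) abort("`mask` must be a logical array.")
    dh <- dim(hu) %||% length(hu)
    dm <- dim(mask) %||% length(mask)
    if (!identical(dh, dm)) {
      abort("`hu` and `mask` must have identical dimensions.")
    }
  }
  sel <- as.vector(hu)[as.vector(mask)]
  if (length(sel) == 0L) {
    warn("Empty lung mask: returning an all-zero measurement.")
    return(tibble(
      lung_weight_g = 0, lung_gas_volume_ml = 0, lung_tissue_volume_ml = 0,
      n_voxels = 0L, n_clamped = 0L
    ))
  }
  if (anyNA(sel) || any(!is.finite(sel))) {
    abort("`hu` contains missing or non-finite values inside the mask.")
  }
  n_clamped <- sum(sel < -1000 | sel > 1000)
  if (n_clamped > 0) {
    message(n_clamped, " masked voxel(s) outside [-1000, 1000] HU were clamped.")
  }
  vv_cm3 <- voxel_volume_mm3 / 1000
  tissue <- tissue_fraction(sel)
  gas <- pmin(pmax(-sel / 1000, 0), 1)
  tibble(
    lung_weight_g = sum(tissue) * vv_cm3,
    lung_gas_volume_ml = sum(gas) * vv_cm3,
    lung_tissue_volume_ml = sum(tissue) * vv_cm3,
    n_voxels = length(sel),
    n_clamped = as.integer(n_clamped)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Lung weight index
#'
#' @param lung_weight_g Lung weight in grams, >= 0.
#' @param body_weight_kg Body weight in kg, > 0.
#' @return Lung weight index in g/kg.
#' @examples
#' lung_weight_index(316, 20)
#' @export
lung_weight_index <- function(lung_weight_g, body_weight_kg) {
  if (!is.numeric(lung_weight_g) || anyNA(lung_weight_g) || any(lung_weight_g < 0)) {
    abort("`lung_weight_g` must be numeric and >= 0.")
  }
  check_positive_vector(body_weight_kg, "body_weight_kg")
  lung_weight_g / body_weight_kg
}

#' Synthetic CT phantom with known analytic lung weight
#'
#' Builds a fully masked HU volume whose voxels sit at
#' `-1000 * gas_fraction`, optionally with zero-mean jitter, so the analytic
#' lung weight is `(1 - gas_fraction) * n_voxels * voxel_volume(cm^3)`
#' grams. The jitter is re-centred to mean zero after sampling so the
#' analytic weight stays exact whenever no voxel leaves `[-1000, 1000]` HU.
#'
#' @param dim Length-3 integer vector of array dimensions.
#' @param gas_fraction Mean gas fraction in `[0, 1]`.
#' @param voxel_volume_mm3 Voxel volume in mm^3.
#' @param jitter_sd SD of per-voxel HU jitter (0 = constant phantom).
#' @param seed Integer seed; required when `jitter_sd > 0`.
#' @return A list with `hu`, `mask`, `voxel_volume_mm3`,
#'   `analytic_weight_g`.
#' @examples
#' ph <- make_phantom(c(10, 10, 10), gas_fraction = 0.5)
#' lung_weight_ct(ph$hu, ph$mask, ph$voxel_volume_mm3)$lung_weight_g
#' ph$analytic_weight_g
#' @export
make_phantom <- function(dim = c(16, 16, 16), gas_fraction, voxel_volume_mm3 = 1.8,
                         jitter_sd = 0, seed = NULL) {
  if (!is.numeric(dim) || length(dim) != 3L || any(dim < 1)) {
    abort("`dim` must be three positive integers.")
  }
  check_number(gas_fraction, "gas_fraction")
  if (gas_fraction < 0 || gas_fraction > 1) {
    abort("`gas_fraction` must lie in [0, 1].")
  }
  check_number(voxel_volume_mm3, "voxel_volume_mm3", positive = TRUE)
  check_number(jitter_sd, "jitter_sd")
  if (jitter_sd < 0) abort("`jitter_sd` must be >= 0.")

  n <- prod(dim)
  hu <- rep(-1000 * gas_fraction, n)
  if (jitter_sd > 0) {
    seed <- check_seed(seed)
    eps <- withr::with_seed(seed, rnorm(n, 0, jitter_sd))
    eps <- eps - mean(eps)
    hu <- hu + eps
    if (any(hu < -1000 | hu > 1000)) {
      abort("`jitter_sd` too large: jittered HU values leave [-1000, 1000].")
    }
  }
  list(
    hu = array(hu, dim = dim),
    mask = array(TRUE, dim = dim),
    voxel_volume_mm3 = voxel_volume_mm3,
    analytic_weight_g = (1 - gas_fraction) * n * voxel_volume_mm3 / 1000
  )
}

#' Read a CT volume and lung mask from NIfTI files
#'
#' Thin wrapper around [RNifti::readNifti()]. The voxel volume defaults to
#' the product of the first three pixel dimensions of the HU image's header;
#' pass `voxel_volume_mm3` to override. Mask voxels are those with an
#' intensity above 0.5.
#'
#' @param hu_path Path to the Hounsfield-unit volume (`.nii`/`.nii.gz`).
#' @param mask_path Path to the binary lung mask, same geometry.
#' @param voxel_volume_mm3 Optional override of the header voxel volume.
#' @return A list with `hu`, `mask`, `voxel_volume_mm3`, ready for
#'   [lung_weight_ct()].
#' @export
read_ct_volume <- function(hu_path, mask_path, voxel_volume_mm3 = NULL) {
  img <- RNifti::readNifti(hu_path)
  mask_img <- RNifti::readNifti(mask_path)
  if (!identical(dim(img), dim(mask_img))) {
    abort("HU volume and mask have different dimensions.")
  }
  if (is.null(voxel_volume_mm3)) {
    voxel_volume_mm3 <- prod(RNifti::pixdim(img)[1:3])
  }
  check_number(voxel_volume_mm3, "voxel_volume_mm3", positive = TRUE)
  list(
    hu = array(as.numeric(img), dim = dim(img)),
    mask = array(as.numeric(mask_img) > 0.5, dim = dim(mask_img)),
    voxel_volume_mm3 = voxel_volume_mm3
  )
}
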