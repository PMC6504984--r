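#' Voxel volume in Hounsfield units
#'
#' A 3-D scalar grid with per-axis spacing and a corner origin, sharing
#' the package-wide mm frame (voxel `(i, j, k)`, zero-based, sampled at
#' `origin + (i + 1/2) * spacing`).
#'
#' @param values 3-D numeric array (HU).
#' @param spacing_mm length-3 positive spacing.
#' @param origin_mm length-3 corner origin.
#' @return an object of class `voxel_volume`.
#' @export
voxel_volume <- function(values, spacing_mm, origin_mm = c(0, 0, 0)) {
  if (length(dim(values)) != 3L)
    mf_stop("mf_invalid_volume", "values must be a 3-D array")
  spacing_mm <- rep_len(as.numeric(spacing_mm), 3L)
  if (any(spacing_mm <= 0))
    mf_stop("mf_invalid_volume", "spacing must be strictly positive")
  structure(list(values = values, spacing_mm = spacing_mm,
                 origin_mm = rep_len(as.numeric(origin_mm), 3L)),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<voxel_volume> %d x %d x %d voxels, spacing %.4g mm, HU [%.0f, %.0f]\n",
              d[1], d[2], d[3], x$spacing_mm[1], min(x$values), max(x$values)))
  invisible(x)
}

# HU display scale exposed by the segmentation software
HU_SCALE_MIN <- -1000
HU_SCALE_MAX <- 7000

#' Simulate a CBCT acquisition of a mesh
#'
#' Forward model: analytic partial-volume occupancy of each voxel
#' (exact along z, 4x supersampled in x/y), mapped to
#' `hu_air + occupancy * (hu_stone - hu_air)`, convolved with an
#' isotropic Gaussian point-spread function, plus i.i.d. Gaussian
#' noise, then affine HU calibration `v -> gain * v + offset`, finally
#' clamped to the software's displayed HU scale (-1000..7000). The grid
#' is padded at least `3 * psf_sigma_mm` (and two voxels) beyond the
#' mesh bounding box.
#'
#' @param mesh a watertight [tri_mesh()].
#' @param device a [device_model()].
#' @param seed integer seed for the noise realization.
#' @param supersample sub-rays per voxel edge for the occupancy model.
#' @return a [voxel_volume()] in the mesh's frame.
#' @export
voxelize <- function(mesh, device, seed = 0L, supersample = 4L) {
  if (!inherits(device, "device_model"))
    mf_stop("mf_invalid_spec", "device must be a device_model")
  if (!is_watertight(mesh))
    mf_stop("mf_open_mesh", "voxelize requires a watertight mesh")
  vx <- device$voxel_mm
  pad <- max(3 * device$psf_sigma_mm, 2 * vx)
  lo <- apply(mesh$vertices, 2, min) - pad
  hi <- apply(mesh$vertices, 2, max) + pad
  dims <- pmax(2L, as.integer(ceiling((hi - lo) / vx)))
  occ <- .voxelize_occupancy(mesh$vertices, mesh$faces, dims,
                             rep(vx, 3), lo, as.integer(supersample))
  hu <- device$hu_air + occ * (device$hu_stone - device$hu_air)
  if (device$psf_sigma_mm > 0)
    hu <- .gaussian_blur3(hu, dims, rep(device$psf_sigma_mm / vx, 3))
  if (device$noise_sd_hu > 0)
    hu <- hu + with_seed(seed, rnorm(length(hu), 0, device$noise_sd_hu))
  hu <- device$hu_gain * hu + device$hu_offset
  hu <- pmin(pmax(hu, HU_SCALE_MIN), HU_SCALE_MAX)
  voxel_volume(array(hu, dims), rep(vx, 3), lo)
}
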