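#' Phantom specification
#'
#' Parameters of the synthetic dental stone model: a gingiva base band
#' following a circular arch, carrying smooth tooth-like protrusions.
#' The phantom stands in for a physical gypsum cast: it is watertight
#' by construction and has high-curvature features so that segmentation
#' threshold errors are visible in the deviation statistics.
#'
#' Geometry defaults are sized for desk-scale runtime (a reduced arch
#' segment, not an anatomically scaled full arch); all lengths in mm.
#'
#' @param case_id label carried through the pipeline.
#' @param arch_kind `"maxilla"` or `"mandible"` (slightly different arch
#'   span; cosmetic).
#' @param n_teeth number of tooth bumps (>= 1).
#' @param arch_radius_mm radius of the arch centerline.
#' @param tooth_height_mm protrusion height of the teeth above the base.
#' @param gingiva_band_mm gingiva band retained after the default crop
#'   (target 3-5 mm).
#' @param rng_seed integer seed controlling per-case geometry jitter.
#' @param surface_resolution_mm sampling pitch of the implicit field
#'   from which the ground-truth surface is extracted.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(case_id = "case1",
                         arch_kind = c("maxilla", "mandible"),
                         n_teeth = 6L,
                         arch_radius_mm = 9,
                         tooth_height_mm = 4,
                         gingiva_band_mm = 4,
                         rng_seed = 1L,
                         surface_resolution_mm = 0.12) {
  arch_kind <- match.arg(arch_kind)
  if (n_teeth < 1L)
    mf_stop("mf_invalid_spec", "n_teeth must be >= 1")
  lengths <- c(arch_radius_mm, tooth_height_mm, gingiva_band_mm,
               surface_resolution_mm)
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    mf_stop("mf_invalid_spec", "all phantom lengths must be positive")
  structure(list(case_id = as.character(case_id), arch_kind = arch_kind,
                 n_teeth = as.integer(n_teeth),
                 arch_radius_mm = arch_radius_mm,
                 tooth_height_mm = tooth_height_mm,
                 gingiva_band_mm = gingiva_band_mm,
                 rng_seed = as.integer(rng_seed),
                 surface_resolution_mm = surface_resolution_mm),
            class = "phantom_spec")
}

# run expr with a local RNG state, restoring the caller's stream
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# implicit field of the phantom (positive inside), vectorized over points
phantom_field <- function(spec, x, y, z) {
  jit <- with_seed(spec$rng_seed, list(
    r = runif(spec$n_teeth, -0.15, 0.15),
    h = runif(spec$n_teeth, -0.15, 0.15),
    a = runif(spec$n_teeth, -0.04, 0.04)
  ))
  R <- spec$arch_radius_mm
  span <- if (spec$arch_kind == "maxilla") 100 else 110 # half-span, degrees
  span <- span * pi / 180
  w_base <- 2.5                       # base half-thickness
  z_top <- spec$gingiva_band_mm + 2   # top of the gingiva base

  # distance in xy to the arch centerline arc (angle from +y axis)
  theta <- atan2(x, y)
  th <- pmin(pmax(theta, -span), span)
  ax <- R * sin(th)
  ay <- R * cos(th)
  rho <- sqrt((x - ax)^2 + (y - ay)^2)
  dz <- pmax(0, z - z_top) + pmax(0, -z)
  f_base <- w_base - sqrt(rho^2 + dz^2)

  # tooth bumps: ellipsoidal protrusions centered on the base top
  tt <- seq(-span * 0.85, span * 0.85, length.out = spec$n_teeth) + jit$a
  pitch <- if (spec$n_teeth > 1) R * (tt[2] - tt[1]) else R * span
  r_t <- pmin(0.45 * pitch, 2.2) * (1 + jit$r)
  h_t <- spec$tooth_height_mm * (1 + jit$h)
  f <- f_base
  s <- 0.35 # smooth-union bandwidth (mm)
  for (t in seq_len(spec$n_teeth)) {
    cx <- R * sin(tt[t])
    cy <- R * cos(tt[t])
    nrm <- sqrt(((x - cx) / r_t[t])^2 + ((y - cy) / r_t[t])^2 +
                  ((z - z_top) / h_t[t])^2)
    f_tooth <- r_t[t] * (1 - nrm)
    # smooth union keeps the surface free of creases (watertight, C1)
    m <- pmax(f, f_tooth)
    f <- m + s * log(exp((f - m) / s) + exp((f_tooth - m) / s))
  }
  f
}

#' Generate the ground-truth stone-model surface
#'
#' Evaluates the phantom's implicit field on a fine grid and extracts
#' its zero level set with the same marching-tetrahedra kernel used for
#' CBCT segmentation. The result is closed and consistently oriented by
#' construction (the field is negative on the whole grid boundary);
#' identical `(spec, rng_seed)` pairs reproduce identical vertex arrays.
#'
#' @param spec a [phantom_spec()].
#' @return a watertight [tri_mesh()].
#' @export
generate_ground_truth <- function(spec) {
  if (!inherits(spec, "phantom_spec"))
    mf_stop("mf_invalid_spec", "spec must be a phantom_spec")
  res <- spec$surface_resolution_mm
  R <- spec$arch_radius_mm
  pad <- 1.2
  lo <- c(-(R + 3.5 + pad), -(0.35 * R + 3.5 + pad), -(2.5 + pad))
  hi <- c(R + 3.5 + pad, R + 3.5 + pad,
          spec$gingiva_band_mm + 2 + spec$tooth_height_mm + pad)
  dim <- pmax(2L, as.integer(ceiling((hi - lo) / res)) + 1L)
  xs <- lo[1] + (seq_len(dim[1]) - 0.5) * res
  ys <- lo[2] + (seq_len(dim[2]) - 0.5) * res
  zs <- lo[3] + (seq_len(dim[3]) - 0.5) * res
  g <- expand.grid(x = xs, y = ys, z = zs, KEEP.OUT.ATTRS = FALSE)
  f <- phantom_field(spec, g$x, g$y, g$z)
  out <- .mt_extract(f, dim, rep(res, 3), lo, 0)
  if (nrow(out$faces) == 0L)
    mf_stop("mf_invalid_spec", "degenerate phantom: empty surface")
  mesh <- tri_mesh(out$vertices, out$faces,
                   sprintf("ground-truth %s (%s)", spec$case_id, spec$arch_kind))
  mesh <- largest_component(mesh_clean(mesh))
  if (!is_watertight(mesh))
    mf_stop("mf_invalid_spec", "phantom surface is not watertight")
  mesh
}

#' CBCT device forward model
#'
#' A minimal acquisition model: partial-volume occupancy of the stone
#' against air, isotropic Gaussian point-spread blur, additive white
#' noise, and an affine HU calibration. Values are surrogates emulating
#' device differences, not measurements of any physical scanner.
#'
#' @param device_id label.
#' @param hu_air,hu_stone HU plateau values of background and gypsum.
#' @param psf_sigma_mm Gaussian point-spread sigma (mm).
#' @param noise_sd_hu white-noise standard deviation (HU).
#' @param hu_gain,hu_offset affine calibration `v -> gain * v + offset`.
#' @param voxel_mm isotropic voxel pitch (default 0.150 mm).
#' @return an object of class `device_model`.
#' @export
device_model <- function(device_id, hu_air = -800, hu_stone = 5050,
                         psf_sigma_mm = 0.1, noise_sd_hu = 0,
                         hu_gain = 1, hu_offset = 0, voxel_mm = 0.150) {
  if (hu_stone <= hu_air)
    mf_stop("mf_invalid_spec", "hu_stone must exceed hu_air")
  if (psf_sigma_mm < 0 || noise_sd_hu < 0 || voxel_mm <= 0)
    mf_stop("mf_invalid_spec", "invalid device parameters")
  structure(list(device_id = as.character(device_id), hu_air = hu_air,
                 hu_stone = hu_stone, psf_sigma_mm = psf_sigma_mm,
                 noise_sd_hu = noise_sd_hu, hu_gain = hu_gain,
                 hu_offset = hu_offset, voxel_mm = voxel_mm),
            class = "device_model")
}

#' Built-in device presets
#'
#' Three presets emulating the study design: one low-blur, low-noise
#' device (`NewtomVG`-like) and two identical higher-blur, higher-noise
#' devices (`Planmeca80`/`Planmeca90`-like) that differ only in their
#' noise realization. With `hu_air = -800` and `hu_stone = 5050` the
#' air/stone midpoint is 2125 HU, inside the default threshold sweep.
#'
#' @return named list of three [device_model()] objects.
#' @export
device_presets <- function() {
  list(
    Planmeca80 = device_model("Planmeca80", psf_sigma_mm = 0.18,
                              noise_sd_hu = 150),
    Planmeca90 = device_model("Planmeca90", psf_sigma_mm = 0.18,
                              noise_sd_hu = 150),
    NewtomVG   = device_model("NewtomVG", psf_sigma_mm = 0.08,
                              noise_sd_hu = 40)
  )
}
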