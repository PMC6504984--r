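#' Segmentation threshold sweep
#'
#' The default sweep replicates the bench protocol: window level from
#' 1425 to 2625 HU in 100-unit steps (13 segmentations) with the
#' display window width fixed at 2500 HU. The exported surface is the
#' iso-surface at the window level; the width is a display concept and
#' does not affect extraction.
#'
#' @param levels strictly increasing HU iso-values.
#' @param window_width display window width (HU), carried for
#'   provenance only.
#' @return an object of class `threshold_sweep`.
#' @export
threshold_sweep <- function(levels = seq(1425, 2625, by = 100),
                            window_width = 2500) {
  levels <- as.numeric(levels)
  if (length(levels) < 1L || any(diff(levels) <= 0))
    mf_stop("mf_invalid_spec", "sweep levels must be strictly increasing")
  structure(list(levels = levels, window_width = window_width),
            class = "threshold_sweep")
}

#' Extract the iso-surface mesh at a segmentation threshold
#'
#' Marching tetrahedra on the Kuhn cube subdivision: vertices are
#' placed by linear interpolation along the tetrahedral edges of the
#' voxel lattice, scaled by the spacing and offset by the origin. The
#' largest connected component (by area) is retained and degenerate
#' faces are removed.
#'
#' @param vol a [voxel_volume()].
#' @param level iso-value in HU, strictly inside the volume's range.
#' @param keep_largest retain only the largest connected component.
#' @return a [tri_mesh()].
#' @export
extract_mesh <- function(vol, level, keep_largest = TRUE) {
  if (!inherits(vol, "voxel_volume"))
    mf_stop("mf_invalid_volume", "vol must be a voxel_volume")
  rng <- range(vol$values)
  if (level <= rng[1] || level >= rng[2])
    mf_stop("mf_empty_segmentation",
            "level %g is outside the volume's value range [%g, %g]",
            level, rng[1], rng[2])
  out <- .mt_extract(as.numeric(vol$values), dim(vol$values),
                     vol$spacing_mm, vol$origin_mm, level)
  if (nrow(out$faces) == 0L)
    mf_stop("mf_empty_segmentation", "empty segmentation at level %g", level)
  mesh <- tri_mesh(out$vertices, out$faces, sprintf("level=%g", level))
  mesh <- mesh_clean(mesh)
  if (keep_largest) mesh <- largest_component(mesh)
  mesh
}

#' Crop region
#'
#' An axis-aligned box or an extruded polygon (a 2-D polygon in the
#' x/y plane extruded over a z interval), in the common mm frame.
#'
#' @param shape `"box"` or `"extruded-polygon"`.
#' @param lo,hi box corners (box shape).
#' @param polygon_xy `n x 2` matrix of polygon vertices
#'   (extruded-polygon shape).
#' @param z_range length-2 z interval (extruded-polygon shape).
#' @return an object of class `crop_region`.
#' @export
crop_region <- function(shape = c("box", "extruded-polygon"),
                        lo = NULL, hi = NULL,
                        polygon_xy = NULL, z_range = NULL) {
  shape <- match.arg(shape)
  if (shape == "box") {
    if (is.null(lo) || is.null(hi) || any(hi <= lo))
      mf_stop("mf_invalid_spec", "box crop needs lo < hi on every axis")
    structure(list(shape = shape, lo = as.numeric(lo), hi = as.numeric(hi)),
              class = "crop_region")
  } else {
    polygon_xy <- as.matrix(polygon_xy)
    if (is.null(z_range) || diff(z_range) <= 0 || nrow(polygon_xy) < 3L)
      mf_stop("mf_invalid_spec",
              "extruded-polygon crop needs >= 3 vertices and z_lo < z_hi")
    structure(list(shape = shape, polygon_xy = polygon_xy,
                   z_range = as.numeric(z_range)),
              class = "crop_region")
  }
}

# even-odd point-in-polygon, vectorized over points
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

region_contains <- function(region, pts) {
  if (region$shape == "box") {
    pts[, 1] >= region$lo[1] & pts[, 1] <= region$hi[1] &
      pts[, 2] >= region$lo[2] & pts[, 2] <= region$hi[2] &
      pts[, 3] >= region$lo[3] & pts[, 3] <= region$hi[3]
  } else {
    point_in_polygon(pts[, 1], pts[, 2], region$polygon_xy) &
      pts[, 3] >= region$z_range[1] & pts[, 3] <= region$z_range[2]
  }
}

#' Simultaneously crop co-registered meshes
#'
#' Applies one region to every mesh in a single call, mirroring the
#' protocol step in which all overlapped meshes are cropped together.
#' A face is retained when its centroid lies inside the region; open
#' boundaries are permitted afterwards.
#'
#' @param meshes list of co-registered [tri_mesh()] objects.
#' @param region a [crop_region()].
#' @return list of cropped meshes, same order and provenance.
#' @export
crop_meshes <- function(meshes, region) {
  if (inherits(meshes, "tri_mesh")) meshes <- list(meshes)
  lapply(seq_along(meshes), function(i) {
    m <- meshes[[i]]
    keep <- region_contains(region, face_centroids(m))
    if (!any(keep))
      mf_stop("mf_empty_mesh",
              "crop region removes the entire mesh #%d (%s)", i, m$provenance)
    mesh_subset_faces(m, keep)
  })
}

#' Default crop region for a phantom case
#'
#' Keeps the teeth plus the spec's gingiva band: everything above
#' `(top of the gingiva base) - gingiva_band_mm`.
#'
#' @param spec a [phantom_spec()].
#' @param margin_mm lateral margin beyond the arch extent.
#' @return a box [crop_region()].
#' @export
default_crop_region <- function(spec, margin_mm = 10) {
  R <- spec$arch_radius_mm
  z_top <- spec$gingiva_band_mm + 2
  crop_region("box",
              lo = c(-(R + 5 + margin_mm), -(0.35 * R + 5 + margin_mm),
                     z_top - spec$gingiva_band_mm),
              hi = c(R + 5 + margin_mm, R + 5 + margin_mm,
                     z_top + spec$tooth_height_mm + 5))
}
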