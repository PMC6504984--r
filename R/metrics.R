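#' Per-face deviations between a test mesh and the reference surface
#'
#' For each face of the registered test mesh, the absolute Euclidean
#' distance from the face centroid to its exact closest point anywhere
#' on the reference surface (point-to-triangle, tree-accelerated).
#' Output order matches the face order of `test`.
#'
#' @param test registered test [tri_mesh()] (non-empty).
#' @param reference reference (gold standard) [tri_mesh()], or a
#'   prebuilt [surface_tree()] over it.
#' @return numeric vector of distances (mm), one per test face.
#' @export
face_deviations <- function(test, reference) {
  if (nrow(test$faces) < 1L)
    mf_stop("mf_empty_mesh", "test mesh has no faces")
  tree <- if (inherits(reference, "mf_surface_tree")) reference
          else surface_tree(reference)
  closest_points(tree, face_centroids(test))$distance
}

#' Summary statistics of a deviation sample
#'
#' The protocol's per-pair statistics: median and interquartile range
#' (linear-interpolation quantiles, R type 7), the Dissimilarity Index
#' `DI = median_mm * iqr_mm * 1000` (dimensionless; small is good), the
#' 95% bound (value below which 95% of the per-face differences fall,
#' i.e. the extreme 5% of errors are trimmed), mean and SD.
#'
#' @param sample numeric vector of non-negative distances (mm), e.g.
#'   from [face_deviations()].
#' @return an object of class `deviation_summary` with fields
#'   `median_mm`, `iqr_mm`, `di`, `p95_mm`, `mean_mm`, `sd_mm`,
#'   `n_faces`.
#' @export
summarize_deviations <- function(sample) {
  sample <- as.numeric(sample)
  if (length(sample) == 0L || anyNA(sample))
    mf_stop("mf_empty_sample", "deviation sample is empty or has NAs")
  if (any(sample < 0))
    mf_stop("mf_empty_sample", "deviations must be non-negative")
  q <- quantile(sample, c(0.25, 0.5, 0.75, 0.95), names = FALSE, type = 7)
  med <- q[2]
  iqr <- q[3] - q[1]
  structure(list(median_mm = med, iqr_mm = iqr, di = med * iqr * 1000,
                 p95_mm = q[4], mean_mm = mean(sample),
                 sd_mm = if (length(sample) > 1L) sd(sample) else 0,
                 n_faces = length(sample)),
            class = "deviation_summary")
}

#' @export
print.deviation_summary <- function(x, ...) {
  cat(sprintf(
    "<deviation_summary> n=%d  median %.4f mm  IQR %.4f mm  DI %.2f  p95 %.4f mm\n",
    x$n_faces, x$median_mm, x$iqr_mm, x$di, x$p95_mm))
  invisible(x)
}

#' Attach a deviation sample to mesh faces for export
#'
#' Pure reshaping: pairs each face of `test` with its deviation so the
#' result can be exported or rendered as a deviation map.
#'
#' @param test the test [tri_mesh()].
#' @param sample numeric deviations, one per face of `test`.
#' @return list of class `deviation_map` with `mesh` and `values`.
#' @export
deviation_map <- function(test, sample) {
  if (length(sample) != nrow(test$faces))
    mf_stop("mf_length_mismatch",
            "sample length %d does not match face count %d",
            length(sample), nrow(test$faces))
  structure(list(mesh = test, values = as.numeric(sample)),
            class = "deviation_map")
}

#' Export a deviation map as ASCII PLY with a per-face quality channel
#'
#' @param map a [deviation_map()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_deviation_ply <- function(map, path) {
  m <- map$mesh
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "ply", "format ascii 1.0",
    sprintf("element vertex %d", nrow(m$vertices)),
    "property float x", "property float y", "property float z",
    sprintf("element face %d", nrow(m$faces)),
    "property list uchar int vertex_indices",
    "property float quality",
    "end_header",
    sprintf("%.9g %.9g %.9g", m$vertices[, 1], m$vertices[, 2], m$vertices[, 3]),
    sprintf("3 %d %d %d %.9g", m$faces[, 1] - 1L, m$faces[, 2] - 1L,
            m$faces[, 3] - 1L, map$values)), con)
  invisible(path)
}
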