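#' Triangle mesh
#'
#' A minimal indexed triangle surface: an `n x 3` numeric matrix of
#' vertex coordinates in mm and an `m x 3` integer matrix of 1-based
#' vertex indices, plus a free-text provenance label (device, case,
#' threshold, ...).
#'
#' @param vertices numeric matrix with 3 columns (mm).
#' @param faces integer matrix with 3 columns, 1-based vertex indices.
#' @param provenance free-text label carried along the pipeline.
#' @return an object of class `tri_mesh`.
#' @export
tri_mesh <- function(vertices, faces, provenance = "") {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L || ncol(faces) != 3L)
    mf_stop("mf_invalid_mesh", "vertices and faces must have 3 columns")
  if (nrow(vertices) < 3L || nrow(faces) < 1L)
    mf_stop("mf_invalid_mesh", "mesh needs >= 3 vertices and >= 1 face")
  if (anyNA(vertices) || anyNA(faces))
    mf_stop("mf_invalid_mesh", "mesh contains missing values")
  if (min(faces) < 1L || max(faces) > nrow(vertices))
    mf_stop("mf_invalid_mesh", "face indices out of range")
  structure(list(vertices = vertices, faces = faces,
                 provenance = as.character(provenance)),
            class = "tri_mesh")
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("<tri_mesh> %d vertices, %d faces%s\n",
              nrow(x$vertices), nrow(x$faces),
              if (nzchar(x$provenance)) paste0("  [", x$provenance, "]") else ""))
  invisible(x)
}

#' Surface area and enclosed volume of a mesh
#'
#' The enclosed volume uses the divergence theorem and is only
#' meaningful (and positive) for closed, outward-oriented surfaces.
#'
#' @param mesh a [tri_mesh()].
#' @return named numeric vector with `area` (mm^2) and `volume` (mm^3).
#' @export
mesh_area_volume <- function(mesh) {
  av <- .mesh_area_volume(mesh$vertices, mesh$faces)
  c(area = av[1], volume = av[2])
}

#' Topological summary of a mesh
#'
#' @param mesh a [tri_mesh()].
#' @return list with `n_edges`, `n_boundary_edges`, `n_nonmanifold_edges`,
#'   `closed` (every edge shared by exactly two consistently oriented
#'   faces) and `euler` (V - E + F; 2 for a closed genus-0 surface).
#' @export
mesh_topology <- function(mesh) {
  .mesh_topology(mesh$faces, nrow(mesh$vertices))
}

#' Is a mesh watertight?
#'
#' Watertight here means topologically closed with consistent
#' orientation and strictly positive enclosed volume.
#'
#' @param mesh a [tri_mesh()].
#' @export
is_watertight <- function(mesh) {
  top <- mesh_topology(mesh)
  isTRUE(top$closed) && mesh_area_volume(mesh)[["volume"]] > 0
}

#' Per-face areas and centroids
#' @param mesh a [tri_mesh()].
#' @return `face_areas`: numeric vector (mm^2); `face_centroids`:
#'   matrix `m x 3` (mm).
#' @export
face_areas <- function(mesh) .face_areas(mesh$vertices, mesh$faces)

#' @rdname face_areas
#' @export
face_centroids <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  (v[f[, 1], , drop = FALSE] + v[f[, 2], , drop = FALSE] +
     v[f[, 3], , drop = FALSE]) / 3
}

#' Keep selected faces, dropping unreferenced vertices
#' @param mesh a [tri_mesh()].
#' @param keep logical or integer face index vector.
#' @keywords internal
mesh_subset_faces <- function(mesh, keep) {
  f <- mesh$faces[keep, , drop = FALSE]
  if (nrow(f) == 0L)
    mf_stop("mf_empty_mesh", "face subset leaves an empty mesh")
  used <- sort(unique(as.vector(f)))
  remap <- integer(nrow(mesh$vertices))
  remap[used] <- seq_along(used)
  tri_mesh(mesh$vertices[used, , drop = FALSE],
           matrix(remap[f], ncol = 3L), mesh$provenance)
}

#' Remove degenerate faces
#'
#' Welds vertices with bit-identical coordinates, then drops faces
#' referencing a vertex twice. Dropping such faces never opens the
#' surface: their directed edges cancel within the face itself.
#'
#' @param mesh a [tri_mesh()].
#' @keywords internal
mesh_clean <- function(mesh) {
  out <- .weld_clean(mesh$vertices, mesh$faces)
  if (nrow(out$faces) == 0L)
    mf_stop("mf_empty_mesh", "cleaning leaves an empty mesh")
  tri_mesh(out$vertices, out$faces, mesh$provenance)
}

#' Largest connected component (by surface area)
#' @param mesh a [tri_mesh()].
#' @export
largest_component <- function(mesh) {
  comp <- .mesh_face_components(mesh$faces, nrow(mesh$vertices))
  if (max(comp) == 1L) return(mesh)
  a <- face_areas(mesh)
  areas <- tapply(a, comp, sum)
  best <- as.integer(names(areas)[which.max(areas)])
  mesh_subset_faces(mesh, comp == best)
}

#' Sample points uniformly (area-weighted) on a mesh surface
#'
#' Faces are drawn with probability proportional to area, then a point
#' is placed uniformly in each face via the square-root barycentric
#' trick. Deterministic given the R random seed in effect.
#'
#' @param mesh a [tri_mesh()].
#' @param n number of points.
#' @return `n x 3` matrix of points.
#' @export
sample_surface_points <- function(mesh, n) {
  a <- face_areas(mesh)
  idx <- sample.int(nrow(mesh$faces), n, replace = TRUE, prob = a)
  r1 <- sqrt(runif(n))
  r2 <- runif(n)
  w1 <- 1 - r1
  w2 <- r1 * (1 - r2)
  w3 <- r1 * r2
  v <- mesh$vertices
  f <- mesh$faces[idx, , drop = FALSE]
  w1 * v[f[, 1], , drop = FALSE] + w2 * v[f[, 2], , drop = FALSE] +
    w3 * v[f[, 3], , drop = FALSE]
}

#' Closest-point search structure over a mesh surface
#'
#' Builds an axis-aligned bounding-box tree over the triangles; queries
#' return the exact closest surface point per query point.
#'
#' @param mesh a [tri_mesh()].
#' @return opaque handle for [closest_points()].
#' @export
surface_tree <- function(mesh) {
  structure(list(ptr = .aabb_build(mesh$vertices, mesh$faces),
                 n_faces = nrow(mesh$faces)),
            class = "mf_surface_tree")
}

#' @rdname surface_tree
#' @param tree a [surface_tree()].
#' @param points `n x 3` matrix of query points (mm).
#' @return list with `distance` (mm), `closest` (`n x 3`), `face`
#'   (1-based index of the nearest triangle).
#' @export
closest_points <- function(tree, points) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  .aabb_query(tree$ptr, points)
}
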