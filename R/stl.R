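#' Read and write STL surface files
#'
#' Binary and ASCII stereolithography (STL) files. The format stores a
#' triangle soup; on read, vertices with bit-identical coordinates are
#' welded so the result is an indexed [tri_mesh()]. Writing uses
#' 32-bit floats (the format's precision) with outward facet normals
#' recomputed from the counter-clockwise vertex order.
#'
#' @param path file path.
#' @param provenance label attached to the mesh read.
#' @return `read_stl`: a [tri_mesh()]. `write_stl`: `path`, invisibly.
#' @export
read_stl <- function(path, provenance = basename(path)) {
  if (!file.exists(path))
    mf_stop("mf_format_error", "STL file not found: %s", path)
  size <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  head <- readBin(con, "raw", n = min(size, 512L))
  is_ascii <- FALSE
  if (size >= 6 && rawToChar(head[1:5]) == "solid") {
    # binary files may also start with "solid": require the keyword "facet"
    txt <- tolower(rawToChar(head[head != as.raw(0)]))
    if (grepl("facet", txt, fixed = TRUE)) is_ascii <- TRUE
  }
  if (is_ascii) return(read_stl_ascii(path, provenance))

  if (size < 84)
    mf_stop("mf_format_error",
            "truncated binary STL (%d bytes, header needs 84): %s", size, path)
  seek(con, 80)
  n_tri <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  expected <- 84 + 50 * as.numeric(n_tri)
  if (n_tri < 1L)
    mf_stop("mf_empty_mesh", "STL declares %d triangles: %s", n_tri, path)
  if (size < expected)
    mf_stop("mf_format_error",
            "truncated binary STL at byte %d (expected %d bytes): %s",
            size, expected, path)
  raw_body <- readBin(con, "raw", n = 50L * n_tri)
  # each 50-byte record: 12 floats (normal + 3 vertices) + uint16 attribute
  rec <- matrix(raw_body, nrow = 50L)
  floats <- readBin(as.vector(rec[1:48, ]), "double", n = 12L * n_tri,
                    size = 4L, endian = "little")
  fm <- matrix(floats, nrow = 12L)
  verts <- matrix(as.vector(fm[4:12, ]), ncol = 3L, byrow = TRUE)
  weld_soup(verts, provenance)
}

read_stl_ascii <- function(path, provenance = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vl) == 0L)
    mf_stop("mf_empty_mesh", "ASCII STL has no vertices: %s", path)
  if (length(vl) %% 3L != 0L)
    mf_stop("mf_format_error",
            "ASCII STL vertex count %d not a multiple of 3: %s",
            length(vl), path)
  nums <- lapply(strsplit(trimws(vl), "\\s+"), function(p) as.numeric(p[2:4]))
  verts <- do.call(rbind, nums)
  if (anyNA(verts))
    mf_stop("mf_format_error", "unparseable vertex line in %s", path)
  weld_soup(verts, provenance)
}

# weld triangle-soup vertices that agree bit-for-bit
weld_soup <- function(verts, provenance) {
  key <- paste(format(verts[, 1], digits = 17),
               format(verts[, 2], digits = 17),
               format(verts[, 3], digits = 17))
  idx <- match(key, key)          # first-occurrence row per soup vertex
  firsts <- unique(idx)
  vid <- match(idx, firsts)
  faces <- matrix(vid, ncol = 3L, byrow = TRUE)
  tri_mesh(verts[firsts, , drop = FALSE], faces, provenance)
}

#' @rdname read_stl
#' @param mesh a [tri_mesh()].
#' @param binary write binary (default) or ASCII STL.
#' @export
write_stl <- function(mesh, path, binary = TRUE) {
  # quantize to 32-bit float up front so ASCII and binary dumps agree
  v <- matrix(float32_round(mesh$vertices), ncol = 3L,
              dimnames = NULL)
  f <- mesh$faces
  n <- nrow(f)
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  u <- b - a
  w <- c_ - a
  nrm <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
               u[, 3] * w[, 1] - u[, 1] * w[, 3],
               u[, 1] * w[, 2] - u[, 2] * w[, 1])
  len <- sqrt(rowSums(nrm^2))
  len[len == 0] <- 1
  nrm <- nrm / len

  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    header <- charToRaw(sprintf("%-80s", "meshfidelity binary STL"))[1:80]
    writeBin(header, con)
    writeBin(as.integer(n), con, size = 4L, endian = "little")
    block <- t(cbind(nrm, a, b, c_)) # 12 floats per triangle, column = face
    fl <- writeBin(as.numeric(block), raw(), size = 4L, endian = "little")
    rec <- rbind(matrix(fl, nrow = 48L), matrix(as.raw(0), nrow = 2L, ncol = n))
    writeBin(as.vector(rec), con)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    fmt <- function(m) sprintf("%.9g %.9g %.9g", m[, 1], m[, 2], m[, 3])
    lines <- c("solid meshfidelity",
               as.vector(rbind(
                 sprintf("  facet normal %s", fmt(nrm)),
                 "    outer loop",
                 sprintf("      vertex %s", fmt(a)),
                 sprintf("      vertex %s", fmt(b)),
                 sprintf("      vertex %s", fmt(c_)),
                 "    endloop",
                 "  endfacet")),
               "endsolid meshfidelity")
    writeLines(lines, con)
  }
  invisible(path)
}

# round a double through IEEE float32 (STL's stored precision)
float32_round <- function(x) {
  readBin(writeBin(as.numeric(x), raw(), size = 4L, endian = "little"),
          "double", n = length(x), size = 4L, endian = "little")
}
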