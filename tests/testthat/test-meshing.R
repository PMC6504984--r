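test_that("sphere extraction matches the closed form", {
  vol <- sphere_volume(r = 5, vx = 0.15, mode = "pv")
  m <- extract_mesh(vol, 1000) # midpoint of -1000/3000
  area <- mesh_area_volume(m)[["area"]]
  expect_lt(abs(area / (4 * pi * 25) - 1), 0.05)
  rad <- sqrt(rowSums(m$vertices^2))
  expect_lt(max(abs(rad - 5)), 0.075) # half a voxel
  expect_true(is_watertight(m))
})

test_that("levels outside the data range raise an empty-segmentation error", {
  vol <- sphere_volume(r = 3, vx = 0.4)
  err <- tryCatch(extract_mesh(vol, -5000), error = function(e) e)
  expect_s3_class(err, "mf_empty_segmentation")
  expect_match(conditionMessage(err), "-5000")
  expect_error(extract_mesh(vol, 1e5), class = "mf_empty_segmentation")
})

test_that("enclosed volume is non-increasing in the threshold", {
  vol <- sphere_volume(r = 4, vx = 0.25, mode = "pv")
  blur <- meshfidelity:::.gaussian_blur3(as.numeric(vol$values),
                                         dim(vol$values), rep(1.5, 3))
  volb <- voxel_volume(array(blur, dim(vol$values)), vol$spacing_mm,
                       vol$origin_mm)
  vols <- vapply(seq(-200, 2200, by = 400), function(lv)
    mesh_area_volume(extract_mesh(volb, lv))[["volume"]], numeric(1))
  expect_true(all(diff(vols) <= 1e-9))
})

test_that("halving the voxel size converges to the analytic sphere", {
  hd <- vapply(c(0.5, 0.25, 0.125), function(vx) {
    m <- extract_mesh(sphere_volume(r = 4, vx = vx, mode = "sdf"), 0)
    max(abs(sqrt(rowSums(m$vertices^2)) - 4))
  }, numeric(1))
  expect_true(all(diff(hd) < 0))
})

test_that("extraction is deterministic", {
  vol <- sphere_volume(r = 3, vx = 0.4)
  m1 <- extract_mesh(vol, 500)
  m2 <- extract_mesh(vol, 500)
  expect_identical(m1$vertices, m2$vertices)
  expect_identical(m1$faces, m2$faces)
})

test_that("cropping follows the centroid rule and is simultaneous", {
  m <- micro_sphere()
  all_in <- crop_region("box", lo = rep(-10, 3), hi = rep(10, 3))
  expect_identical(crop_meshes(list(m), all_in)[[1]]$faces, m$faces)

  half <- crop_region("box", lo = c(-10, -10, 0), hi = rep(10, 3))
  cropped <- crop_meshes(list(m, m), half)
  a_half <- mesh_area_volume(cropped[[1]])[["area"]]
  a_full <- mesh_area_volume(m)[["area"]]
  expect_lt(abs(a_half / a_full - 0.5), 0.02)
  expect_identical(cropped[[1]]$faces, cropped[[2]]$faces)

  off <- crop_region("box", lo = rep(50, 3), hi = rep(60, 3))
  err <- tryCatch(crop_meshes(list(m), off), error = function(e) e)
  expect_s3_class(err, "mf_empty_mesh")

  poly <- crop_region("extruded-polygon",
                      polygon_xy = cbind(c(-10, 10, 10, -10),
                                         c(-10, -10, 10, 10)),
                      z_range = c(0, 10))
  expect_equal(mesh_area_volume(crop_meshes(list(m), poly)[[1]])[["area"]],
               a_half, tolerance = 1e-9)
})

test_that("STL round-trips in both encodings", {
  m <- tri_mesh(matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0, 1, 1, 0.5),
                       4, 3, byrow = TRUE),
                matrix(c(1, 2, 3, 2, 4, 3), 2, 3, byrow = TRUE))
  fb <- withr::local_tempfile(fileext = ".stl")
  fa <- withr::local_tempfile(fileext = ".stl")
  write_stl(m, fb)
  write_stl(m, fa, binary = FALSE)
  mb <- read_stl(fb)
  ma <- read_stl(fa)
  expect_identical(mb$vertices, ma$vertices)
  expect_identical(mb$faces, ma$faces)
  expect_equal(mb$vertices, m$vertices, tolerance = 1e-6)

  # a bigger float32-stressing mesh survives the round trip; welding
  # reorders vertices by first face appearance, so compare canonically
  s <- micro_sphere()
  write_stl(s, fb)
  s2 <- read_stl(fb)
  canon <- function(m) {
    v <- m$vertices
    v[order(v[, 1], v[, 2], v[, 3]), , drop = FALSE]
  }
  s32 <- tri_mesh(matrix(meshfidelity:::float32_round(s$vertices), ncol = 3),
                  s$faces)
  expect_identical(canon(s2), canon(s32))
  expect_identical(nrow(s2$faces), nrow(s$faces))
  expect_equal(mesh_area_volume(s2), mesh_area_volume(s32), tolerance = 1e-12)
})

test_that("broken STL inputs raise format errors", {
  f <- withr::local_tempfile(fileext = ".stl")
  con <- file(f, "wb")
  writeBin(charToRaw(sprintf("%-80s", "header")), con)
  writeBin(0L, con, size = 4L, endian = "little") # zero triangles
  close(con)
  expect_error(read_stl(f), class = "mf_empty_mesh")

  con <- file(f, "wb")
  writeBin(charToRaw(sprintf("%-80s", "header")), con)
  writeBin(5L, con, size = 4L, endian = "little")
  writeBin(raw(60), con) # truncated: needs 250 bytes of records
  close(con)
  err <- tryCatch(read_stl(f), error = function(e) e)
  expect_s3_class(err, "mf_format_error")
  expect_match(conditionMessage(err), "byte")
})
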