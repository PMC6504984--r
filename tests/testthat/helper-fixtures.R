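# shared fixtures, built once per session, plus independent oracles
# (deliberately different algorithms from the package internals)

.fixtures <- new.env()

fixt <- function(name, fn) {
  if (is.null(.fixtures[[name]])) assign(name, fn(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# sphere voxel volume; "pv" = analytic partial-volume occupancy (the
# forward model's construction: a one-voxel linear transition), "sdf" =
# signed distance, "binary" = sharp two-value
sphere_volume <- function(r = 5, vx = 0.15, mode = "pv",
                          hu_air = -1000, hu_stone = 3000, pad = 1) {
  n <- as.integer(ceiling(2 * (r + pad) / vx))
  lo <- rep(-(r + pad), 3)
  xs <- lo[1] + (seq_len(n) - 0.5) * vx
  g <- expand.grid(x = xs, y = xs, z = xs, KEEP.OUT.ATTRS = FALSE)
  d <- sqrt(g$x^2 + g$y^2 + g$z^2)
  f <- switch(mode,
    pv = {
      occ <- pmin(1, pmax(0, (r - d) / vx + 0.5))
      hu_air + occ * (hu_stone - hu_air)
    },
    sdf = r - d,
    binary = ifelse(d < r, hu_stone, hu_air),
    stop("unknown mode"))
  voxel_volume(array(f, c(n, n, n)), rep(vx, 3), lo)
}

# small phantom mesh for registration/metrics tests (~15k faces)
tiny_phantom <- function() fixt("tiny_phantom", function() {
  spec <- phantom_spec(case_id = "tiny", n_teeth = 3, arch_radius_mm = 5,
                       tooth_height_mm = 3, gingiva_band_mm = 3,
                       rng_seed = 7, surface_resolution_mm = 0.25)
  generate_ground_truth(spec)
})

# ~2k-face sphere mesh for the cheapest mesh-pair tests
micro_sphere <- function() fixt("micro_sphere", function() {
  extract_mesh(sphere_volume(r = 3, vx = 0.4), 1000)
})

# axis-aligned box mesh (12 triangles, outward orientation)
box_mesh <- function(lo = c(0, 0, 0), hi = c(1, 1, 1)) {
  v <- as.matrix(expand.grid(x = c(lo[1], hi[1]), y = c(lo[2], hi[2]),
                             z = c(lo[3], hi[3])))
  # faces chosen so normals point outward (verified: volume > 0)
  f <- matrix(c(
    1, 3, 2, 2, 3, 4,   # z = lo
    5, 6, 7, 6, 8, 7,   # z = hi
    1, 2, 5, 2, 6, 5,   # y = lo
    3, 7, 4, 4, 7, 8,   # y = hi
    1, 5, 3, 3, 5, 7,   # x = lo
    2, 4, 6, 4, 8, 6),  # x = hi
    ncol = 3, byrow = TRUE)
  tri_mesh(v, f)
}

# independent point-to-triangle distance: constrained quadratic plus
# clamped edge projections (different route than the C++ kernel)
tri_dist_oracle <- function(p, a, b, c) {
  u <- b - a; v <- c - a; w <- p - a
  uu <- sum(u * u); vv <- sum(v * v); uv <- sum(u * v)
  wu <- sum(w * u); wv <- sum(w * v)
  dt <- uu * vv - uv^2
  cand <- list()
  if (dt > 0) {
    s <- (vv * wu - uv * wv) / dt
    t <- (uu * wv - uv * wu) / dt
    if (s >= 0 && t >= 0 && s + t <= 1)
      cand <- c(cand, list(a + s * u + t * v))
  }
  edge <- function(p0, p1) {
    e <- p1 - p0
    tt <- min(1, max(0, sum((p - p0) * e) / sum(e * e)))
    p0 + tt * e
  }
  cand <- c(cand, list(edge(a, b), edge(a, c), edge(b, c)))
  sqrt(min(vapply(cand, function(q) sum((p - q)^2), numeric(1))))
}

# brute force over every triangle of a mesh
brute_force_deviations <- function(test, reference) {
  ctr <- face_centroids(test)
  V <- reference$vertices
  F <- reference$faces
  vapply(seq_len(nrow(ctr)), function(i) {
    p <- ctr[i, ]
    min(vapply(seq_len(nrow(F)), function(f)
      tri_dist_oracle(p, V[F[f, 1], ], V[F[f, 2], ], V[F[f, 3], ]),
      numeric(1)))
  }, numeric(1))
}

# Horn's quaternion absolute-orientation fit: independent oracle for the
# SVD-based Kabsch solver
horn_fit <- function(src, dst) {
  cs <- colMeans(src); cd <- colMeans(dst)
  S <- t(sweep(src, 2, cs)) %*% sweep(dst, 2, cd)
  N <- rbind(
    c(S[1,1] + S[2,2] + S[3,3], S[2,3] - S[3,2], S[3,1] - S[1,3], S[1,2] - S[2,1]),
    c(S[2,3] - S[3,2], S[1,1] - S[2,2] - S[3,3], S[1,2] + S[2,1], S[3,1] + S[1,3]),
    c(S[3,1] - S[1,3], S[1,2] + S[2,1], -S[1,1] + S[2,2] - S[3,3], S[2,3] + S[3,2]),
    c(S[1,2] - S[2,1], S[3,1] + S[1,3], S[2,3] + S[3,2], -S[1,1] - S[2,2] + S[3,3]))
  q <- eigen(N, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- rbind(
    c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y)),
    c(2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x)),
    c(2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)))
  list(rotation = R, translation = cd - as.numeric(R %*% cs))
}

# from-scratch one-way repeated-measures sums of squares (loops, no
# matrix shortcuts)
rm_oneway_oracle <- function(Y) {
  n <- nrow(Y); k <- ncol(Y)
  grand <- mean(Y)
  ss_cond <- 0
  for (j in seq_len(k)) ss_cond <- ss_cond + n * (mean(Y[, j]) - grand)^2
  ss_subj <- 0
  for (i in seq_len(n)) ss_subj <- ss_subj + k * (mean(Y[i, ]) - grand)^2
  ss_res <- 0
  for (i in seq_len(n)) for (j in seq_len(k))
    ss_res <- ss_res + (Y[i, j] - mean(Y[, j]) - mean(Y[i, ]) + grand)^2
  Fv <- (ss_cond / (k - 1)) / (ss_res / ((k - 1) * (n - 1)))
  list(F = Fv, ss_cond = ss_cond, ss_subj = ss_subj, ss_res = ss_res)
}
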