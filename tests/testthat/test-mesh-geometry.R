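test_that("distance field matches the definition on single-voxel sources", {
  d <- c(5, 5, 5)
  m <- array(FALSE, d); m[3, 3, 3] <- TRUE
  df <- distance_from_mask(label_mask(m, c(1, 1, 1)))
  expect_equal(df$values[3, 3, 3], 0)
  expect_equal(df$values[4, 3, 3], 1)
  expect_equal(df$values[4, 4, 4], sqrt(3))

  dfa <- distance_from_mask(label_mask(m, c(1, 1, 2)))
  expect_equal(dfa$values[3, 3, 4], 2)
  expect_equal(dfa$values[4, 3, 3], 1)
})

test_that("distance field equals brute force on random anisotropic masks", {
  set.seed(17)
  for (trial in 1:20) {
    d <- sample(8:20, 3, replace = TRUE)
    sp <- round(runif(3, 0.4, 2.2), 2)
    m <- array(runif(prod(d)) < 0.04, d)
    if (!any(m)) m[1, 1, 1] <- TRUE
    df <- distance_from_mask(label_mask(m, sp))
    expect_lt(max(abs(df$values - brute_force_edt(m, sp))), 1e-9)
  }
})

test_that("distance field is symmetric under axis permutation with spacing", {
  set.seed(23)
  d <- c(12, 12, 12)
  m <- array(runif(prod(d)) < 0.05, d)
  sp <- c(0.6, 1.1, 1.7)
  base <- distance_from_mask(label_mask(m, sp))$values
  perm <- distance_from_mask(label_mask(aperm(m, c(3, 1, 2)),
                                        sp[c(3, 1, 2)]))$values
  expect_equal(aperm(base, c(3, 1, 2)), perm, tolerance = 1e-12)
  expect_error(distance_from_mask(label_mask(array(FALSE, d), sp)),
               "empty source")
})

test_that("iso-surface of a digitized sphere encloses the analytic volume", {
  sph <- digitized_sphere(10, 0.5)
  mesh <- extract_mesh(sph$mask)
  expect_true(is_watertight(mesh))
  expect_lt(abs(mesh_volume(mesh) - 4188.79) / 4188.79, 0.02)
})

test_that("mesh volume error decreases as spacing shrinks", {
  errs <- vapply(c(1.0, 0.5, 0.25), function(sp) {
    m <- extract_mesh(digitized_sphere(10, sp)$mask)
    abs(mesh_volume(m) - 4188.79) / 4188.79
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("single-voxel and border-touching masks mesh correctly", {
  m <- array(FALSE, c(4, 4, 4)); m[2, 2, 2] <- TRUE
  mesh <- extract_mesh(label_mask(m, c(1, 1, 1)))
  expect_true(is_watertight(mesh))
  expect_gte(mesh_volume(mesh), 0.4)
  expect_lte(mesh_volume(mesh), 1.1)

  # mask touching the border gets a closing pad
  mb <- array(FALSE, c(5, 5, 5)); mb[1:3, 1:3, 1:3] <- TRUE
  meshb <- extract_mesh(label_mask(mb, c(1, 1, 1)))
  expect_true(is_watertight(meshb))
  expect_error(extract_mesh(label_mask(array(FALSE, c(4, 4, 4)), c(1, 1, 1))),
               "empty")
})

test_that("divergence-theorem volume is exact on a hand-built cube", {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  # 12 triangles, outward-oriented
  f <- rbind(c(1, 3, 2), c(2, 3, 4),   # z = 0
             c(5, 6, 7), c(6, 8, 7),   # z = 1
             c(1, 2, 5), c(2, 6, 5),   # y = 0
             c(3, 7, 4), c(4, 7, 8),   # y = 1
             c(1, 5, 3), c(3, 5, 7),   # x = 0
             c(2, 4, 6), c(4, 8, 6))   # x = 1
  cube <- surface_mesh(v, f)
  expect_true(is_watertight(cube))
  expect_equal(mesh_volume(cube), 1.0)
  expect_equal(mesh_area(cube), 6.0)

  holed <- surface_mesh(v, f[-1, ])
  expect_false(is_watertight(holed))
  expect_error(mesh_volume(holed), "watertight")
})

test_that("icosphere volume agrees with the analytic sphere to 1%", {
  # icosahedron subdivided 4 times, projected to radius 10
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in 1:4) {
    nf <- nrow(f)
    newf <- matrix(0L, 4 * nf, 3)
    mid_cache <- new.env()
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      if (!is.null(mid_cache[[key]])) return(mid_cache[[key]])
      v <<- rbind(v, (v[a, ] + v[b, ]) / 2)
      mid_cache[[key]] <- nrow(v)
      nrow(v)
    }
    for (i in seq_len(nf)) {
      a <- f[i, 1]; b <- f[i, 2]; c <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      newf[4 * i - 3, ] <- c(a, ab, ca)
      newf[4 * i - 2, ] <- c(b, bc, ab)
      newf[4 * i - 1, ] <- c(c, ca, bc)
      newf[4 * i, ] <- c(ab, bc, ca)
    }
    f <- newf
    v <- v / sqrt(rowSums(v^2)) * 10
  }
  ico <- surface_mesh(v, f)
  expect_true(is_watertight(ico))
  expect_lt(abs(mesh_volume(ico) - 4188.79) / 4188.79, 0.01)
})

test_that("smoothing keeps the enclosed volume within the 2% bound", {
  sph <- digitized_sphere(6, 1)
  raw <- extract_mesh(sph$mask)
  for (it in c(1L, 5L, 20L)) {
    sm <- extract_mesh(sph$mask, smoothing_iterations = it)
    expect_lte(abs(mesh_volume(sm) - mesh_volume(raw)) / mesh_volume(raw),
               0.02 + 1e-9)
  }
})

test_that("CT sampling on mesh vertices reproduces constant and linear fields", {
  sph <- digitized_sphere(5, 1)
  mesh <- extract_mesh(sph$mask)
  d <- dim(sph$mask$data)

  const <- ct_volume(array(77, d), sph$mask$spacing)
  expect_true(all(sample_ct_on_mesh(const, mesh)$vertex_scalars == 77))

  xs <- (seq_len(d[1]) - 1) * sph$mask$spacing[1]
  ramp <- ct_volume(array(rep(xs, times = d[2] * d[3]), d), sph$mask$spacing)
  sampled <- sample_ct_on_mesh(ramp, mesh)
  expect_equal(sampled$vertex_scalars, mesh$vertices[, 1], tolerance = 1e-6)

  outside <- surface_mesh(rbind(c(-5, 0, 0), c(1, 1, 1), c(2, 2, 2)),
                          matrix(c(1, 2, 3), 1))
  expect_warning(sample_ct_on_mesh(const, outside), "clamped")
})
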