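test_that("CT volumes round-trip through NIfTI with header spacing intact", {
  set.seed(11)
  vol <- ct_volume(array(rnorm(20 * 18 * 16, mean = 100, sd = 50),
                         c(20, 18, 16)),
                   spacing = c(0.7, 0.7, 1.0), origin = c(3, -2, 10))
  path <- tempfile(fileext = ".nii.gz")
  write_volume(vol, path)
  back <- read_volume(path)
  expect_equal(back$data, vol$data, tolerance = 1e-6)  # float32 storage
  # spacing survives at the header's float32 precision, bit-for-bit
  f32 <- function(x) readBin(writeBin(as.numeric(x), raw(), size = 4),
                             "numeric", n = length(x), size = 4)
  expect_identical(back$spacing, f32(c(0.7, 0.7, 1.0)))
  expect_equal(back$origin, vol$origin, tolerance = 1e-6)

  # independent header parse: sform rows straight out of the gzipped file
  con <- gzfile(path, "rb")
  hdr <- readBin(con, "raw", 352)
  close(con)
  srow <- readBin(hdr[281:328], "numeric", n = 12, size = 4,
                  endian = "little")
  expect_identical(srow[c(1, 6, 11)], f32(c(0.7, 0.7, 1.0)))
  expect_identical(srow[c(4, 8, 12)], f32(c(3, -2, 10)))
})

test_that("masks round-trip losslessly and counts survive", {
  d <- c(9, 8, 7)
  m <- array(FALSE, d)
  set.seed(5)
  m[sample(prod(d), 17)] <- TRUE
  mask <- label_mask(m, spacing = c(1, 1, 1.5))
  path <- tempfile(fileext = ".nii.gz")
  write_mask(mask, path)
  back <- read_mask(path)
  expect_identical(back$data, mask$data)
  # voxel sum by independent iteration
  n <- 0L
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (back$data[i, j, k]) n <- n + 1L
  }
  expect_identical(n, 17L)

  zero <- label_mask(array(FALSE, d), spacing = c(1, 1, 1.5))
  pz <- tempfile(fileext = ".nii.gz")
  write_mask(zero, pz)
  expect_identical(mask_count(read_mask(pz)), 0L)
})

test_that("malformed or unsupported NIfTI inputs are rejected clearly", {
  expect_error(read_volume(tempfile(fileext = ".nii")), "not found")

  p4 <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(0, c(4, 4, 4, 3))), p4)
  expect_error(read_volume(p4), "expected 3D")

  # oblique affine: 10-degree rotation about z
  th <- 10 * pi / 180
  aff <- diag(4)
  aff[1:2, 1:2] <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  img <- RNifti::asNifti(array(0, c(5, 5, 5)))
  RNifti::sform(img) <- structure(aff, code = 2L)
  pob <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(img, pob)
  expect_error(read_volume(pob), "oblique")

  expect_error(write_volume(list(a = 1), tempfile(fileext = ".nii")),
               "ct_volume or label_mask")
})

test_that("world/index mapping follows the voxel-center convention", {
  vol <- ct_volume(array(0, c(6, 6, 6)), spacing = c(2, 2, 2),
                   origin = c(0, 0, 0))
  expect_equal(world_to_index(c(0, 0, 0), vol), c(0, 0, 0))
  expect_equal(world_to_index(c(4, 2, 0), vol), c(2, 1, 0))

  volo <- ct_volume(array(0, c(6, 6, 6)), spacing = c(0.7, 1.3, 2.1),
                    origin = c(-4, 2.5, 11))
  expect_equal(world_to_index(volo$origin, volo), c(0, 0, 0))

  set.seed(3)
  pts <- matrix(runif(60, -20, 20), ncol = 3)
  expect_equal(index_to_world(world_to_index(pts, volo), volo), pts,
               tolerance = 1e-12)
  expect_identical(in_bounds(rbind(c(0, 0, 0), c(5, 5, 5), c(5.1, 0, 0),
                                   c(-0.1, 2, 2)), volo),
                   c(TRUE, TRUE, FALSE, FALSE))
})

test_that("grid and alignment invariants are enforced", {
  expect_error(ct_volume(array(0, c(4, 4)), c(1, 1, 1)), "3D")
  expect_error(ct_volume(array(0, c(4, 4, 1)), c(1, 1, 1)), "at least 2")
  expect_error(ct_volume(array(0, c(4, 4, 4)), c(1, 0, 1)), "positive")
  expect_error(label_mask(array(2, c(4, 4, 4)), c(1, 1, 1)), "0/1")
  a <- label_mask(array(FALSE, c(4, 4, 4)), c(1, 1, 1))
  b <- label_mask(array(FALSE, c(4, 4, 5)), c(1, 1, 1))
  expect_error(detect_opening(a, b), "misaligned")
})

test_that("annotation JSON files round-trip", {
  scr <- scribble_set(rbind(c(1, 2, 3), c(4, 5, 6)), rbind(c(0, 0, 0)))
  ps <- tempfile(fileext = ".json")
  write_annotations(scr, ps)
  back <- read_scribbles(ps)
  expect_identical(back$foreground, scr$foreground)
  expect_identical(back$background, scr$background)

  seeds <- seed_set(rbind(c(7, 8, 9)), threshold_r = 385)
  pe <- tempfile(fileext = ".json")
  write_annotations(seeds, pe)
  expect_identical(read_seeds(pe)$seeds, seeds$seeds)
  expect_identical(read_seeds(pe)$threshold_r, 385)

  th <- seq(0, 2 * pi, length.out = 13)[-13]
  cs <- contour_stack(lapply(c(4L, 8L), function(k) {
    list(plane_axis = 2L, plane_index = k,
         points = cbind(10 + 5 * cos(th), 10 + 5 * sin(th)))
  }))
  pc <- tempfile(fileext = ".json")
  write_annotations(cs, pc)
  back <- read_contours(pc)
  expect_equal(back$contours[[2]]$points, cs$contours[[2]]$points)
  expect_identical(back$contours[[1]]$plane_index, 4L)

  expect_error(read_seeds(ps), "'seeds'")
})

test_that("annotation invariants reject malformed input", {
  expect_error(scribble_set(rbind(c(1, 1, 1)), rbind(c(1, 1, 1))),
               "overlap")
  expect_error(seed_set(matrix(numeric(0), 0, 3), 385), "non-empty")
  one_plane <- list(
    list(plane_axis = 2L, plane_index = 3L,
         points = rbind(c(0, 0), c(4, 0), c(2, 3))),
    list(plane_axis = 2L, plane_index = 3L,
         points = rbind(c(0, 0), c(5, 0), c(2, 4))))
  expect_error(contour_stack(one_plane[1]), "two planes")
  expect_error(contour_stack(one_plane), "single plane")
  bowtie <- list(plane_axis = 2L, plane_index = 1L,
                 points = rbind(c(0, 0), c(4, 0), c(3, 2), c(1, -1)))
  expect_error(contour_stack(list(bowtie, bowtie)), "self-intersecting")
  collinear <- list(plane_axis = 2L, plane_index = 1L,
                    points = rbind(c(0, 0), c(1, 1), c(2, 2)))
  expect_error(contour_stack(list(collinear, collinear)), "degenerate|collinear")
})
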