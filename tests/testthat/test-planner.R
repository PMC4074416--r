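# Nested spheres: tumor r=10 mm centered inside kidney r=30 mm, 0.5 mm
# spacing — every removed-region quantity has a closed form.
nested_spheres <- function(spacing = 0.5, r_tumor = 10, r_kidney = 30) {
  n <- ceiling(2 * r_kidney / spacing) + 7
  xs <- (seq_len(n) - 1) * spacing
  ctr <- (n - 1) * spacing / 2
  q <- outer(outer((xs - ctr)^2, (xs - ctr)^2, "+"), (xs - ctr)^2, "+")
  list(kidney = label_mask(q < r_kidney^2, rep(spacing, 3)),
       tumor = label_mask(q < r_tumor^2, rep(spacing, 3)),
       center = rep(ctr, 3), n = n)
}

test_that("a margin below the voxel step removes exactly the tumor", {
  ns <- nested_spheres(spacing = 1, r_tumor = 6, r_kidney = 14)
  removed <- removed_region(ns$kidney, ns$tumor, margin = 0.4)
  expect_identical(removed$data, ns$tumor$data)
})

test_that("removed volume matches the closed ball around the tumor", {
  ns <- nested_spheres()
  removed <- removed_region(ns$kidney, ns$tumor, margin = 5)
  analytic <- 4 / 3 * pi * 15^3
  expect_lt(abs(mask_volume_mm3(removed) - analytic) / analytic, 0.03)
  # containment invariants
  expect_true(all(removed$data[ns$tumor$data]))
  expect_true(all(ns$kidney$data[removed$data] | ns$tumor$data[removed$data]))
})

test_that("removed regions nest monotonically across margins", {
  ph <- generate_phantom(random_phantom_spec(2.2, rng_seed = 31))
  dist <- distance_from_mask(ph$tumor)
  prev <- NULL
  for (m in c(1, 2, 3, 4, 5)) {
    cur <- removed_region(ph$kidney, ph$tumor, m, tumor_distance = dist)
    if (!is.null(prev)) expect_true(all(cur$data[prev$data]))
    prev <- cur
  }
  expect_error(removed_region(ph$kidney, ph$tumor, 0), "margin")
  empty <- label_mask(array(FALSE, dim(ph$tumor$data)), ph$tumor$spacing)
  expect_error(removed_region(ph$kidney, empty, 3), "empty tumor")
})

test_that("interior resection surface is closed with the analytic area", {
  ns <- nested_spheres()
  removed <- removed_region(ns$kidney, ns$tumor, margin = 5)
  surf <- resection_surface(ns$kidney, removed)
  expect_true(is_watertight(surf))
  # the raw iso-surface carries the staircase area excess of voxelized
  # surfaces; a few volume-preserving smoothing passes recover the
  # geometric area of the sphere
  smoothed <- smooth_mesh(surf, 5)
  analytic_area <- 4 * pi * 15^2
  expect_lt(abs(mesh_area(smoothed) - analytic_area) / analytic_area, 0.05)
})

test_that("capsule faces are excluded for a protruding tumor", {
  # tumor hemisphere sticking out of the kidney boundary
  spacing <- 1
  n <- 36
  xs <- (seq_len(n) - 1) * spacing
  ctr <- (n - 1) * spacing / 2
  qk <- outer(outer((xs - ctr)^2, (xs - ctr)^2, "+"), (xs - ctr)^2, "+")
  kidney <- label_mask(qk < 14^2, rep(spacing, 3))
  qt <- outer(outer((xs - ctr - 12)^2, (xs - ctr)^2, "+"), (xs - ctr)^2, "+")
  tumor_arr <- qt < 6^2
  tumor <- label_mask(tumor_arr, rep(spacing, 3))
  removed <- removed_region(kidney, tumor, margin = 2)
  full <- extract_mesh(removed)
  surf <- resection_surface(kidney, removed)
  expect_lt(nrow(surf$faces), nrow(full$faces))
  expect_gt(nrow(surf$faces), 0)
})

test_that("no remnant interface yields an empty surface with a warning", {
  sph <- digitized_sphere(8, 1)
  expect_warning(surf <- resection_surface(sph$mask, sph$mask), "empty")
  expect_identical(nrow(surf$faces), 0L)
})

test_that("opening detection reports intersection, centroid and extent", {
  d <- c(12, 12, 12)
  a <- array(FALSE, d); a[3:5, 3:5, 3:5] <- TRUE
  b <- array(FALSE, d); b[8:10, 8:10, 8:10] <- TRUE
  sp <- c(2, 1, 1)
  res <- detect_opening(label_mask(a, sp), label_mask(b, sp))
  expect_false(res$open)
  expect_identical(res$voxel_count, 0L)
  expect_null(res$centroid)
  expect_null(res$extent_mm)

  b2 <- array(FALSE, d); b2[6, 6, 6] <- TRUE
  a2 <- a; a2[6, 6, 6] <- TRUE
  one <- detect_opening(label_mask(a2, sp), label_mask(b2, sp))
  expect_true(one$open)
  expect_identical(one$voxel_count, 1L)
  expect_equal(one$centroid, c(10, 5, 5))
  expect_equal(one$extent_mm, 0)
})

test_that("opening extent via boundary reduction equals the direct diameter", {
  d <- c(40, 15, 15)
  a <- array(TRUE, d)
  blob <- array(FALSE, d); blob[2:39, 2:13, 2:13] <- TRUE
  sp <- c(0.9, 1.1, 0.7)
  res <- detect_opening(label_mask(blob, sp), label_mask(a, sp))
  # diameter of a solid box: corner-to-corner diagonal
  pts <- sweep(which(blob, arr.ind = TRUE) - 1, 2, sp, "*")
  rng <- apply(pts, 2, range)
  expect_equal(res$extent_mm, sqrt(sum((rng[2, ] - rng[1, ])^2)))
  expect_gt(res$voxel_count, 5000)
})

test_that("opening centroid falls at the tube's closest approach", {
  ph <- generate_phantom(default_phantom_spec())
  res <- plan_all_margins(ph$kidney, ph$tumor, ph$tract, ct = ph$volume)
  expect_identical(res$report$status_text, "Open with 3 mm margin")
  expect_identical(res$report$min_opening_margin_mm, 3)
  # voxel-center distance may exceed the analytic gap by up to one step
  expect_gte(res$report$min_tract_distance_mm, 2.5 - 1e-9)
  expect_lt(res$report$min_tract_distance_mm, 2.5 + 0.8 + 1e-9)

  spec <- ph$spec
  # analytic closest point on the tube surface (toward the tumor center)
  axis_y <- spec$tract_centerline[1, 2]
  A <- c(spec$tumor_center[1], axis_y, spec$tract_centerline[1, 3])
  to_tumor <- (spec$tumor_center - A) / sqrt(sum((spec$tumor_center - A)^2))
  closest <- A + spec$tract_radius * to_tumor
  opening3 <- res$report$per_margin[[3]]
  expect_true(opening3$open)
  expect_lt(sqrt(sum((opening3$centroid - closest)^2)), 2 * 0.8)
})

test_that("distant tract reports the not-open sentinel", {
  ph <- generate_phantom(random_phantom_spec(6.5, rng_seed = 77))
  res <- plan_all_margins(ph$kidney, ph$tumor, ph$tract)
  expect_identical(res$report$status_text, "Not open with 5 mm margin")
  expect_null(res$report$min_opening_margin_mm)
  expect_false(any(vapply(res$report$per_margin, `[[`, logical(1), "open")))
})

test_that("a tract touching the tumor opens at the first margin", {
  ph <- generate_phantom(random_phantom_spec(0.3, rng_seed = 13))
  res <- plan_all_margins(ph$kidney, ph$tumor, ph$tract)
  expect_identical(res$report$min_opening_margin_mm, 1)
  expect_identical(res$report$status_text, "Open with 1 mm margin")
})

test_that("overlapping tumor and tract trigger the distance-0 warning", {
  d <- c(10, 10, 10)
  k <- array(TRUE, d)
  t1 <- array(FALSE, d); t1[4:6, 4:6, 4:6] <- TRUE
  sp <- c(1, 1, 1)
  expect_warning(
    res <- plan_all_margins(label_mask(k, sp), label_mask(t1, sp),
                            label_mask(t1, sp)),
    "tract inside tumor")
  expect_identical(res$report$min_opening_margin_mm, 1)
  expect_identical(res$report$min_tract_distance_mm, 0)
})

test_that("per-margin plans equal independently recomputed removed regions", {
  ph <- generate_phantom(random_phantom_spec(3.7, rng_seed = 55))
  res <- plan_all_margins(ph$kidney, ph$tumor, ph$tract)
  for (p in res$plans) {
    indep <- removed_region(ph$kidney, ph$tumor, p$margin_mm)
    expect_identical(p$removed_region$data, indep$data)
    # plan invariants: tumor <= removed <= kidney | tumor; remnant disjoint
    expect_true(all(p$removed_region$data[ph$tumor$data]))
    expect_true(all((ph$kidney$data | ph$tumor$data)[p$removed_region$data]))
    expect_false(any(p$remnant_kidney$data & p$removed_region$data))
  }
})

test_that("schedule logic matches a brute-force pairwise distance oracle", {
  set.seed(61)
  for (trial in 1:6) {
    d <- c(20, 18, 16)
    sp <- round(runif(3, 0.5, 1.4), 2)
    kid <- array(TRUE, d)
    tum <- array(FALSE, d)
    ctr <- sample(5:9, 3, replace = TRUE)
    tum[(ctr[1] - 2):(ctr[1] + 2), (ctr[2] - 2):(ctr[2] + 2),
        (ctr[3] - 1):(ctr[3] + 1)] <- TRUE
    tra <- array(FALSE, d)
    off <- sample(3:6, 1)
    lo <- ctr[2] + 2 + off
    tra[, lo:min(lo + 1, d[2]), (ctr[3]):(ctr[3] + 1)] <- TRUE
    res <- plan_all_margins(label_mask(kid, sp), label_mask(tum, sp),
                            label_mask(tra, sp))
    # brute force min pairwise voxel-center distance
    pt <- sweep(which(tum, arr.ind = TRUE) - 1, 2, sp, "*")
    pu <- sweep(which(tra, arr.ind = TRUE) - 1, 2, sp, "*")
    bf <- sqrt(min(vapply(seq_len(nrow(pu)), function(i) {
      min(rowSums(sweep(pt, 2, pu[i, ])^2))
    }, numeric(1))))
    expect_equal(res$report$min_tract_distance_mm, bf, tolerance = 1e-9)
    sched <- res$report$margins_mm
    open_flags <- vapply(res$report$per_margin, `[[`, logical(1), "open")
    expect_identical(open_flags, sched >= bf - 1e-12)
    expected_margin <- if (any(sched >= bf)) min(sched[sched >= bf]) else NULL
    expect_identical(res$report$min_opening_margin_mm, expected_margin)
    # open status monotone along the schedule
    expect_false(is.unsorted(open_flags))
  }
})

test_that("margin schedules are validated", {
  expect_error(margin_schedule(c(2, 1)), "increasing")
  expect_error(margin_schedule(c(-1, 2)), "positive")
  expect_identical(margin_schedule()$margins, c(1, 2, 3, 4, 5))
})
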