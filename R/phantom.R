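#' Specification of a synthetic delay-phase CT phantom
#'
#' The phantom emulates the contrast pattern this pipeline relies on: a
#' mid-intensity kidney parenchyma (ellipsoid), an embedded lower-intensity
#' tumor (sphere), and a contrast-bright urinary tract (tube around a
#' polyline centerline) whose CT value exceeds 420, so any threshold in
#' the usual per-patient range 350-420 isolates it. Gaussian noise with a
#' reproducible seed is added on top. All geometry is in mm world
#' coordinates, so every pairwise distance has a closed form against which
#' the pipeline can be checked.
#'
#' @param shape integer length-3 grid dimensions.
#' @param spacing voxel spacing, mm.
#' @param kidney_center,kidney_semiaxes ellipsoid geometry, mm.
#' @param tumor_center,tumor_radius sphere geometry, mm.
#' @param tract_centerline n-by-3 matrix of mm points; consecutive rows are
#'   tube segments (>= 1 segment; 3 segments by default mimic the
#'   calyx-to-pelvis branching minimally).
#' @param tract_radius tube radius, mm.
#' @param intensities named list: `background`, `parenchyma`, `tumor`,
#'   `tract` CT values. Tract must exceed 420; tumor must differ from
#'   parenchyma by at least 3 noise standard deviations.
#' @param noise_sd Gaussian noise standard deviation, CT units.
#' @param rng_seed integer seed governing noise (and annotation sampling).
#' @return A `phantom_spec`.
#' @export
phantom_spec <- function(shape, spacing,
                         kidney_center, kidney_semiaxes,
                         tumor_center, tumor_radius,
                         tract_centerline, tract_radius,
                         intensities = list(background = 0, parenchyma = 150,
                                            tumor = 60, tract = 500),
                         noise_sd = 15, rng_seed = 1L) {
  shape <- as.integer(shape)
  spacing <- as_spacing(spacing)
  stopifnot(length(shape) == 3L, all(shape >= 2L))
  kidney_center <- as_vec3(kidney_center, "kidney_center")
  kidney_semiaxes <- as_vec3(kidney_semiaxes, "kidney_semiaxes")
  tumor_center <- as_vec3(tumor_center, "tumor_center")
  tract_centerline <- as.matrix(tract_centerline)
  storage.mode(tract_centerline) <- "double"
  if (ncol(tract_centerline) != 3L || nrow(tract_centerline) < 2L) {
    stop("tract_centerline must be an n-by-3 matrix with n >= 2", call. = FALSE)
  }
  if (any(kidney_semiaxes <= 0) || tumor_radius <= 0 || tract_radius <= 0) {
    stop("kidney semi-axes, tumor radius and tract radius must be > 0",
         call. = FALSE)
  }
  if (intensities$tract <= 420) {
    stop("tract intensity must exceed 420 so any threshold r in [350, 420] segments it",
         call. = FALSE)
  }
  if (abs(intensities$tumor - intensities$parenchyma) < 3 * noise_sd) {
    stop("tumor intensity must differ from parenchyma by >= 3 * noise_sd",
         call. = FALSE)
  }
  rel <- (tumor_center - kidney_center) / kidney_semiaxes
  if (sum(rel^2) >= 1) {
    stop("tumor center must lie inside the kidney ellipsoid", call. = FALSE)
  }
  cl_rel <- sweep(sweep(tract_centerline, 2, kidney_center, "-"), 2,
                  pmax(kidney_semiaxes - tract_radius, 1e-6), "/")
  if (any(rowSums(cl_rel^2) >= 1)) {
    stop("tract tube must lie inside the kidney ellipsoid (centerline too close to the boundary)",
         call. = FALSE)
  }
  structure(list(shape = shape, spacing = spacing,
                 kidney_center = kidney_center,
                 kidney_semiaxes = kidney_semiaxes,
                 tumor_center = tumor_center, tumor_radius = tumor_radius,
                 tract_centerline = tract_centerline,
                 tract_radius = tract_radius,
                 intensities = intensities, noise_sd = noise_sd,
                 rng_seed = as.integer(rng_seed)),
            class = "phantom_spec")
}

#' Default clinical-scale phantom
#'
#' A 136x92x80 grid at 0.8 mm spacing holding a 50x30x25 mm semi-axis
#' kidney, a 12 mm radius tumor, and a 3-segment, 2 mm radius urinary
#' tract whose surface passes exactly 2.5 mm from the tumor surface (the
#' closed-form sphere-to-segment gap), so the expected minimum opening
#' margin on the default 1-5 mm schedule is 3 mm.
#'
#' @param noise_sd,rng_seed see [phantom_spec()].
#' @return A `phantom_spec`.
#' @export
default_phantom_spec <- function(noise_sd = 15, rng_seed = 1L) {
  shape <- c(136L, 92L, 80L)
  spacing <- c(0.8, 0.8, 0.8)
  K <- (shape - 1) * spacing / 2
  # the sub-voxel y-offset keeps the tumor-tract lattice phase where the
  # voxel-center distance (2.88 mm) resolves the 2.5 mm gap into the 3 mm
  # schedule bin; grid-symmetric placement sits on a phase that overshoots
  tumor_center <- K + c(18, 0.3, 6)
  tumor_radius <- 12
  tract_radius <- 2
  gap <- 2.5
  # main segment runs along x, offset in y so the perpendicular distance
  # from the tumor center is exactly the sum of radii plus the gap
  reach <- tumor_radius + tract_radius + gap        # 16.5
  y0 <- sqrt(reach^2 - 6^2)                         # tumor z-offset is 6
  centerline <- rbind(c(K[1] - 30, tumor_center[2] + y0, K[3]),
                      c(K[1] + 30, tumor_center[2] + y0, K[3]),
                      c(K[1] + 34, tumor_center[2] + y0 - 4, K[3] + 4),
                      c(K[1] + 38, tumor_center[2] + y0 - 8, K[3] + 8))
  phantom_spec(shape = shape, spacing = spacing,
               kidney_center = K, kidney_semiaxes = c(50, 30, 25),
               tumor_center = tumor_center, tumor_radius = tumor_radius,
               tract_centerline = centerline, tract_radius = tract_radius,
               noise_sd = noise_sd, rng_seed = rng_seed)
}

#' Randomized compact phantom with a prescribed tumor-tract surface gap
#'
#' Used for margin-recovery studies: a 128^3 grid at 0.5 mm spacing with a
#' randomly placed and sized tumor and a straight tract tube whose
#' perpendicular offset is set so the analytic surface-to-surface gap
#' equals `gap_mm` exactly.
#'
#' @param gap_mm desired tumor-to-tract surface distance, mm.
#' @param rng_seed integer seed for the geometry and the noise.
#' @param noise_sd see [phantom_spec()].
#' @return A `phantom_spec` whose `analytic` gap is `gap_mm`.
#' @export
random_phantom_spec <- function(gap_mm, rng_seed, noise_sd = 15) {
  stopifnot(gap_mm > 0)
  with_seed(rng_seed, {
    shape <- c(128L, 128L, 128L)
    spacing <- c(0.5, 0.5, 0.5)
    K <- (shape - 1) * spacing / 2
    tumor_radius <- runif(1, 6, 8.5)
    tumor_center <- K + c(runif(1, 2, 5), runif(1, -2, 2), runif(1, -2, 2))
    tract_radius <- runif(1, 1.2, 1.8)
    reach <- tumor_radius + tract_radius + gap_mm
    phi <- runif(1, 0, 2 * pi)
    # straight tube along x, offset perpendicular to it by exactly `reach`,
    # spanning the tumor's x position so the gap is the perpendicular one
    off <- c(0, reach * cos(phi), reach * sin(phi))
    p0 <- c(K[1] - 14, tumor_center[2] + off[2], tumor_center[3] + off[3])
    p1 <- c(K[1] + 12, tumor_center[2] + off[2], tumor_center[3] + off[3])
    phantom_spec(shape = shape, spacing = spacing,
                 kidney_center = K, kidney_semiaxes = c(29, 28, 27),
                 tumor_center = tumor_center, tumor_radius = tumor_radius,
                 tract_centerline = rbind(p0, p1), tract_radius = tract_radius,
                 noise_sd = noise_sd, rng_seed = rng_seed)
  })
}

#' Generate a phantom CT volume with ground-truth masks
#'
#' Voxelizes the analytic shapes (a voxel belongs to a mask iff its center
#' lies inside the shape), assigns intensities, adds seeded Gaussian
#' noise, and reports the exact analytic minimum distance between the
#' tumor sphere surface and the tract tube surface (closed-form
#' point-to-segment minimisation; independent of the voxel grid).
#'
#' @param spec a [phantom_spec()].
#' @return List: `volume` ([ct_volume()]), `kidney` / `tumor` / `tract`
#'   ([label_mask()]s), `analytic_min_distance` (mm), `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$shape
  sp <- spec$spacing
  xs <- (seq_len(d[1]) - 1) * sp[1]
  ys <- (seq_len(d[2]) - 1) * sp[2]
  zs <- (seq_len(d[3]) - 1) * sp[3]

  kidney <- ellipsoid_mask(xs, ys, zs, spec$kidney_center, spec$kidney_semiaxes)
  tumor <- ellipsoid_mask(xs, ys, zs, spec$tumor_center, rep(spec$tumor_radius, 3))
  tract <- tube_mask(xs, ys, zs, spec$tract_centerline, spec$tract_radius)

  ints <- spec$intensities
  vol <- array(ints$background, d)
  vol[kidney] <- ints$parenchyma
  vol[tumor] <- ints$tumor
  vol[tract] <- ints$tract
  if (spec$noise_sd > 0) {
    vol <- vol + with_seed(spec$rng_seed,
                           array(rnorm(prod(d), sd = spec$noise_sd), d))
  }

  gaps <- apply_segments(spec$tract_centerline, function(a, b) {
    point_segment_distance(spec$tumor_center, a, b)
  })
  analytic <- min(gaps) - spec$tumor_radius - spec$tract_radius

  list(volume = ct_volume(vol, spacing = sp),
       kidney = label_mask(kidney, spacing = sp),
       tumor = label_mask(tumor, spacing = sp),
       tract = label_mask(tract, spacing = sp),
       analytic_min_distance = analytic,
       spec = spec)
}

ellipsoid_mask <- function(xs, ys, zs, center, semiaxes) {
  u2 <- ((xs - center[1]) / semiaxes[1])^2
  v2 <- ((ys - center[2]) / semiaxes[2])^2
  w2 <- ((zs - center[3]) / semiaxes[3])^2
  q <- outer(outer(u2, v2, "+"), w2, "+")
  q < 1
}

tube_mask <- function(xs, ys, zs, centerline, radius) {
  d <- c(length(xs), length(ys), length(zs))
  mask <- array(FALSE, d)
  segs <- cbind(centerline[-nrow(centerline), , drop = FALSE],
                centerline[-1, , drop = FALSE])
  for (s in seq_len(nrow(segs))) {
    a <- segs[s, 1:3]; b <- segs[s, 4:6]
    lo <- pmin(a, b) - radius; hi <- pmax(a, b) + radius
    ii <- which(xs >= lo[1] & xs <= hi[1])
    jj <- which(ys >= lo[2] & ys <= hi[2])
    kk <- which(zs >= lo[3] & zs <= hi[3])
    if (!length(ii) || !length(jj) || !length(kk)) next
    g <- as.matrix(expand.grid(x = xs[ii], y = ys[jj], z = zs[kk]))
    dist <- points_segment_distance(g, a, b)
    idx <- as.matrix(expand.grid(i = ii, j = jj, k = kk))
    mask[idx[dist <= radius, , drop = FALSE]] <- TRUE
  }
  mask
}

apply_segments <- function(centerline, fn) {
  n <- nrow(centerline)
  vapply(seq_len(n - 1), function(s) {
    fn(centerline[s, ], centerline[s + 1, ])
  }, numeric(1))
}

point_segment_distance <- function(p, a, b) {
  ab <- b - a
  t <- sum((p - a) * ab) / sum(ab^2)
  t <- min(max(t, 0), 1)
  sqrt(sum((p - (a + t * ab))^2))
}

points_segment_distance <- function(pts, a, b) {
  ab <- b - a
  t <- (sweep(pts, 2, a, "-") %*% ab) / sum(ab^2)
  t <- pmin(pmax(as.numeric(t), 0), 1)
  closest <- outer(t, ab) + rep(a, each = length(t))
  sqrt(rowSums((pts - closest)^2))
}

#' Simulate the user annotations for a phantom
#'
#' Produces the three annotation sets a clinician would supply, from the
#' ground-truth geometry: kidney scribbles sampled at least 2 mm clear of
#' the kidney boundary (foreground inside, background outside), tract
#' seeds on centerline voxels, and tumor contours as exact analytic
#' circles of the sphere on equally spaced axial planes. The kidney is
#' the whole organ, so foreground scribbles are stratified across its
#' internal intensity populations: most in parenchyma plus a few inside
#' the tumor and the contrast-bright tract, mirroring how inside points
#' are spread over several cross-sections in practice.
#'
#' @param phantom output of [generate_phantom()].
#' @param n_scribbles scribbles per class (default 20).
#' @param n_contours number of axial tumor contours (default 5).
#' @param threshold_r region-growing threshold stored with the seeds
#'   (default 385, the middle of the usual 350-420 range).
#' @param clearance_mm minimum scribble distance from the kidney boundary.
#' @return List: `scribbles` ([scribble_set()]), `seeds` ([seed_set()]),
#'   `contours` ([contour_stack()]).
#' @export
generate_annotations <- function(phantom, n_scribbles = 20L, n_contours = 5L,
                                 threshold_r = 385, clearance_mm = 2) {
  spec <- phantom$spec
  kidney <- phantom$kidney
  d <- dim(kidney$data)

  not_kidney <- label_mask(!kidney$data, spacing = kidney$spacing,
                           origin = kidney$origin)
  dist_inside <- distance_from_mask(not_kidney)   # depth inside the kidney
  dist_outside <- distance_from_mask(kidney)      # distance from the kidney
  deep <- kidney$data & dist_inside$values >= clearance_mm
  n_struct <- max(2L, n_scribbles %/% 6L)
  pools <- list(parenchyma = which(deep & !phantom$tumor$data &
                                     !phantom$tract$data),
                tumor = which(deep & phantom$tumor$data),
                tract = which(deep & phantom$tract$data))
  counts <- c(parenchyma = n_scribbles - 2L * n_struct,
              tumor = n_struct, tract = n_struct)
  bg_pool <- which(!kidney$data & dist_outside$values >= clearance_mm)
  if (any(lengths(pools) < counts) || length(bg_pool) < n_scribbles) {
    stop("shapes too thin to admit the scribble clearance", call. = FALSE)
  }
  scribbles <- with_seed(spec$rng_seed + 1L, {
    fg <- do.call(rbind, lapply(names(pools), function(nm) {
      arrayInd(sample(pools[[nm]], counts[[nm]]), d) - 1L
    }))
    bg <- arrayInd(sample(bg_pool, n_scribbles), d) - 1L
    scribble_set(fg, bg)
  })

  # seeds: voxels nearest the centerline vertices and segment midpoints
  cl <- spec$tract_centerline
  mids <- (cl[-nrow(cl), , drop = FALSE] + cl[-1, , drop = FALSE]) / 2
  seed_pts <- rbind(cl, mids)
  seed_idx <- unique(round(world_to_index(seed_pts, kidney)))
  seeds <- seed_set(seed_idx, threshold_r)

  # contours: analytic circles of the tumor sphere on axial planes
  ctr <- spec$tumor_center
  r <- spec$tumor_radius
  sz <- kidney$spacing[3]
  zoffs <- seq(-0.75, 0.75, length.out = n_contours) * r
  planes <- unique(round((ctr[3] + zoffs) / sz))
  planes <- planes[abs(planes * sz - ctr[3]) < r]
  theta <- seq(0, 2 * pi, length.out = 25L)[-25L]
  contours <- lapply(planes, function(k) {
    rc <- sqrt(r^2 - (k * sz - ctr[3])^2)
    list(plane_axis = 2L, plane_index = as.integer(k),
         points = cbind((ctr[1] + rc * cos(theta)) / kidney$spacing[1],
                        (ctr[2] + rc * sin(theta)) / kidney$spacing[2]))
  })
  list(scribbles = scribbles, seeds = seeds,
       contours = contour_stack(contours))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG stream afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
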