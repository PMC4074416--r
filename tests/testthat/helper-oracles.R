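# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths: brute-force loops and closed forms
# only, so agreement is evidence rather than tautology.

dice <- function(a, b) {
  aa <- if (inherits(a, "label_mask")) a$data else a
  bb <- if (inherits(b, "label_mask")) b$data else b
  2 * sum(aa & bb) / (sum(aa) + sum(bb))
}

# All-pairs nearest-source distance, the brute-force counterpart of the
# separable distance transform.
brute_force_edt <- function(mask_array, spacing) {
  d <- dim(mask_array)
  src <- which(mask_array, arr.ind = TRUE)
  src_mm <- sweep(src - 1, 2, spacing, "*")
  out <- array(NA_real_, d)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    p <- c(i - 1, j - 1, k - 1) * spacing
    out[i, j, k] <- sqrt(min(colSums((t(src_mm) - p)^2)))
  }
  out
}

# Threshold-then-flood-fill region growing oracle: repeated dilation of the
# seed set inside the supra-threshold set, in plain R.
flood_fill_oracle <- function(values, seeds0, r, connectivity = 6L) {
  d <- dim(values)
  supra <- values > r
  reach <- array(FALSE, d)
  reach[seeds0 + 1L] <- TRUE
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6L) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  repeat {
    frontier <- which(reach, arr.ind = TRUE)
    grown <- reach
    for (o in seq_len(nrow(offs))) {
      nb <- sweep(frontier, 2, offs[o, ], "+")
      ok <- nb[, 1] >= 1 & nb[, 2] >= 1 & nb[, 3] >= 1 &
        nb[, 1] <= d[1] & nb[, 2] <= d[2] & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      grown[nb[supra[nb], , drop = FALSE]] <- TRUE
    }
    if (identical(grown, reach)) break
    reach <- grown
  }
  reach & supra
}

# Voxelized sphere: radius mm, isotropic spacing, centered in an n^3 grid.
digitized_sphere <- function(radius, spacing, n = NULL) {
  if (is.null(n)) n <- ceiling(2 * radius / spacing) + 6
  xs <- (seq_len(n) - 1) * spacing
  ctr <- (n - 1) * spacing / 2
  q <- outer(outer((xs - ctr)^2, (xs - ctr)^2, "+"), (xs - ctr)^2, "+")
  list(mask = label_mask(q < radius^2, rep(spacing, 3)),
       center = rep(ctr, 3), n = n)
}

# Circular cross-sections of a sphere on axial planes, as a contour_stack.
sphere_contours <- function(radius, center_mm, planes_mm, spacing,
                            npts = 24L) {
  th <- seq(0, 2 * pi, length.out = npts + 1L)[-(npts + 1L)]
  contour_stack(lapply(planes_mm, function(zmm) {
    rc <- sqrt(radius^2 - (zmm - center_mm[3])^2)
    list(plane_axis = 2L, plane_index = as.integer(round(zmm / spacing[3])),
         points = cbind((center_mm[1] + rc * cos(th)) / spacing[1],
                        (center_mm[2] + rc * sin(th)) / spacing[2]))
  }))
}

# Dense samples of the zero level set of a field array: sign changes along
# grid lines, located by linear interpolation. Returns mm points.
level_set_points <- function(vals, coords) {
  pts <- NULL
  d <- dim(vals)
  sgn <- vals < 0
  for (ax in 1:3) {
    n <- d[ax]
    idx_a <- lapply(d, seq_len); idx_a[[ax]] <- 1:(n - 1)
    idx_b <- lapply(d, seq_len); idx_b[[ax]] <- 2:n
    cross <- sgn[idx_a[[1]], idx_a[[2]], idx_a[[3]]] !=
      sgn[idx_b[[1]], idx_b[[2]], idx_b[[3]]]
    hits <- which(cross, arr.ind = TRUE)
    if (nrow(hits) == 0L) next
    for (rr in seq_len(nrow(hits))) {
      a <- hits[rr, ]; b <- a; b[ax] <- b[ax] + 1L
      va <- vals[a[1], a[2], a[3]]; vb <- vals[b[1], b[2], b[3]]
      t0 <- va / (va - vb)
      p <- c(coords[[1]][a[1]], coords[[2]][a[2]], coords[[3]][a[3]])
      p[ax] <- coords[[ax]][a[ax]] +
        t0 * (coords[[ax]][b[ax]] - coords[[ax]][a[ax]])
      pts <- rbind(pts, p)
    }
  }
  pts
}

# Independent graph-cut energy: unary from scratch-written Gaussian KDE,
# boundary term by explicit neighbour loops.
independent_gc_energy <- function(volume, scribbles, mask_array,
                                  lambda = 1, sigma = NULL,
                                  big = NULL) {
  vals <- volume$data
  d <- dim(vals)
  kde <- function(x, sample) {
    bw <- if (length(sample) >= 2 && sd(sample) > 0) bw.nrd0(sample) else 1
    rowMeans(outer(x, sample, function(a, b) dnorm(a, b, bw)))
  }
  fg_int <- vals[scribbles$foreground + 1L]
  bg_int <- vals[scribbles$background + 1L]
  u_fg <- -log(pmax(kde(as.numeric(vals), fg_int), 1e-12))
  u_bg <- -log(pmax(kde(as.numeric(vals), bg_int), 1e-12))
  lab <- as.logical(mask_array)
  e <- sum(u_fg[lab]) + sum(u_bg[!lab])
  offs <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  diffs <- c()
  pair_terms <- 0
  for (o in 1:3) {
    sh <- offs[o, ]
    ia <- lapply(d, seq_len); ia[[o]] <- 1:(d[o] - 1)
    ib <- lapply(d, seq_len); ib[[o]] <- 2:d[o]
    va <- vals[ia[[1]], ia[[2]], ia[[3]]]
    vb <- vals[ib[[1]], ib[[2]], ib[[3]]]
    diffs <- c(diffs, abs(as.numeric(va) - as.numeric(vb)))
  }
  if (is.null(sigma)) {
    sigma <- median(diffs)
    if (sigma <= 0) sigma <- 1e-6
  }
  la <- array(lab, d)
  for (o in 1:3) {
    ia <- lapply(d, seq_len); ia[[o]] <- 1:(d[o] - 1)
    ib <- lapply(d, seq_len); ib[[o]] <- 2:d[o]
    va <- vals[ia[[1]], ia[[2]], ia[[3]]]
    vb <- vals[ib[[1]], ib[[2]], ib[[3]]]
    laa <- la[ia[[1]], ia[[2]], ia[[3]]]
    lbb <- la[ib[[1]], ib[[2]], ib[[3]]]
    w <- lambda * exp(-(va - vb)^2 / (2 * sigma^2)) /
      (1 + volume$spacing[o])
    pair_terms <- pair_terms + sum(w[laa != lbb])
  }
  viol <- sum(!la[scribbles$foreground + 1L]) +
    sum(la[scribbles$background + 1L])
  if (is.null(big)) big <- 1e9
  e + pair_terms + viol * big
}

# Ellipsoid phantom for segmentation tests: value `fg_value` inside, 0
# outside, optional Gaussian noise.
ellipsoid_volume <- function(n = 24, semiaxes = c(8, 6, 5), fg_value = 100,
                             noise_sd = 0, seed = 1) {
  xs <- seq_len(n) - 1
  ctr <- (n - 1) / 2
  q <- outer(outer(((xs - ctr) / semiaxes[1])^2,
                   ((xs - ctr) / semiaxes[2])^2, "+"),
             ((xs - ctr) / semiaxes[3])^2, "+")
  gt <- q < 1
  vals <- array(ifelse(gt, fg_value, 0), c(n, n, n))
  if (noise_sd > 0) {
    set.seed(seed)
    vals <- vals + array(rnorm(n^3, sd = noise_sd), c(n, n, n))
  }
  list(volume = ct_volume(vals, c(1, 1, 1)), truth = gt)
}

# Scribbles drawn from the ground truth of ellipsoid_volume.
ellipsoid_scribbles <- function(truth, n_each = 20, seed = 2) {
  set.seed(seed)
  d <- dim(truth)
  interior <- which(truth)
  exterior <- which(!truth)
  scribble_set(arrayInd(sample(interior, n_each), d) - 1L,
               arrayInd(sample(exterior, n_each), d) - 1L)
}
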