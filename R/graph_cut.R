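#' Parameters of the scribble-driven graph-cut energy
#'
#' The kidney is segmented by minimising a two-term energy over binary
#' voxel labelings: a region term (negative log-likelihood of each voxel's
#' CT value under Gaussian kernel density estimates built from the
#' foreground and background scribble intensities, with hard terms at the
#' scribbles themselves) plus a boundary term
#' `lambda * exp(-(dI)^2 / (2 sigma^2)) / (1 + d_mm)` summed over
#' neighbouring voxel pairs, where `dI` is the intensity difference and
#' `d_mm` the physical distance between voxel centers. The minimiser is
#' found exactly by max-flow/min-cut on the voxel graph.
#'
#' @param lambda_region non-negative weight of the boundary term relative
#'   to the region term (dimensionless, default 1).
#' @param sigma_boundary intensity scale of the boundary term in CT units;
#'   `NULL` (default) estimates it as the median absolute intensity step
#'   between neighbouring voxels along the grid axes.
#' @param neighborhood 6 or 26.
#' @return A `graph_cut_params` object.
#' @export
graph_cut_params <- function(lambda_region = 1, sigma_boundary = NULL,
                             neighborhood = 6L) {
  if (lambda_region < 0) stop("lambda_region must be >= 0", call. = FALSE)
  if (!is.null(sigma_boundary) && sigma_boundary <= 0) {
    stop("sigma_boundary must be > 0", call. = FALSE)
  }
  if (!neighborhood %in% c(6L, 26L)) {
    stop("neighborhood must be 6 or 26", call. = FALSE)
  }
  structure(list(lambda_region = lambda_region,
                 sigma_boundary = sigma_boundary,
                 neighborhood = as.integer(neighborhood)),
            class = "graph_cut_params")
}

#' Graph-cut segmentation from foreground/background scribbles
#'
#' Solves the scribble-constrained labeling problem of
#' [graph_cut_params()] by a single max-flow computation
#' (Dinic blocking-flow max-flow on the voxel graph); the returned mask
#' is a global minimiser of the
#' energy among labelings that keep every foreground scribble inside and
#' every background scribble outside (the hard constraints are enforced
#' by terminal capacities exceeding the total finite energy, so they can
#' never be cut).
#'
#' @param volume a [ct_volume()].
#' @param scribbles a [scribble_set()] with all voxels inside the grid.
#' @param params a [graph_cut_params()].
#' @return A [label_mask()]. A trivial cut (all voxels foreground or all
#'   background apart from the scribbles) triggers a diagnostic warning.
#' @export
segment_graph_cut <- function(volume, scribbles, params = graph_cut_params()) {
  stopifnot(inherits(volume, "ct_volume"), inherits(scribbles, "scribble_set"),
            inherits(params, "graph_cut_params"))
  check_indices_in_grid(scribbles$foreground, volume, "foreground scribble")
  check_indices_in_grid(scribbles$background, volume, "background scribble")

  comp <- graph_cut_components(volume, scribbles, params)
  n <- length(comp$unary_fg)

  # terminal capacities: s->v pays when v is labeled background,
  # v->t pays when v is labeled foreground (plus hard scribble terms)
  cap_s <- comp$unary_bg
  cap_t <- comp$unary_fg
  cap_s[comp$fg_lin] <- cap_s[comp$fg_lin] + comp$big
  cap_t[comp$bg_lin] <- cap_t[comp$bg_lin] + comp$big

  fl <- .grid_mincut(n, comp$pairs - 1L, comp$weights, comp$weights,
                     cap_s, cap_t)
  mask <- array(fl$source_side, dim(volume$data))

  n_scrib <- nrow(scribbles$foreground) + nrow(scribbles$background)
  if (sum(mask) <= nrow(scribbles$foreground) ||
      sum(!mask) <= nrow(scribbles$background)) {
    warning(paste("trivial graph cut: segmentation collapsed onto the",
                  "scribbles; check scribble placement and parameters"))
  }
  label_mask(mask, spacing = volume$spacing, origin = volume$origin)
}

#' Evaluate the graph-cut energy of a candidate labeling
#'
#' Computes the exact objective minimised by [segment_graph_cut()] for an
#' arbitrary mask: region terms of the chosen labels, boundary terms over
#' label-discontinuous neighbour pairs, and the hard scribble penalty for
#' any violated scribble. Useful for optimality diagnostics: the
#' segmentation result never has higher energy than any other labeling.
#'
#' @inheritParams segment_graph_cut
#' @param mask a [label_mask()] labeling to score (TRUE = foreground).
#' @return The energy (a scalar; includes `big` for each violated scribble).
#' @export
graph_cut_energy <- function(volume, scribbles, mask,
                             params = graph_cut_params()) {
  check_aligned(volume, mask, "volume/mask")
  comp <- graph_cut_components(volume, scribbles, params)
  lab <- as.logical(mask$data)
  e <- sum(comp$unary_fg[lab]) + sum(comp$unary_bg[!lab])
  cut <- lab[comp$pairs[, 1]] != lab[comp$pairs[, 2]]
  e <- e + sum(comp$weights[cut])
  e + comp$big * (sum(!lab[comp$fg_lin]) + sum(lab[comp$bg_lin]))
}

# Shared energy ingredients: KDE unaries, neighbour pairs and weights,
# scribble linear indices, and the hard-constraint capacity `big`.
graph_cut_components <- function(volume, scribbles, params) {
  d <- dim(volume$data)
  vals <- as.numeric(volume$data)

  fg_lin <- linear_index(scribbles$foreground, d)
  bg_lin <- linear_index(scribbles$background, d)

  unary_fg <- -log(pmax(kde_density(vals, vals[fg_lin]), 1e-12))
  unary_bg <- -log(pmax(kde_density(vals, vals[bg_lin]), 1e-12))

  nb <- neighbor_pairs(d, params$neighborhood)
  sigma <- params$sigma_boundary
  if (is.null(sigma)) {
    di <- abs(vals[nb$pairs[, 1]] - vals[nb$pairs[, 2]])
    sigma <- stats::median(di)
    if (!is.finite(sigma) || sigma <= 0) sigma <- 1e-6
  }
  dist_mm <- sqrt(colSums((t(nb$offsets) * volume$spacing)^2))[nb$offset_id]
  di <- vals[nb$pairs[, 1]] - vals[nb$pairs[, 2]]
  weights <- params$lambda_region * exp(-di^2 / (2 * sigma^2)) / (1 + dist_mm)

  big <- sum(unary_fg) + sum(unary_bg) + sum(weights) + 1
  list(unary_fg = unary_fg, unary_bg = unary_bg, pairs = nb$pairs,
       weights = weights, fg_lin = fg_lin, bg_lin = bg_lin,
       big = big, sigma = sigma)
}

# Gaussian KDE of `sample` evaluated at `x` (Silverman/nrd0 bandwidth,
# guarded for tiny or constant samples).
kde_density <- function(x, sample) {
  bw <- if (length(sample) >= 2 && stats::sd(sample) > 0) {
    stats::bw.nrd0(sample)
  } else {
    1
  }
  out <- numeric(length(x))
  for (s in sample) out <- out + stats::dnorm(x, mean = s, sd = bw)
  out / length(sample)
}

linear_index <- function(idx, d) {
  as.integer(idx[, 1] + d[1] * (idx[, 2] + d[2] * idx[, 3]) + 1)
}

# Undirected neighbour pairs of a 3D grid for 6/26 connectivity, as a
# 2-column matrix of linear indices plus the generating offsets.
neighbor_pairs <- function(d, neighborhood) {
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[rowSums(abs(offs)) > 0, ]
  if (neighborhood == 6L) offs <- offs[rowSums(abs(offs)) == 1, ]
  # keep one direction per unordered pair
  keep <- offs$dz > 0 | (offs$dz == 0 & offs$dy > 0) |
    (offs$dz == 0 & offs$dy == 0 & offs$dx > 0)
  offs <- as.matrix(offs[keep, , drop = FALSE])

  ii <- seq_len(d[1]); jj <- seq_len(d[2]); kk <- seq_len(d[3])
  pairs_list <- vector("list", nrow(offs))
  ids <- vector("list", nrow(offs))
  for (o in seq_len(nrow(offs))) {
    dx <- offs[o, 1]; dy <- offs[o, 2]; dz <- offs[o, 3]
    xi <- ii[ii + dx >= 1 & ii + dx <= d[1]]
    yj <- jj[jj + dy >= 1 & jj + dy <= d[2]]
    zk <- kk[kk + dz >= 1 & kk + dz <= d[3]]
    from <- as.vector(outer(outer(xi, (yj - 1) * d[1], "+"),
                            (zk - 1) * d[1] * d[2], "+"))
    shift <- dx + dy * d[1] + dz * d[1] * d[2]
    pairs_list[[o]] <- cbind(from, from + shift)
    ids[[o]] <- rep.int(o, length(from))
  }
  list(pairs = do.call(rbind, pairs_list), offset_id = unlist(ids),
       offsets = offs)
}
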