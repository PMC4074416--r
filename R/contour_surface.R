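#' Fit a smooth implicit surface through planar contours
#'
#' Tumors often lack a high-contrast boundary, so they are delineated by a
#' few closed contours drawn on cross-sections. This fits a continuous
#' signed scalar field whose zero level set passes through every contour
#' vertex and interpolates smoothly in between: a radial-basis expansion
#' with the triharmonic kernel `phi(r) = r^3` plus a linear polynomial,
#' constrained to 0 at contour vertices and to +/- one in-plane voxel
#' spacing at points offset along the in-plane contour normals (outside
#' positive, inside negative). The field is negative inside the tumor.
#'
#' @param contours a [contour_stack()].
#' @param smoothness non-negative ridge added to the RBF system diagonal;
#'   0 (default) gives pure interpolation ("passes through all contours"),
#'   larger values trade fidelity for smoothness.
#' @param spacing,origin grid geometry (mm) used to place contours in
#'   world coordinates; take them from the CT volume the contours were
#'   drawn on.
#' @return A `contour_surface_fit`; evaluate it with [predict()] at n-by-3
#'   world points (mm), negative inside.
#' @export
fit_contour_surface <- function(contours, smoothness = 0,
                                spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  stopifnot(inherits(contours, "contour_stack"))
  if (smoothness < 0) stop("smoothness must be >= 0", call. = FALSE)
  spacing <- as_spacing(spacing)
  origin <- as_vec3(origin, "origin")

  pts <- list()
  vals <- list()
  centroids <- matrix(numeric(0), ncol = 3)
  for (cc in contours$contours) {
    axis <- cc$plane_axis + 1L
    inplane <- setdiff(1:3, axis)
    su <- spacing[inplane[1]]
    sv <- spacing[inplane[2]]
    off_mm <- mean(c(su, sv))  # one voxel spacing, in-plane

    uv_mm <- cbind(cc$points[, 1] * su, cc$points[, 2] * sv)
    nrm <- polygon_vertex_normals(uv_mm)
    # outward side = offset point falling outside the polygon
    probe <- uv_mm + 1e-3 * off_mm * nrm
    inside <- points_in_polygon(probe, uv_mm)
    nrm[inside, ] <- -nrm[inside, , drop = FALSE]

    to3d <- function(uv) {
      out <- matrix(0, nrow(uv), 3)
      out[, inplane[1]] <- uv[, 1]
      out[, inplane[2]] <- uv[, 2]
      out[, axis] <- cc$plane_index * spacing[axis]
      sweep(out, 2, origin, "+")
    }
    pts <- c(pts, list(to3d(uv_mm),
                       to3d(uv_mm + off_mm * nrm),
                       to3d(uv_mm - off_mm * nrm)))
    vals <- c(vals, list(rep(0, nrow(uv_mm)),
                         rep(off_mm, nrow(uv_mm)),
                         rep(-off_mm, nrow(uv_mm))))
    ctr_uv <- matrix(colMeans(uv_mm), 1, 2)
    centroids <- rbind(centroids, to3d(ctr_uv))
  }
  P <- do.call(rbind, pts)
  f <- unlist(vals)
  M <- nrow(P)

  K <- triharmonic_kernel(P, P)
  diag(K) <- diag(K) + smoothness
  Q <- cbind(1, P)
  A <- rbind(cbind(K, Q), cbind(t(Q), matrix(0, 4, 4)))
  rhs <- c(f, numeric(4))
  sol <- tryCatch(solve(A, rhs), error = function(e) {
    stop(sprintf(paste0("ill-conditioned RBF system (reciprocal condition ",
                        "estimate %.3g); jitter contour points or increase ",
                        "smoothness"), rcond_estimate(A)), call. = FALSE)
  })

  structure(list(points = P, weights = sol[seq_len(M)],
                 poly = sol[M + 1:4], centroids = centroids,
                 spacing = spacing, origin = origin,
                 tol_fit = 0.25),
            class = "contour_surface_fit")
}

rcond_estimate <- function(A) {
  tryCatch(rcond(A), error = function(e) NA_real_)
}

triharmonic_kernel <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2^1.5
}

# Outward-agnostic unit normals of a closed 2D polygon at its vertices
# (average of the two adjacent edge normals; sign fixed by the caller).
polygon_vertex_normals <- function(uv) {
  n <- nrow(uv)
  nxt <- uv[c(2:n, 1), , drop = FALSE]
  prv <- uv[c(n, 1:(n - 1)), , drop = FALSE]
  e1 <- nxt - uv
  e2 <- uv - prv
  perp <- function(e) cbind(e[, 2], -e[, 1])
  nn <- perp(e1) / pmax(sqrt(rowSums(e1^2)), 1e-12) +
    perp(e2) / pmax(sqrt(rowSums(e2^2)), 1e-12)
  nn / pmax(sqrt(rowSums(nn^2)), 1e-12)
}

#' Evaluate a fitted contour surface field at world points
#' @param object a `contour_surface_fit`.
#' @param points n-by-3 matrix (or length-3 vector) of mm world positions.
#' @param ... unused.
#' @return Signed field values (negative inside).
#' @export
predict.contour_surface_fit <- function(object, points, ...) {
  p <- to_point_matrix(points)
  out <- numeric(nrow(p))
  chunk <- max(1L, floor(2e7 / nrow(object$points)))
  for (s in seq(1L, nrow(p), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(p))
    K <- triharmonic_kernel(p[s:e, , drop = FALSE], object$points)
    out[s:e] <- as.numeric(K %*% object$weights) +
      object$poly[1] + p[s:e, , drop = FALSE] %*% object$poly[2:4]
  }
  out
}

#' Contour-based tumor segmentation
#'
#' Fits the implicit surface of [fit_contour_surface()] in the volume's
#' world coordinates and labels every voxel whose center lies strictly
#' inside the zero level set (field < 0). Evaluation is restricted to a
#' padded bounding box around the contours; the tumor cannot extend past
#' it, and far-field RBF extrapolation is untrustworthy anyway.
#'
#' @param volume a [ct_volume()] (supplies grid geometry).
#' @param contours a [contour_stack()].
#' @param smoothness see [fit_contour_surface()].
#' @return A [label_mask()].
#' @export
segment_contour_based <- function(volume, contours, smoothness = 0) {
  stopifnot(inherits(volume, "ct_volume"))
  fit <- fit_contour_surface(contours, smoothness,
                             spacing = volume$spacing, origin = volume$origin)
  d <- dim(volume$data)
  lo_w <- apply(fit$points, 2, min)
  hi_w <- apply(fit$points, 2, max)
  pad <- max(hi_w - lo_w) / 2 + 2 * max(volume$spacing)
  lo <- pmax(floor(world_to_index(lo_w - pad, volume)), 0)
  hi <- pmin(ceiling(world_to_index(hi_w + pad, volume)), d - 1)

  ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
  grid_idx <- as.matrix(expand.grid(i = ii, j = jj, k = kk))
  world <- index_to_world(grid_idx, volume)
  vals <- predict(fit, world)

  mask <- array(FALSE, d)
  mask[grid_idx + 1L] <- vals < 0
  label_mask(mask, spacing = volume$spacing, origin = volume$origin)
}
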