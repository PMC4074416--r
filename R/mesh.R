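#' Triangle surface mesh in world coordinates
#'
#' @param vertices n-by-3 numeric matrix, mm world coordinates.
#' @param faces m-by-3 integer matrix of 1-based vertex indices.
#' @param vertex_scalars optional numeric vector (length n) of per-vertex
#'   CT values, as produced by [sample_ct_on_mesh()].
#' @return A `surface_mesh` object.
#' @export
surface_mesh <- function(vertices, faces, vertex_scalars = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be n-by-3", call. = FALSE)
  if (nrow(faces) > 0L) {
    if (ncol(faces) != 3L) stop("faces must be m-by-3", call. = FALSE)
    if (min(faces) < 1L || max(faces) > nrow(vertices)) {
      stop("face indices out of range", call. = FALSE)
    }
  }
  if (!is.null(vertex_scalars) && length(vertex_scalars) != nrow(vertices)) {
    stop("vertex_scalars must have one value per vertex", call. = FALSE)
  }
  structure(list(vertices = vertices, faces = faces,
                 vertex_scalars = vertex_scalars),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d faces%s\n",
              nrow(x$vertices), nrow(x$faces),
              if (is.null(x$vertex_scalars)) "" else ", with CT scalars"))
  invisible(x)
}

#' Extract the iso-surface of a binary mask as a triangle mesh
#'
#' Marching tetrahedra at iso-level 0.5 on the 0/1 grid (Freudenthal
#' 6-tetrahedron decomposition, translation-consistent so the surface of a
#' closed mask is watertight). Vertices are returned in mm world
#' coordinates. Masks touching the grid border are padded with one zero
#' layer first so the surface closes. Optional Laplacian smoothing keeps
#' the enclosed volume within 2% of the unsmoothed mesh (enforced by
#' uniform rescaling about the centroid).
#'
#' @param mask a non-empty [label_mask()].
#' @param smoothing_iterations number of Laplacian smoothing passes
#'   (default 0: off, so mesh geometry is exactly the iso-surface).
#' @return A [surface_mesh()].
#' @export
extract_mesh <- function(mask, smoothing_iterations = 0L) {
  stopifnot(inherits(mask, "label_mask"))
  if (!any(mask$data)) stop("cannot mesh an empty mask", call. = FALSE)
  dat <- mask$data
  origin <- mask$origin
  if (mask_touches_border(dat)) {
    d <- dim(dat)
    padded <- array(FALSE, d + 2L)
    padded[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- dat
    dat <- padded
    origin <- origin - mask$spacing
  }
  res <- .march_tets(as.logical(dat), dim(dat), mask$spacing, origin)
  mesh <- surface_mesh(res$vertices, res$faces)
  if (smoothing_iterations > 0L) {
    mesh <- smooth_mesh(mesh, smoothing_iterations)
  }
  mesh
}

mask_touches_border <- function(dat) {
  d <- dim(dat)
  any(dat[c(1, d[1]), , ]) || any(dat[, c(1, d[2]), ]) || any(dat[, , c(1, d[3])])
}

#' Laplacian mesh smoothing with volume preservation
#'
#' Each pass moves every vertex halfway towards the mean of its neighbours.
#' Afterwards the mesh is rescaled uniformly about its centroid so the
#' enclosed volume drifts by at most 2% from the input mesh (watertight
#' meshes only; open meshes are smoothed without the volume check).
#'
#' @param mesh a [surface_mesh()].
#' @param iterations number of smoothing passes.
#' @return The smoothed [surface_mesh()].
#' @export
smooth_mesh <- function(mesh, iterations = 1L) {
  v <- mesh$vertices
  f <- mesh$faces
  n <- nrow(v)
  edges <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  adj_i <- c(edges[, 1], edges[, 2])
  adj_j <- c(edges[, 2], edges[, 1])
  deg <- tabulate(adj_i, nbins = n)
  watertight <- is_watertight(mesh)
  v0_volume <- if (watertight) mesh_volume(mesh) else NA_real_
  for (it in seq_len(iterations)) {
    mean_nb <- matrix(0, n, 3)
    for (c in 1:3) {
      mean_nb[, c] <- rowsum(v[adj_j, c], adj_i, reorder = TRUE) / pmax(deg, 1L)
    }
    v <- 0.5 * v + 0.5 * mean_nb
  }
  out <- surface_mesh(v, f, mesh$vertex_scalars)
  if (watertight) {
    v1_volume <- mesh_volume(out)
    drift <- abs(v1_volume - v0_volume) / v0_volume
    if (drift > 0.02) {
      scale <- (v0_volume / v1_volume)^(1 / 3)
      ctr <- colMeans(v)
      v <- sweep(sweep(v, 2, ctr, "-") * scale, 2, ctr, "+")
      out <- surface_mesh(v, f, mesh$vertex_scalars)
    }
  }
  out
}

#' Enclosed volume of a watertight mesh (mm^3)
#'
#' Divergence-theorem sum of signed tetrahedron volumes spanned by the
#' origin and each face; the absolute value is returned, so the result is
#' independent of global orientation.
#'
#' @param mesh a watertight [surface_mesh()].
#' @return Positive volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  if (!is_watertight(mesh)) {
    stop("not watertight: mesh volume requires every edge on exactly 2 faces",
         call. = FALSE)
  }
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c <- v[f[, 3], , drop = FALSE]
  det6 <- a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) -
    a[, 2] * (b[, 1] * c[, 3] - b[, 3] * c[, 1]) +
    a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])
  abs(sum(det6)) / 6
}

#' Test whether every mesh edge borders exactly two faces
#' @param mesh a [surface_mesh()].
#' @return `TRUE` for closed (watertight) meshes.
#' @export
is_watertight <- function(mesh) {
  f <- mesh$faces
  if (nrow(f) == 0L) return(FALSE)
  n <- as.numeric(nrow(mesh$vertices)) + 1
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- pmin(e[, 1], e[, 2]) * n + pmax(e[, 1], e[, 2])
  all(table(key) == 2L)
}

#' Total surface area of a mesh (mm^2)
#' @param mesh a [surface_mesh()].
#' @return Sum of triangle areas.
#' @export
mesh_area <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  if (nrow(f) == 0L) return(0)
  u <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  w <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- u[, 2] * w[, 3] - u[, 3] * w[, 2]
  cy <- u[, 3] * w[, 1] - u[, 1] * w[, 3]
  cz <- u[, 1] * w[, 2] - u[, 2] * w[, 1]
  sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
}

#' Sample CT values on mesh vertices by trilinear interpolation
#'
#' Attaches a per-vertex scalar (the CT value at the vertex's world
#' position) to the mesh, the package's counterpart of rendering the CT
#' image on the resection surface. Vertices outside the volume are clamped
#' to the grid with a warning.
#'
#' @param volume a [ct_volume()].
#' @param mesh a [surface_mesh()].
#' @return The mesh with `vertex_scalars` filled in.
#' @export
sample_ct_on_mesh <- function(volume, mesh) {
  vals <- interp_trilinear(volume, mesh$vertices)
  surface_mesh(mesh$vertices, mesh$faces, vertex_scalars = vals)
}

# Trilinear interpolation of a 3D grid at world points (n x 3 mm).
# Out-of-grid points are clamped (with a warning) to the valid index box.
interp_trilinear <- function(volume, points, warn_clamp = TRUE) {
  idx <- world_to_index(points, volume)
  if (is.null(dim(idx))) idx <- matrix(idx, ncol = 3)
  d <- dim(volume$data)
  clamped <- FALSE
  for (c in 1:3) {
    bad <- idx[, c] < 0 | idx[, c] > d[c] - 1
    if (any(bad)) {
      clamped <- TRUE
      idx[, c] <- pmin(pmax(idx[, c], 0), d[c] - 1)
    }
  }
  if (clamped && warn_clamp) {
    warning("vertices outside the volume were clamped to the grid")
  }
  i0 <- pmin(floor(idx[, 1]), d[1] - 2); fx <- idx[, 1] - i0
  j0 <- pmin(floor(idx[, 2]), d[2] - 2); fy <- idx[, 2] - j0
  k0 <- pmin(floor(idx[, 3]), d[3] - 2); fz <- idx[, 3] - k0
  at <- function(di, dj, dk) {
    volume$data[cbind(i0 + di + 1, j0 + dj + 1, k0 + dk + 1)]
  }
  (1 - fz) * ((1 - fy) * ((1 - fx) * at(0, 0, 0) + fx * at(1, 0, 0)) +
                fy * ((1 - fx) * at(0, 1, 0) + fx * at(1, 1, 0))) +
    fz * ((1 - fy) * ((1 - fx) * at(0, 0, 1) + fx * at(1, 0, 1)) +
            fy * ((1 - fx) * at(0, 1, 1) + fx * at(1, 1, 1)))
}
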