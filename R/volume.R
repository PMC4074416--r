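#' 3D CT volume with voxel spacing and origin
#'
#' A `ct_volume` wraps a 3D numeric array of CT values together with the
#' voxel spacing (mm along each array axis) and the world position (mm) of
#' the center of voxel `(1,1,1)` (index `(0,0,0)` in the 0-based convention
#' used by [world_to_index()]). Voxel values are on the scanner's CT scale
#' and are never rescaled by this package.
#'
#' @param data 3D numeric array of CT values.
#' @param spacing numeric length-3, mm per voxel along each axis; all > 0.
#' @param origin numeric length-3, mm world coordinates of the center of the
#'   first voxel. Default `c(0, 0, 0)`.
#' @return An object of class `ct_volume`.
#' @examples
#' v <- ct_volume(array(0, c(4, 4, 4)), spacing = c(0.7, 0.7, 1))
#' dim(v$data)
#' @export
ct_volume <- function(data, spacing, origin = c(0, 0, 0)) {
  data <- as_grid3d(data, "CT volume")
  spacing <- as_spacing(spacing)
  origin <- as_vec3(origin, "origin")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "ct_volume")
}

#' Binary label mask aligned to a CT volume
#'
#' A `label_mask` is a 3D logical grid (one structure: kidney, tumor or
#' urinary tract) sharing shape, spacing and origin with its parent
#' [ct_volume()]. Alignment is re-checked by every pairwise operation.
#'
#' @param data 3D logical (or 0/1 numeric) array.
#' @param spacing,origin as in [ct_volume()].
#' @return An object of class `label_mask`.
#' @examples
#' m <- label_mask(array(FALSE, c(4, 4, 4)), spacing = c(1, 1, 1))
#' mask_count(m)
#' @export
label_mask <- function(data, spacing, origin = c(0, 0, 0)) {
  data <- as_grid3d(data, "label mask")
  if (!is.logical(data)) {
    if (!all(data %in% c(0, 1))) {
      stop("label mask values must be logical or 0/1", call. = FALSE)
    }
    storage.mode(data) <- "logical"
  }
  spacing <- as_spacing(spacing)
  origin <- as_vec3(origin, "origin")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "label_mask")
}

as_grid3d <- function(data, what) {
  if (is.null(dim(data)) || length(dim(data)) != 3L) {
    stop(sprintf("%s must be a 3D array, got %s dimension(s)",
                 what, length(dim(data))), call. = FALSE)
  }
  if (any(dim(data) < 2L)) {
    stop(sprintf("%s needs at least 2 voxels along every axis", what),
         call. = FALSE)
  }
  data
}

as_spacing <- function(spacing) {
  spacing <- as_vec3(spacing, "spacing")
  if (any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("spacing components must be strictly positive", call. = FALSE)
  }
  spacing
}

as_vec3 <- function(x, what) {
  x <- as.numeric(x)
  if (length(x) != 3L) stop(sprintf("%s must have length 3", what), call. = FALSE)
  x
}

#' @export
print.ct_volume <- function(x, ...) {
  cat(sprintf("<ct_volume> %s voxels, spacing (%s) mm, origin (%s) mm\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = ", "),
              paste(format(x$origin), collapse = ", ")))
  cat(sprintf("  CT values in [%g, %g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.label_mask <- function(x, ...) {
  cat(sprintf("<label_mask> %s voxels, %d set, spacing (%s) mm\n",
              paste(dim(x$data), collapse = "x"), mask_count(x),
              paste(format(x$spacing), collapse = ", ")))
  invisible(x)
}

#' Number of set voxels in a mask
#' @param mask a [label_mask()].
#' @return Integer count of `TRUE` voxels.
#' @export
mask_count <- function(mask) {
  stopifnot(inherits(mask, "label_mask"))
  sum(mask$data)
}

#' Physical volume of a mask in cubic millimetres
#' @param mask a [label_mask()].
#' @return Voxel count times voxel volume (mm^3).
#' @export
mask_volume_mm3 <- function(mask) {
  mask_count(mask) * prod(mask$spacing)
}

# Shared geometry of two grids; every pairwise mask/volume op calls this.
check_aligned <- function(a, b, what = "grids") {
  if (!identical(dim(a$data), dim(b$data)) ||
      max(abs(a$spacing - b$spacing)) > 1e-9 ||
      max(abs(a$origin - b$origin)) > 1e-9) {
    stop(sprintf("misaligned %s: shape/spacing/origin must match", what),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Convert world coordinates (mm) to continuous 0-based voxel indices
#'
#' Voxel centers sit at integer indices; index `(0,0,0)` is the volume
#' origin. The mapping is `index = (point - origin) / spacing` per
#' component, so out-of-grid points yield indices outside
#' `[0, dim - 1]` (see [in_bounds()]).
#'
#' @param points numeric length-3 vector or n-by-3 matrix of mm positions.
#' @param volume a [ct_volume()] or [label_mask()].
#' @return Continuous indices, same shape as `points`.
#' @seealso [index_to_world()]
#' @export
world_to_index <- function(points, volume) {
  p <- to_point_matrix(points)
  idx <- sweep(sweep(p, 2, volume$origin, "-"), 2, volume$spacing, "/")
  restore_point_shape(idx, points)
}

#' Convert 0-based voxel indices to world coordinates (mm)
#' @inheritParams world_to_index
#' @param indices numeric length-3 vector or n-by-3 matrix of continuous
#'   0-based indices.
#' @return World coordinates in mm, same shape as `indices`.
#' @export
index_to_world <- function(indices, volume) {
  p <- to_point_matrix(indices)
  w <- sweep(sweep(p, 2, volume$spacing, "*"), 2, volume$origin, "+")
  restore_point_shape(w, indices)
}

#' Test whether continuous 0-based indices fall inside the grid
#' @inheritParams index_to_world
#' @return Logical vector, one entry per point.
#' @export
in_bounds <- function(indices, volume) {
  p <- to_point_matrix(indices)
  d <- dim(volume$data)
  apply(p, 1, function(q) all(q >= 0) && all(q <= d - 1))
}

to_point_matrix <- function(points) {
  if (is.null(dim(points))) {
    matrix(as.numeric(points), ncol = 3)
  } else {
    m <- as.matrix(points)
    if (ncol(m) != 3L) stop("points must be length-3 or n-by-3", call. = FALSE)
    storage.mode(m) <- "double"
    m
  }
}

restore_point_shape <- function(m, original) {
  if (is.null(dim(original))) as.numeric(m[1, ]) else m
}

# World coordinates (n x 3 mm) of the centers of the TRUE voxels of a mask.
mask_voxel_world <- function(mask) {
  idx <- which(mask$data, arr.ind = TRUE) - 1  # 0-based
  if (nrow(idx) == 0L) return(matrix(numeric(0), ncol = 3))
  index_to_world(idx, mask)
}
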