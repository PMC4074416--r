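#' User annotations driving the three segmentation methods
#'
#' Three light-weight containers mirror the interactions a clinician
#' performs when segmenting delay-phase CT: foreground/background scribbles
#' for the kidney graph cut, supra-threshold seeds for urinary-tract region
#' growing, and planar closed contours for the tumor. All voxel indices are
#' 0-based (the package-wide convention, see [world_to_index()]).
#'
#' @param foreground,background integer n-by-3 matrices of 0-based voxel
#'   indices; both non-empty and disjoint.
#' @return `scribble_set` / `seed_set` / `contour_stack` objects.
#' @name annotations
NULL

#' @rdname annotations
#' @export
scribble_set <- function(foreground, background) {
  fg <- as_index_matrix(foreground, "foreground scribbles")
  bg <- as_index_matrix(background, "background scribbles")
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  if (length(intersect(key(fg), key(bg))) > 0L) {
    stop("scribble sets overlap: a voxel cannot be foreground and background",
         call. = FALSE)
  }
  structure(list(foreground = fg, background = bg), class = "scribble_set")
}

#' @rdname annotations
#' @param seeds integer n-by-3 matrix of 0-based voxel indices in the
#'   urinary tract.
#' @param threshold_r CT-value threshold: region growing only visits voxels
#'   with value strictly greater than `threshold_r`. Chosen per patient,
#'   typically in \[350, 420\] for delay-phase contrast.
#' @export
seed_set <- function(seeds, threshold_r) {
  seeds <- as_index_matrix(seeds, "seeds")
  threshold_r <- as.numeric(threshold_r)
  if (length(threshold_r) != 1L || !is.finite(threshold_r)) {
    stop("threshold_r must be a single finite CT value", call. = FALSE)
  }
  structure(list(seeds = seeds, threshold_r = threshold_r),
            class = "seed_set")
}

#' @rdname annotations
#' @param contours list of contours; each a list with `plane_axis` (0, 1 or
#'   2: the grid axis orthogonal to the drawing plane), `plane_index`
#'   (0-based slice index), and `points`, an n-by-2 matrix (n >= 3) of
#'   continuous 0-based in-plane voxel coordinates along the two remaining
#'   axes in ascending axis order. Contours are implicitly closed (the last
#'   vertex connects back to the first) and must be simple.
#' @export
contour_stack <- function(contours) {
  if (!is.list(contours) || length(contours) < 2L) {
    stop("at least two planes required: supply >= 2 contours", call. = FALSE)
  }
  contours <- lapply(contours, validate_contour)
  planes <- vapply(contours, function(cc) {
    paste(cc$plane_axis, cc$plane_index)
  }, character(1))
  if (length(unique(planes)) < 2L) {
    stop("at least two planes required: contours lie on a single plane",
         call. = FALSE)
  }
  structure(list(contours = contours), class = "contour_stack")
}

validate_contour <- function(cc) {
  if (!all(c("plane_axis", "plane_index", "points") %in% names(cc))) {
    stop("each contour needs plane_axis, plane_index and points",
         call. = FALSE)
  }
  axis <- as.integer(cc$plane_axis)
  if (!axis %in% 0:2) stop("plane_axis must be 0, 1 or 2", call. = FALSE)
  pts <- as.matrix(cc$points)
  storage.mode(pts) <- "double"
  if (ncol(pts) != 2L || nrow(pts) < 3L) {
    stop("contour points must be an n-by-2 matrix with n >= 3", call. = FALSE)
  }
  if (polygon_area2(pts) == 0) {
    stop("degenerate contour: vertices are collinear", call. = FALSE)
  }
  if (!polygon_is_simple(pts)) {
    stop("contour polyline is self-intersecting", call. = FALSE)
  }
  list(plane_axis = axis, plane_index = as.integer(cc$plane_index),
       points = pts)
}

as_index_matrix <- function(x, what) {
  if (is.null(dim(x))) x <- matrix(as.numeric(x), ncol = 3, byrow = TRUE)
  m <- as.matrix(x)
  if (ncol(m) != 3L || nrow(m) == 0L) {
    stop(sprintf("%s must be a non-empty n-by-3 index matrix", what),
         call. = FALSE)
  }
  if (any(m != round(m)) || any(m < 0)) {
    stop(sprintf("%s must be non-negative integer voxel indices", what),
         call. = FALSE)
  }
  storage.mode(m) <- "integer"
  m
}

check_indices_in_grid <- function(idx, volume, what) {
  d <- dim(volume$data)
  ok <- idx[, 1] < d[1] & idx[, 2] < d[2] & idx[, 3] < d[3]
  if (!all(ok)) {
    bad <- idx[which(!ok)[1], ]
    stop(sprintf("%s voxel (%d, %d, %d) lies outside the %s grid",
                 what, bad[1], bad[2], bad[3],
                 paste(d, collapse = "x")), call. = FALSE)
  }
  invisible(TRUE)
}

# Twice the signed area of a closed 2D polygon (shoelace).
polygon_area2 <- function(pts) {
  n <- nrow(pts)
  j <- c(2:n, 1)
  sum(pts[, 1] * pts[j, 2] - pts[j, 1] * pts[, 2])
}

# Simple-polygon test: no two non-adjacent edges intersect.
polygon_is_simple <- function(pts) {
  n <- nrow(pts)
  a <- pts
  b <- pts[c(2:n, 1), , drop = FALSE]
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      adjacent <- (j == i + 1L) || (i == 1L && j == n)
      if (adjacent) next
      if (segments_intersect(a[i, ], b[i, ], a[j, ], b[j, ])) return(FALSE)
    }
  }
  TRUE
}

segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
     ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
}

# Even-odd point-in-polygon test for row vectors `q` (m x 2).
points_in_polygon <- function(q, pts) {
  n <- nrow(pts)
  xs <- pts[, 1]; ys <- pts[, 2]
  xe <- xs[c(2:n, 1)]; ye <- ys[c(2:n, 1)]
  vapply(seq_len(nrow(q)), function(k) {
    x <- q[k, 1]; y <- q[k, 2]
    crosses <- ((ys > y) != (ye > y)) &
      (x < (xe - xs) * (y - ys) / (ye - ys) + xs)
    sum(crosses) %% 2L == 1L
  }, logical(1))
}
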