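#' Read a 3D CT volume from a NIfTI-1 file
#'
#' The affine is reduced to per-axis spacing plus an origin (world mm of the
#' first voxel center). Volumes whose affine carries a non-axis-aligned
#' rotation are rejected: the planning geometry assumes axis-aligned grids
#' and silently dropping a rotation would corrupt every mm distance
#' downstream. Header slope/intercept scaling is applied by the NIfTI
#' reader; no other rescaling happens.
#'
#' @param path path to a `.nii` or `.nii.gz` file with 3 spatial dimensions.
#' @return A [ct_volume()].
#' @export
read_volume <- function(path) {
  hdr <- read_nifti_grid(path)
  ct_volume(hdr$data, spacing = hdr$spacing, origin = hdr$origin)
}

#' Read a binary label mask from a NIfTI-1 file
#'
#' @param path path to a NIfTI file containing 0/1 voxels.
#' @return A [label_mask()].
#' @export
read_mask <- function(path) {
  hdr <- read_nifti_grid(path)
  label_mask(hdr$data != 0, spacing = hdr$spacing, origin = hdr$origin)
}

#' Write a volume or mask to a NIfTI-1 file
#'
#' CT volumes are stored as float32, masks as unsigned 8-bit 0/1. The
#' spacing/origin convention is encoded in the sform affine so that
#' [read_volume()] / [read_mask()] round-trip losslessly (float32 precision
#' for CT data, exactly for masks).
#'
#' @param x a [ct_volume()] or [label_mask()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return Invisibly, `path`.
#' @export
write_volume <- function(x, path) {
  if (inherits(x, "label_mask")) {
    dat <- array(as.integer(x$data), dim(x$data))
    dtype <- "uint8"
  } else if (inherits(x, "ct_volume")) {
    dat <- x$data
    dtype <- "float"
  } else {
    stop("write_volume expects a ct_volume or label_mask", call. = FALSE)
  }
  affine <- diag(c(x$spacing, 1))
  affine[1:3, 4] <- x$origin
  img <- RNifti::asNifti(dat, datatype = dtype, pixdim = x$spacing)
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
write_mask <- function(x, path) {
  stopifnot(inherits(x, "label_mask"))
  write_volume(x, path)
}

read_nifti_grid <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    dim(img) <- d[1:3]
    d <- dim(img)
  }
  if (length(d) != 3L) {
    stop(sprintf("expected 3D volume, got %dD image in %s", length(d), path),
         call. = FALSE)
  }
  aff <- RNifti::xform(img)
  lin <- aff[1:3, 1:3]
  offdiag <- lin - diag(diag(lin))
  if (max(abs(offdiag)) > 1e-6 * max(abs(diag(lin)))) {
    stop(sprintf(paste0("volume %s has an oblique (rotated) affine; ",
                        "resample to an axis-aligned grid first"), path),
         call. = FALSE)
  }
  spacing <- diag(lin)
  if (any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop(sprintf("non-positive spacing in header of %s", path), call. = FALSE)
  }
  list(data = array(as.numeric(img), d), spacing = as.numeric(spacing),
       origin = as.numeric(aff[1:3, 4]))
}
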