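#' Seeded region growing for the urinary tract
#'
#' Grows a region from user-placed seeds through voxels whose CT value is
#' strictly greater than the threshold `r` carried by the [seed_set()].
#' In delay-phase CT the excreted contrast makes the collecting system far
#' brighter than parenchyma, so a per-patient `r` (typically 350-420 CT
#' units) isolates it; the result is exactly the union, over seeds, of the
#' supra-threshold connected component containing each seed.
#'
#' @param volume a [ct_volume()].
#' @param seeds a [seed_set()]; every seed voxel must itself have CT value
#'   > `threshold_r`, otherwise the offending seed is reported (a seed
#'   below `r` means a mis-placed seed or a wrong threshold choice).
#' @param connectivity 6 (face neighbours, the default: prevents diagonal
#'   leakage through thin tract walls) or 26.
#' @return A [label_mask()].
#' @export
segment_region_growing <- function(volume, seeds, connectivity = 6L) {
  stopifnot(inherits(volume, "ct_volume"), inherits(seeds, "seed_set"))
  if (!connectivity %in% c(6L, 26L)) {
    stop("connectivity must be 6 or 26", call. = FALSE)
  }
  check_indices_in_grid(seeds$seeds, volume, "seed")
  vals <- volume$data[seeds$seeds + 1L]
  low <- vals <= seeds$threshold_r
  if (any(low)) {
    bad <- seeds$seeds[which(low)[1], ]
    stop(sprintf(paste0("seed (%d, %d, %d) has CT value %g <= threshold r = %g; ",
                        "move the seed or lower r"),
                 bad[1], bad[2], bad[3], vals[which(low)[1]],
                 seeds$threshold_r), call. = FALSE)
  }
  grown <- .region_grow(as.numeric(volume$data), dim(volume$data),
                        seeds$seeds, seeds$threshold_r, as.integer(connectivity))
  label_mask(array(grown, dim(volume$data)),
             spacing = volume$spacing, origin = volume$origin)
}
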