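# Annotation files are a small JSON dialect, versioned with "format_version".
# Voxel indices are 0-based triples; contour points are 0-based continuous
# in-plane coordinates. See README for the full format description.

ANNOTATION_FORMAT_VERSION <- "1.0"

#' Read and write annotation JSON files
#'
#' Scribbles: `{"format_version": "1.0", "scribbles": {"foreground":
#' [[i,j,k], ...], "background": [[...]]}}`. Seeds: `{"seeds": [[i,j,k],
#' ...], "threshold": r}`. Contours: `{"contours": [{"plane_axis": 0|1|2,
#' "plane_index": int, "points": [[u,v], ...]}]}`.
#'
#' @param path JSON file path.
#' @return The corresponding annotation object ([scribble_set()],
#'   [seed_set()] or [contour_stack()]).
#' @name annotation_io
NULL

#' @rdname annotation_io
#' @export
read_scribbles <- function(path) {
  x <- read_annotation_json(path, "scribbles")
  scribble_set(x$scribbles$foreground, x$scribbles$background)
}

#' @rdname annotation_io
#' @export
read_seeds <- function(path) {
  x <- read_annotation_json(path, "seeds")
  seed_set(x$seeds, x$threshold)
}

#' @rdname annotation_io
#' @export
read_contours <- function(path) {
  x <- read_annotation_json(path, "contours")
  contour_stack(x$contours)
}

#' @rdname annotation_io
#' @param x an annotation object.
#' @export
write_annotations <- function(x, path) {
  payload <- if (inherits(x, "scribble_set")) {
    list(format_version = ANNOTATION_FORMAT_VERSION,
         scribbles = list(foreground = index_rows(x$foreground),
                          background = index_rows(x$background)))
  } else if (inherits(x, "seed_set")) {
    list(format_version = ANNOTATION_FORMAT_VERSION,
         seeds = index_rows(x$seeds), threshold = x$threshold_r)
  } else if (inherits(x, "contour_stack")) {
    list(format_version = ANNOTATION_FORMAT_VERSION,
         contours = lapply(x$contours, function(cc) {
           list(plane_axis = cc$plane_axis, plane_index = cc$plane_index,
                points = lapply(seq_len(nrow(cc$points)),
                                function(i) cc$points[i, ]))
         }))
  } else {
    stop("unsupported annotation object", call. = FALSE)
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

index_rows <- function(m) lapply(seq_len(nrow(m)), function(i) m[i, ])

read_annotation_json <- function(path, field) {
  if (!file.exists(path)) {
    stop(sprintf("annotation file not found: %s", path), call. = FALSE)
  }
  x <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  if (is.null(x[[field]])) {
    stop(sprintf("%s: expected a '%s' annotation file", path, field),
         call. = FALSE)
  }
  x
}
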