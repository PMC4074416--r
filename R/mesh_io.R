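#' Write a surface mesh to PLY, STL or OBJ
#'
#' The format is chosen from the file extension (`.ply`, `.stl`, `.obj`)
#' unless given explicitly. Per-vertex CT values, when present, are
#' written as a PLY vertex property named `ct_value` (ascii PLY and
#' binary-little-endian PLY); STL and OBJ carry geometry only. Extra
#' per-vertex 0/1 properties (e.g. an `opening` flag) can be added via
#' `extra_properties`.
#'
#' @param mesh a [surface_mesh()].
#' @param path output file path.
#' @param format `"ply"`, `"ply_binary"`, `"stl"` or `"obj"`; default from
#'   the extension (`.ply` means ascii).
#' @param extra_properties named list of numeric vectors (one value per
#'   vertex) written as additional PLY properties.
#' @return Invisibly, `path`.
#' @export
write_mesh <- function(mesh, path, format = NULL, extra_properties = list()) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (is.null(format)) {
    format <- switch(tolower(tools::file_ext(path)),
                     ply = "ply", stl = "stl", obj = "obj",
                     stop("unknown mesh extension; pass format=", call. = FALSE))
  }
  switch(format,
         ply = write_ply(mesh, path, binary = FALSE, extra_properties),
         ply_binary = write_ply(mesh, path, binary = TRUE, extra_properties),
         stl = write_stl(mesh, path),
         obj = write_obj(mesh, path),
         stop(sprintf("unsupported mesh format '%s'", format), call. = FALSE))
  invisible(path)
}

write_ply <- function(mesh, path, binary, extra_properties) {
  v <- mesh$vertices
  f <- mesh$faces
  props <- list()
  if (!is.null(mesh$vertex_scalars)) props$ct_value <- mesh$vertex_scalars
  props <- c(props, extra_properties)
  for (p in props) {
    if (length(p) != nrow(v)) {
      stop("PLY properties need one value per vertex", call. = FALSE)
    }
  }
  header <- c(
    "ply",
    sprintf("format %s 1.0",
            if (binary) "binary_little_endian" else "ascii"),
    sprintf("element vertex %d", nrow(v)),
    "property float x", "property float y", "property float z",
    sprintf("property float %s", names(props)),
    sprintf("element face %d", nrow(f)),
    "property list uchar int vertex_indices",
    "end_header")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(header, con)
  vdata <- cbind(v, do.call(cbind, c(props, list(deparse.level = 0))))
  if (binary) {
    writeBin(as.numeric(t(vdata)), con, size = 4, endian = "little")
    for (i in seq_len(nrow(f))) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(f[i, ] - 1L), con, size = 4, endian = "little")
    }
  } else {
    writeLines(apply(vdata, 1, paste, collapse = " "), con)
    if (nrow(f) > 0L) {
      writeLines(paste(3L, f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
    }
  }
}

write_stl <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  con <- file(path, open = "w")
  on.exit(close(con))
  writeLines("solid mesh", con)
  for (i in seq_len(nrow(f))) {
    a <- v[f[i, 1], ]; b <- v[f[i, 2], ]; c <- v[f[i, 3], ]
    n <- c((b[2] - a[2]) * (c[3] - a[3]) - (b[3] - a[3]) * (c[2] - a[2]),
           (b[3] - a[3]) * (c[1] - a[1]) - (b[1] - a[1]) * (c[3] - a[3]),
           (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1]))
    nn <- sqrt(sum(n^2))
    if (nn > 0) n <- n / nn
    writeLines(c(sprintf("facet normal %g %g %g", n[1], n[2], n[3]),
                 "  outer loop",
                 sprintf("    vertex %g %g %g", a[1], a[2], a[3]),
                 sprintf("    vertex %g %g %g", b[1], b[2], b[3]),
                 sprintf("    vertex %g %g %g", c[1], c[2], c[3]),
                 "  endloop", "endfacet"), con)
  }
  writeLines("endsolid mesh", con)
}

write_obj <- function(mesh, path) {
  con <- file(path, open = "w")
  on.exit(close(con))
  v <- mesh$vertices
  writeLines(sprintf("v %g %g %g", v[, 1], v[, 2], v[, 3]), con)
  f <- mesh$faces
  if (nrow(f) > 0L) writeLines(sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3]), con)
}

#' Read an ascii PLY mesh
#'
#' Minimal reader for the PLY files this package writes (ascii, float
#' vertex properties, triangular faces).
#'
#' @param path PLY file path.
#' @return A [surface_mesh()] (with `vertex_scalars` when the file has a
#'   `ct_value` property).
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  end <- match("end_header", lines)
  if (is.na(end)) stop("not a PLY file (no end_header)", call. = FALSE)
  header <- lines[seq_len(end)]
  if (!any(grepl("^format ascii", header))) {
    stop("only ascii PLY reading is supported", call. = FALSE)
  }
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", header, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face", header, value = TRUE)))
  vstart <- grep("^element vertex", header)
  vprops <- grep("^property float", header[vstart:length(header)], value = TRUE)
  pnames <- sub("property float ", "", vprops)
  vlines <- lines[(end + 1):(end + nv)]
  vdata <- matrix(as.numeric(unlist(strsplit(vlines, " "))), nrow = nv,
                  byrow = TRUE)
  colnames(vdata) <- pnames
  faces <- matrix(integer(0), 0, 3)
  if (nf > 0L) {
    flines <- lines[(end + nv + 1):(end + nv + nf)]
    fdata <- matrix(as.integer(unlist(strsplit(flines, " "))), nrow = nf,
                    byrow = TRUE)
    faces <- fdata[, 2:4, drop = FALSE] + 1L
  }
  surface_mesh(vdata[, c("x", "y", "z"), drop = FALSE], faces,
               vertex_scalars = if ("ct_value" %in% pnames) vdata[, "ct_value"])
}
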