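#' Configuration of an end-to-end planning run
#'
#' Collects every input and tunable of the pipeline in one explicit,
#' serialisable object, because the method is deliberately per-patient:
#' the region-growing threshold, scribbles and contours are chosen case by
#' case and must be recorded for reproducibility. For each structure
#' exactly one of an annotation file or a precomputed mask file must be
#' supplied.
#'
#' @param ct path to the delay-phase CT volume (NIfTI).
#' @param out_dir output directory (created if missing).
#' @param kidney_scribbles,kidney_mask scribble JSON or mask NIfTI.
#' @param tract_seeds,tract_mask seed JSON or mask NIfTI.
#' @param tumor_contours,tumor_mask contour JSON or mask NIfTI.
#' @param margins margin schedule, mm (default 1-5 every 1).
#' @param lambda_region,sigma_boundary,neighborhood see [graph_cut_params()].
#' @param threshold_r optional override of the region-growing threshold in
#'   the seed file.
#' @param connectivity region-growing connectivity, 6 or 26.
#' @param smoothness contour-surface ridge, see [fit_contour_surface()].
#' @param rng_seed integer seed recorded with the run (the pipeline itself
#'   is deterministic; the seed is forwarded to any stochastic component).
#' @param log_level `"debug"`, `"info"` or `"warn"`.
#' @return A `run_config`.
#' @export
run_config <- function(ct, out_dir,
                       kidney_scribbles = NULL, kidney_mask = NULL,
                       tract_seeds = NULL, tract_mask = NULL,
                       tumor_contours = NULL, tumor_mask = NULL,
                       margins = c(1, 2, 3, 4, 5),
                       lambda_region = 1, sigma_boundary = NULL,
                       neighborhood = 6L, threshold_r = NULL,
                       connectivity = 6L, smoothness = 0,
                       rng_seed = 1L, log_level = "info") {
  one_of <- function(a, b, what) {
    if (is.null(a) == is.null(b)) {
      stop(sprintf("%s input required: supply exactly one of annotations or a mask",
                   what), call. = FALSE)
    }
  }
  one_of(kidney_scribbles, kidney_mask, "kidney")
  one_of(tract_seeds, tract_mask, "tract")
  one_of(tumor_contours, tumor_mask, "tumor")
  structure(list(ct = ct, out_dir = out_dir,
                 kidney_scribbles = kidney_scribbles, kidney_mask = kidney_mask,
                 tract_seeds = tract_seeds, tract_mask = tract_mask,
                 tumor_contours = tumor_contours, tumor_mask = tumor_mask,
                 schedule = margin_schedule(margins),
                 graph_cut = graph_cut_params(lambda_region, sigma_boundary,
                                              neighborhood),
                 threshold_r = threshold_r,
                 connectivity = as.integer(connectivity),
                 smoothness = smoothness,
                 rng_seed = as.integer(rng_seed),
                 log_level = log_level),
            class = "run_config")
}

#' Run the full virtual-resection planning pipeline
#'
#' Segments (or loads) the kidney, urinary-tract and tumor masks, plans
#' resections over the margin schedule, and writes all artifacts to the
#' output directory: per-margin removed-region NIfTI masks and
#' resection-surface PLY meshes (with `ct_value` and 0/1 `opening` vertex
#' properties), `report.json` (see [validate_report()] for the schema),
#' `provenance.json` (config echo, package version, input checksums), and
#' `run.log`. Deterministic: identical config and seed give byte-identical
#' reports.
#'
#' @param config a [run_config()].
#' @return Invisibly, the planning result of [plan_all_margins()].
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_file <- file.path(config$out_dir, "run.log")
  cat(sprintf("nephroplan %s pipeline run\n", packageVersion("nephroplan")),
      file = log_file)
  logf <- function(level, fmt, ...) {
    ranks <- c(debug = 1, info = 2, warn = 3)
    msg <- sprintf("[%s] %s", level, sprintf(fmt, ...))
    cat(msg, "\n", file = log_file, append = TRUE, sep = "")
    if (ranks[level] >= ranks[config$log_level]) message(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  ct <- stage("read CT", read_volume(config$ct))
  logf("info", "CT volume %s, spacing (%s) mm",
       paste(dim(ct$data), collapse = "x"),
       paste(format(ct$spacing), collapse = ", "))

  kidney <- stage("kidney segmentation", {
    if (!is.null(config$kidney_mask)) read_mask(config$kidney_mask)
    else segment_graph_cut(ct, read_scribbles(config$kidney_scribbles),
                           config$graph_cut)
  })
  logf("info", "kidney mask: %d voxels (%.1f cm^3)", mask_count(kidney),
       mask_volume_mm3(kidney) / 1000)

  tract <- stage("urinary tract segmentation", {
    if (!is.null(config$tract_mask)) read_mask(config$tract_mask)
    else {
      seeds <- read_seeds(config$tract_seeds)
      if (!is.null(config$threshold_r)) {
        seeds <- seed_set(seeds$seeds, config$threshold_r)
      }
      logf("info", "region growing with r = %g", seeds$threshold_r)
      segment_region_growing(ct, seeds, config$connectivity)
    }
  })
  logf("info", "urinary tract mask: %d voxels", mask_count(tract))

  tumor <- stage("tumor segmentation", {
    if (!is.null(config$tumor_mask)) read_mask(config$tumor_mask)
    else segment_contour_based(ct, read_contours(config$tumor_contours),
                               config$smoothness)
  })
  logf("info", "tumor mask: %d voxels (%.1f cm^3)", mask_count(tumor),
       mask_volume_mm3(tumor) / 1000)

  result <- stage("resection planning",
                  plan_all_margins(kidney, tumor, tract,
                                   schedule = config$schedule, ct = ct))
  logf("info", "min tract-to-tumor distance %.2f mm; %s",
       result$report$min_tract_distance_mm, result$report$status_text)

  stage("artifact export", {
    for (p in result$plans) {
      tag <- sprintf("margin_%gmm", p$margin_mm)
      write_mask(p$removed_region,
                 file.path(config$out_dir, sprintf("removed_%s.nii.gz", tag)))
      surf <- p$resection_surface
      if (nrow(surf$faces) > 0L) {
        opening <- opening_vertex_flag(surf, tract)
        write_mesh(surf,
                   file.path(config$out_dir, sprintf("resection_%s.ply", tag)),
                   extra_properties = list(opening = opening))
      }
    }
    write_report(result$report, file.path(config$out_dir, "report.json"))
    write_provenance(config, file.path(config$out_dir, "provenance.json"))
  })
  logf("info", "artifacts written to %s", config$out_dir)
  invisible(result)
}

# 1 for resection-surface vertices lying on (or sub-voxel close to) the
# urinary tract, i.e. the rim of the predicted opening.
opening_vertex_flag <- function(mesh, tract) {
  tract_vol <- ct_volume(array(as.numeric(tract$data), dim(tract$data)),
                         spacing = tract$spacing, origin = tract$origin)
  as.integer(interp_trilinear(tract_vol, mesh$vertices) >= 0.5)
}

write_report <- function(report, path) {
  payload <- list(
    min_opening_margin_mm = report$min_opening_margin_mm,
    min_tract_distance_mm = report$min_tract_distance_mm,
    status_text = report$status_text,
    per_margin = lapply(report$per_margin, function(p) {
      out <- list(margin_mm = p$margin_mm, open = p$open,
                  opening_voxel_count = p$voxel_count)
      if (p$open) {
        out$opening_centroid_mm <- p$centroid
        out$opening_extent_mm <- p$extent_mm
      }
      out
    }))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

write_provenance <- function(config, path) {
  inputs <- Filter(Negate(is.null),
                   config[c("ct", "kidney_scribbles", "kidney_mask",
                            "tract_seeds", "tract_mask", "tumor_contours",
                            "tumor_mask")])
  checksums <- lapply(inputs, function(p) unname(tools::md5sum(p)))
  echo <- config
  echo$schedule <- config$schedule$margins
  echo$graph_cut <- unclass(config$graph_cut)
  payload <- list(package = "nephroplan",
                  version = as.character(packageVersion("nephroplan")),
                  config = unclass(echo),
                  input_md5 = checksums)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Validate a planning report against the shipped schema
#'
#' Structural validation of `report.json` against the JSON schema shipped
#' in `inst/schema/opening_report.schema.json` (required fields and types;
#' the checker implements the subset of JSON Schema the shipped schema
#' uses).
#'
#' @param report a parsed report (list, e.g. from [jsonlite::read_json()])
#'   or a path to a report JSON file.
#' @return `TRUE` invisibly; errors describe the first violation.
#' @export
validate_report <- function(report) {
  if (is.character(report)) {
    report <- jsonlite::read_json(report, simplifyVector = FALSE)
  }
  need <- function(obj, field, type, where) {
    if (!field %in% names(obj)) {
      stop(sprintf("report invalid: missing '%s' in %s", field, where),
           call. = FALSE)
    }
    val <- obj[[field]]
    ok <- switch(type,
                 number = is.numeric(val) && length(val) == 1L,
                 number_or_null = is.null(val) ||
                   (is.numeric(val) && length(val) == 1L),
                 string = is.character(val) && length(val) == 1L,
                 boolean = is.logical(val) && length(val) == 1L,
                 array = is.list(val) || is.vector(val))
    if (!ok) {
      stop(sprintf("report invalid: '%s' in %s must be %s", field, where,
                   type), call. = FALSE)
    }
  }
  need(report, "min_opening_margin_mm", "number_or_null", "report")
  need(report, "min_tract_distance_mm", "number", "report")
  need(report, "status_text", "string", "report")
  need(report, "per_margin", "array", "report")
  if (!grepl("^(Open|Not open) with [0-9.]+ mm margin$", report$status_text)) {
    stop("report invalid: status_text must read 'Open with N mm margin' or 'Not open with N mm margin'",
         call. = FALSE)
  }
  for (i in seq_along(report$per_margin)) {
    p <- report$per_margin[[i]]
    where <- sprintf("per_margin[%d]", i)
    need(p, "margin_mm", "number", where)
    need(p, "open", "boolean", where)
    need(p, "opening_voxel_count", "number", where)
  }
  invisible(TRUE)
}
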