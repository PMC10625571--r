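#' Pipeline configuration
#'
#' Bundles every tunable of the photograph-to-retainer chain so a run is
#' a pure function of (inputs, config, seed). The effective config is
#' echoed into the output report for provenance.
#'
#' @param marker a [marker_spec()].
#' @param template a [template_params()].
#' @param replicates_n replicate count enforced by
#'   [average_replicates()].
#' @param sanity_max_mm plausibility bound for measurements.
#' @param loa_multiplier limits-of-agreement multiplier.
#' @param normality_alpha Shapiro-Wilk gate level for [paired_compare()].
#' @param seed global seed for stochastic commands.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(marker = marker_spec(), template = template_params(),
                            replicates_n = 3, sanity_max_mm = 50,
                            loa_multiplier = 1.96, normality_alpha = 0.05,
                            seed = 1L) {
  structure(list(marker = marker, template = template,
                 replicates_n = replicates_n, sanity_max_mm = sanity_max_mm,
                 loa_multiplier = loa_multiplier, normality_alpha = normality_alpha,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

config_as_list <- function(cfg) {
  list(marker = unclass(cfg$marker), template = unclass(cfg$template),
       replicates_n = cfg$replicates_n, sanity_max_mm = cfg$sanity_max_mm,
       loa_multiplier = cfg$loa_multiplier, normality_alpha = cfg$normality_alpha,
       seed = cfg$seed)
}

stage_error <- function(stage, e) {
  nf_stop("pipeline", "[stage %s] %s", stage, conditionMessage(e))
}

#' Run the full photograph-to-retainer chain
#'
#' calibrate -> measure -> plan -> reshape -> validate -> export. The
#' scale comes from the annotation set's calibrator segment (or, with
#' `detect = TRUE`, from automatic marker detection on the image). Output
#' files are deterministic for fixed inputs and config: the STL header is
#' constant and the report carries no timestamps.
#'
#' @param image path to the photograph, or a [raster_image()], or `NULL`
#'   when a calibrator segment is supplied in the annotations.
#' @param annotations path to an annotation JSON, or an
#'   [annotation_set()].
#' @param config a [pipeline_config()].
#' @param stl_path output STL path, or `NULL` to skip writing.
#' @param report_path output report JSON path, or `NULL` to skip writing.
#' @param detect use [detect_marker()] on the image for the scale instead
#'   of the drawn calibrator segment.
#' @param overcorrect per-side mm offsets, see [plan_reshape()].
#' @return Invisibly, a list with `scale`, `measurements`, `plan`,
#'   `mesh`, `validation` and `report` (the report also echoes the
#'   config).
#' @export
run_pipeline <- function(image = NULL, annotations, config = pipeline_config(),
                         stl_path = NULL, report_path = NULL, detect = FALSE,
                         overcorrect = list(left = c(0, 0), right = c(0, 0))) {
  ann <- withCallingHandlers(
    if (inherits(annotations, "annotation_set")) annotations
    else read_annotations(annotations)$annotations,
    nariform_error = function(e) stage_error("annotations", e))

  scale <- withCallingHandlers({
    if (detect) {
      img <- if (inherits(image, "raster_image")) image else load_image(image)
      scale_from_detection(detect_marker(img, config$marker), config$marker)
    } else {
      cal <- ann$segments[["calibrator"]]
      if (is.null(cal))
        nf_stop("missing_calibrator",
                "no calibrator segment; supply one or use marker detection")
      scale_from_segment(cal, config$marker)
    }
  }, nariform_error = function(e) if (!inherits(e, "nariform_pipeline"))
       stage_error("calibrate", e))

  meas <- withCallingHandlers(
    measure_annotations(ann, scale, sanity_max_mm = config$sanity_max_mm),
    nariform_error = function(e) if (!inherits(e, "nariform_pipeline"))
      stage_error("measure", e))

  res <- withCallingHandlers({
    plan <- plan_reshape(meas, config$template, overcorrect = overcorrect)
    template <- build_template(config$template)
    mesh <- apply_reshape(template, plan)
    list(plan = plan, mesh = mesh)
  }, nariform_error = function(e) if (!inherits(e, "nariform_pipeline"))
       stage_error("design", e))

  val <- validate_mesh(res$mesh)
  if (!val$ok)
    nf_stop("pipeline", "[stage validate] mesh failed validation")
  if (!is.null(stl_path))
    withCallingHandlers(write_stl(res$mesh, stl_path, sidecar = TRUE),
                        nariform_error = function(e) if (!inherits(e, "nariform_pipeline"))
                          stage_error("export", e))

  parts <- attr(res$mesh, "parts")
  bb_r <- mesh_bbox(res$mesh, parts$right$vidx)
  bb_l <- mesh_bbox(res$mesh, parts$left$vidx)
  report <- list(
    image_id = ann$image_id,
    scale = list(mm_per_px = scale$mm_per_px, source = scale$source),
    measurements_mm = as.list(meas$values_mm),
    plan = unclass(res$plan),
    final_dims_mm = list(
      right = list(width = unname(diff(bb_r[, 1])), height = unname(diff(bb_r[, 2])),
                   depth = unname(diff(bb_r[, 3]))),
      left = list(width = unname(diff(bb_l[, 1])), height = unname(diff(bb_l[, 2])),
                  depth = unname(diff(bb_l[, 3]))),
      columella_gap = retainer_gap_mm(res$mesh)
    ),
    validation = unclass(val)[c("watertight", "consistently_wound", "positive_volume",
                                "degenerate_face_count", "volume_mm3", "ok")],
    config = config_as_list(config)
  )
  if (!is.null(report_path))
    jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(scale = scale, measurements = meas, plan = res$plan,
                 mesh = res$mesh, validation = val, report = report))
}
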