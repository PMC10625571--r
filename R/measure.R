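SEGMENT_ROLES <- c("calibrator", "width_left", "width_right",
                   "height_left", "height_right", "columella")
MEASURE_ROLES <- setdiff(SEGMENT_ROLES, "calibrator")

#' Annotation line segment in pixel coordinates
#'
#' A drawn line on the basilar-view photograph: two endpoints in float
#' pixel coordinates (origin top-left, x right, y down) plus a role tag.
#' Width and height lines are free segments, not axis projections: the
#' measured quantity is the full euclidean length of the line, which keeps
#' measurements correct under small head roll. Sides are anatomical (the
#' patient's left/right), recorded explicitly in the role rather than
#' inferred from image position.
#'
#' @param x1,y1,x2,y2 endpoint coordinates in pixels.
#' @param role one of `"calibrator"`, `"width_left"`, `"width_right"`,
#'   `"height_left"`, `"height_right"`, `"columella"`.
#' @return An object of class `pixel_segment`.
#' @export
pixel_segment <- function(x1, y1, x2, y2, role) {
  role <- match.arg(role, SEGMENT_ROLES)
  stopifnot(is.finite(x1), is.finite(y1), is.finite(x2), is.finite(y2))
  structure(list(p1 = c(x = as.numeric(x1), y = as.numeric(y1)),
                 p2 = c(x = as.numeric(x2), y = as.numeric(y2)),
                 role = role),
            class = "pixel_segment")
}

#' Euclidean length of a segment in pixels
#' @param seg a [pixel_segment()].
#' @return Non-negative length in pixels.
#' @export
segment_length_px <- function(seg) {
  stopifnot(inherits(seg, "pixel_segment"))
  sqrt(sum((seg$p2 - seg$p1)^2))
}

#' Annotation set for one image
#'
#' Collects the drawn segments for one photograph, at most one per role.
#' A side may be absent entirely (unilateral case); the calibrator must be
#' present whenever the set is used for calibrated measurement without an
#' externally supplied scale.
#'
#' @param segments list of [pixel_segment()] objects.
#' @param image_id opaque identifier of the annotated image.
#' @return An object of class `annotation_set`; segments are stored in a
#'   named list keyed by role.
#' @export
annotation_set <- function(segments, image_id = "") {
  stopifnot(is.list(segments), all(vapply(segments, inherits, logical(1), "pixel_segment")))
  roles <- vapply(segments, `[[`, character(1), "role")
  if (anyDuplicated(roles))
    nf_stop("invalid_params", "duplicate annotation role(s): %s",
            paste(unique(roles[duplicated(roles)]), collapse = ", "))
  structure(list(segments = stats::setNames(segments, roles), image_id = image_id),
            class = "annotation_set")
}

#' Read / write annotation JSON
#'
#' One JSON document per image:
#' `{"image": id, "marker_mm": 5, "segments": [{"role", "x1", "y1", "x2", "y2"}, ...]}`,
#' coordinates in float pixels, origin top-left.
#'
#' @param path file path.
#' @return `read_annotations()` returns a list with `annotations` (an
#'   [annotation_set()]) and `marker_mm` (may be `NULL`).
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) nf_stop("file_missing", "no such annotation file: %s", path)
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  segs <- lapply(doc$segments, function(s)
    pixel_segment(s$x1, s$y1, s$x2, s$y2, s$role))
  list(annotations = annotation_set(segs, image_id = doc$image %||% ""),
       marker_mm = if (!is.null(doc$marker_mm)) as.numeric(doc$marker_mm))
}

#' @rdname read_annotations
#' @param ann an [annotation_set()].
#' @param marker_mm optional marker size recorded alongside the segments.
#' @export
write_annotations <- function(ann, path, marker_mm = NULL) {
  stopifnot(inherits(ann, "annotation_set"))
  segs <- lapply(unname(ann$segments), function(s)
    list(role = s$role, x1 = s$p1[["x"]], y1 = s$p1[["y"]],
         x2 = s$p2[["x"]], y2 = s$p2[["y"]]))
  doc <- list(image = ann$image_id, segments = segs)
  if (!is.null(marker_mm)) doc$marker_mm <- marker_mm
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Nostril measurements in millimetres
#'
#' Per-side aperture width and height plus columella width, each optional
#' (absent when its annotation is absent). This is the quantity both the
#' digital caliper and the photograph pipeline estimate.
#'
#' @param height_right_mm,height_left_mm,width_right_mm,width_left_mm,columella_mm
#'   positive lengths in mm, or `NA` when not measured.
#' @param sanity_max_mm upper plausibility bound; values at or above it
#'   raise an error (signals a wrong marker size or unit mix-up).
#' @return An object of class `nostril_measurements` (named numeric vector
#'   wrapper).
#' @export
nostril_measurements <- function(height_right_mm = NA, height_left_mm = NA,
                                 width_right_mm = NA, width_left_mm = NA,
                                 columella_mm = NA, sanity_max_mm = 50) {
  v <- c(height_right_mm = as.numeric(height_right_mm),
         height_left_mm = as.numeric(height_left_mm),
         width_right_mm = as.numeric(width_right_mm),
         width_left_mm = as.numeric(width_left_mm),
         columella_mm = as.numeric(columella_mm))
  bad <- !is.na(v) & (v <= 0 | v >= sanity_max_mm)
  if (any(bad))
    nf_stop("implausible_value",
            "measurement(s) outside (0, %g) mm: %s — check marker size and units",
            sanity_max_mm, paste(names(v)[bad], round(v[bad], 2), collapse = ", "))
  structure(list(values_mm = v, sanity_max_mm = sanity_max_mm),
            class = "nostril_measurements")
}

#' @export
print.nostril_measurements <- function(x, ...) {
  cat("<nostril_measurements (mm)>\n")
  print(round(x$values_mm, 3))
  invisible(x)
}

role_to_field <- c(width_right = "width_right_mm", width_left = "width_left_mm",
                   height_right = "height_right_mm", height_left = "height_left_mm",
                   columella = "columella_mm")

#' Convert annotations to millimetre measurements
#'
#' Each present non-calibrator segment is mapped to
#' `length_px * mm_per_px` and assigned by its role; absent roles yield
#' `NA`. If `scale` is omitted, it is derived from the set's calibrator
#' segment via [scale_from_segment()].
#'
#' @param ann an [annotation_set()].
#' @param scale a `scale_factor`, or `NULL` to use the calibrator segment.
#' @param spec a [marker_spec()], used only when `scale` is `NULL`.
#' @param sanity_max_mm plausibility bound, see [nostril_measurements()].
#' @return A [nostril_measurements()].
#' @export
measure_annotations <- function(ann, scale = NULL, spec = marker_spec(),
                                sanity_max_mm = 50) {
  stopifnot(inherits(ann, "annotation_set"))
  if (is.null(scale)) {
    cal <- ann$segments[["calibrator"]]
    if (is.null(cal))
      nf_stop("missing_calibrator",
              "annotation set has no calibrator segment and no scale was supplied")
    scale <- scale_from_segment(cal, spec)
  }
  stopifnot(inherits(scale, "scale_factor"), scale$mm_per_px > 0)
  args <- list(sanity_max_mm = sanity_max_mm)
  for (role in MEASURE_ROLES) {
    seg <- ann$segments[[role]]
    if (!is.null(seg))
      args[[role_to_field[[role]]]] <- segment_length_px(seg) * scale$mm_per_px
  }
  do.call(nostril_measurements, args)
}

#' Average replicate measurements
#'
#' Each dimension is measured several times (three by protocol) and the
#' arithmetic mean per role is used for analysis. Every role must be
#' present in all replicates or in none.
#'
#' @param reps list of [nostril_measurements()] objects.
#' @param n_required required replicate count (protocol default 3).
#' @return A [nostril_measurements()] of per-role means.
#' @export
average_replicates <- function(reps, n_required = 3) {
  stopifnot(is.list(reps), all(vapply(reps, inherits, logical(1), "nostril_measurements")))
  if (length(reps) != n_required)
    nf_stop("replicate_count_mismatch", "expected %d replicates, got %d",
            n_required, length(reps))
  m <- do.call(rbind, lapply(reps, function(r) r$values_mm))
  n_present <- colSums(!is.na(m))
  if (any(!n_present %in% c(0L, length(reps))))
    nf_stop("role_mismatch", "role(s) present in some replicates but not all: %s",
            paste(colnames(m)[!n_present %in% c(0L, length(reps))], collapse = ", "))
  out <- colMeans(m)
  do.call(nostril_measurements, as.list(out))
}

#' Measurement output as a one-row data frame
#'
#' @param m a [nostril_measurements()].
#' @param image_id identifier column value.
#' @return `data.frame` with columns `image_id`, `height_R`, `height_L`,
#'   `width_R`, `width_L`, `columella` (all mm).
#' @export
measurements_as_row <- function(m, image_id = "") {
  stopifnot(inherits(m, "nostril_measurements"))
  v <- m$values_mm
  data.frame(image_id = image_id,
             height_R = v[["height_right_mm"]], height_L = v[["height_left_mm"]],
             width_R = v[["width_right_mm"]], width_L = v[["width_left_mm"]],
             columella = v[["columella_mm"]])
}
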