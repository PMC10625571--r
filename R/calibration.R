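#' Marker and green-classifier configuration
#'
#' The physical calibration marker is a green square sticker placed at the
#' nasal tip before photography; two sizes are in use, 0.3 cm and 0.5 cm
#' per side, stored internally in millimetres (3 or 5 mm). A pixel is
#' classified as marker if its HSV hue falls in `hue_range_deg`, its
#' saturation is at least `min_saturation` and its value at least
#' `min_value`; the defaults separate a saturated green sticker from skin
#' tones and shadowed nostrils.
#'
#' @param side_mm physical side of the square in mm; one of 3 or 5.
#' @param hue_range_deg length-2 numeric, accepted hue window in degrees.
#' @param min_saturation minimum HSV saturation in `[0, 1]`.
#' @param min_value minimum HSV value in `[0, 1]`.
#' @return A list of class `marker_spec`.
#' @export
marker_spec <- function(side_mm = 5, hue_range_deg = c(90, 150),
                        min_saturation = 0.4, min_value = 0.3) {
  side_mm <- as.numeric(side_mm)
  if (!isTRUE(side_mm %in% c(3, 5)))
    nf_stop("invalid_params", "marker side must be 3 or 5 mm (0.3 or 0.5 cm), got %s", side_mm)
  stopifnot(length(hue_range_deg) == 2L, hue_range_deg[1] < hue_range_deg[2])
  structure(list(side_mm = side_mm, hue_range_deg = as.numeric(hue_range_deg),
                 min_saturation = min_saturation, min_value = min_value),
            class = "marker_spec")
}

# Logical mask of marker-coloured pixels (HSV gate).
green_mask <- function(img, spec) {
  r <- img$rgb[, , 1]; g <- img$rgb[, , 2]; b <- img$rgb[, , 3]
  hsv <- grDevices::rgb2hsv(as.vector(r), as.vector(g), as.vector(b), maxColorValue = 255)
  hue <- hsv[1, ] * 360
  ok <- hue >= spec$hue_range_deg[1] & hue <= spec$hue_range_deg[2] &
    hsv[2, ] >= spec$min_saturation & hsv[3, ] >= spec$min_value
  matrix(ok, nrow = img$height_px, ncol = img$width_px)
}

# 4-connected component labelling of a logical matrix, restricted to TRUE
# pixels (union-find over vertical/horizontal neighbour pairs). Diagonal
# touching does not connect, so thin green reflections cannot leak into
# the marker component. Returns an integer vector of component ids
# parallel to which(mask).
label_components4 <- function(mask) {
  idx <- which(mask)
  if (!length(idx)) return(list(idx = integer(0), comp = integer(0)))
  nr <- nrow(mask)
  pos <- integer(length(mask)); pos[idx] <- seq_along(idx)
  row <- ((idx - 1L) %% nr) + 1L
  col <- ((idx - 1L) %/% nr) + 1L
  up   <- idx[row > 1L & mask[pmax(idx - 1L, 1L)]]
  left <- idx[col > 1L & mask[pmax(idx - nr, 1L)]]
  edges <- cbind(pos[c(up, left)], pos[c(up - 1L, left - nr)])
  parent <- seq_along(idx)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (nrow(edges)) for (e in seq_len(nrow(edges))) {
    a <- find(edges[e, 1L]); b <- find(edges[e, 2L])
    if (a != b) parent[a] <- b
  }
  root <- vapply(seq_along(idx), find, integer(1))
  list(idx = idx, comp = match(root, unique(root)))
}

#' Detect the green calibration marker
#'
#' Finds the largest 4-connected region of marker-coloured pixels (see
#' [marker_spec()] for the HSV gate) and summarises it. The side length in
#' pixels is estimated as the mean of the bounding-box width and height of
#' the region, which is robust to one-pixel boundary raggedness; the raw
#' pixel count is kept for a square-ness sanity check. The centroid is the
#' mean of the member pixel centres (pixel `(c, r)` has centre
#' `(c + 0.5, r + 0.5)`). Detection is deterministic for fixed image bytes.
#'
#' @param img a [raster_image()].
#' @param spec a [marker_spec()].
#' @return A list of class `marker_detection` with `centroid_px` (x, y),
#'   `side_px`, `pixel_count` and `confidence` (fraction of the bounding
#'   box covered by marker pixels; 1 for a perfect axis-aligned square).
#' @export
detect_marker <- function(img, spec = marker_spec()) {
  stopifnot(inherits(img, "raster_image"))
  lab <- label_components4(green_mask(img, spec))
  if (!length(lab$idx))
    nf_stop("marker_not_found", "no pixel passes the green marker classifier")
  sizes <- tabulate(lab$comp)
  sizes[sizes < 9L] <- 0L  # reject degenerate specks
  if (all(sizes == 0L))
    nf_stop("marker_not_found", "green regions found but all below 9 px")
  big <- which.max(sizes)
  if (sum(sizes > 0L) > 1L && sort(sizes, decreasing = TRUE)[2] >= 0.5 * sizes[big])
    nf_stop("ambiguous_marker",
            "two comparable green regions (%d and %d px); cannot pick the marker",
            sizes[big], sort(sizes, decreasing = TRUE)[2])
  sel <- lab$idx[lab$comp == big]
  nr <- img$height_px
  row0 <- ((sel - 1L) %% nr)        # zero-based pixel indices
  col0 <- ((sel - 1L) %/% nr)
  bb_w <- max(col0) - min(col0) + 1L
  bb_h <- max(row0) - min(row0) + 1L
  n <- length(sel)
  det <- structure(list(
    centroid_px = c(x = mean(col0) + 0.5, y = mean(row0) + 0.5),
    side_px = (bb_w + bb_h) / 2,
    pixel_count = n,
    confidence = n / (bb_w * bb_h)
  ), class = "marker_detection")
  if (abs(det$side_px - sqrt(n)) / det$side_px > 0.25)
    nf_stop("ambiguous_marker",
            "largest green region is not square-like (side %.1f px vs sqrt(area) %.1f px)",
            det$side_px, sqrt(n))
  det
}

#' Pixel-to-millimetre scale from a drawn calibrator segment
#'
#' The user draws a line spanning one side of the green square; dividing
#' the marker's physical side by the segment's pixel length gives the
#' image scale in mm per pixel.
#'
#' @param seg a [pixel_segment()] with role `"calibrator"`.
#' @param spec a [marker_spec()] giving the physical side in mm.
#' @return A list of class `scale_factor` with `mm_per_px` and `source`.
#' @export
scale_from_segment <- function(seg, spec = marker_spec()) {
  stopifnot(inherits(seg, "pixel_segment"), inherits(spec, "marker_spec"))
  if (!identical(seg$role, "calibrator"))
    nf_stop("invalid_params", "scale segment must have role 'calibrator', got '%s'", seg$role)
  len <- segment_length_px(seg)
  if (len <= 0) nf_stop("zero_length_segment", "calibrator segment has zero length")
  structure(list(mm_per_px = spec$side_mm / len, source = "from_segment"),
            class = "scale_factor")
}

#' Pixel-to-millimetre scale from an automatic marker detection
#'
#' @param det a `marker_detection` from [detect_marker()].
#' @param spec a [marker_spec()].
#' @return A `scale_factor` as in [scale_from_segment()].
#' @export
scale_from_detection <- function(det, spec = marker_spec()) {
  stopifnot(inherits(det, "marker_detection"), inherits(spec, "marker_spec"))
  if (!is.finite(det$side_px) || det$side_px <= 0)
    nf_stop("degenerate_detection", "detected marker side must be > 0 px")
  structure(list(mm_per_px = spec$side_mm / det$side_px, source = "from_detection"),
            class = "scale_factor")
}
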