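# Run expr with a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# x half-extent of an ellipse with semi-axes (rx, ry) rolled by phi (rad)
ellipse_x_extent <- function(rx, ry, phi) sqrt((rx * cos(phi))^2 + (ry * sin(phi))^2)
ellipse_y_extent <- function(rx, ry, phi) sqrt((rx * sin(phi))^2 + (ry * cos(phi))^2)

#' Specification of a synthetic basilar-view image
#'
#' Describes a flat-shaded stand-in for a basilar-view photograph with
#' exact ground truth: a skin-tone background, an axis-aligned green
#' calibration square of known physical size, and two dark elliptical
#' nostril apertures separated by a columella-wide strip of background.
#' It emulates the geometry and colour contrast that drive calibration
#' and measurement — not skin texture, lighting, or perspective.
#'
#' Pixel geometry: the marker square side is `round(side_mm / mm_per_px)`
#' pixels (the rounding is recorded in the ground truth); nostril centres
#' are placed so the horizontal gap between the ellipses' inner extreme
#' points equals `columella_mm`.
#'
#' @param mm_per_px ground-truth image scale.
#' @param marker_side_mm physical marker side, 3 or 5 mm.
#' @param width_right_mm,height_right_mm,width_left_mm,height_left_mm
#'   nostril aperture dimensions in mm (anatomical sides; the patient's
#'   right appears on the image's left here, at negative x from the
#'   mid-line).
#' @param columella_mm gap between the apertures in mm.
#' @param roll_right_deg,roll_left_deg in-plane rotation of each aperture.
#' @param image_px `c(width, height)` in pixels, or `NULL` to size the
#'   canvas automatically around the shapes.
#' @param marker_center_px,nostril_center_y_px layout overrides (pixels);
#'   `NULL` for automatic layout.
#' @param skin_rgb,nostril_rgb,marker_rgb 8-bit colours.
#' @param antialias logical; `FALSE` (default) renders hard-edged shapes
#'   so pixel counts are exact, `TRUE` feathers edges over one pixel to
#'   stress sub-pixel robustness.
#' @param seed bookkeeping seed recorded in the ground truth (rendering
#'   itself is deterministic).
#' @return A list of class `synthetic_face_spec`.
#' @export
synthetic_face_spec <- function(mm_per_px = 0.1, marker_side_mm = 5,
                                width_right_mm = 6.8, height_right_mm = 9.9,
                                width_left_mm = 7.0, height_left_mm = 9.8,
                                columella_mm = 5.8,
                                roll_right_deg = 0, roll_left_deg = 0,
                                image_px = NULL, marker_center_px = NULL,
                                nostril_center_y_px = NULL,
                                skin_rgb = c(224, 172, 140),
                                nostril_rgb = c(40, 20, 20),
                                marker_rgb = c(0, 200, 0),
                                antialias = FALSE, seed = 1L) {
  stopifnot(mm_per_px > 0, all(c(width_right_mm, height_right_mm, width_left_mm,
                                 height_left_mm, columella_mm) > 0))
  px <- function(mm) mm / mm_per_px
  side_px <- round(px(marker_side_mm))
  ex_r <- ellipse_x_extent(px(width_right_mm) / 2, px(height_right_mm) / 2,
                           roll_right_deg * pi / 180)
  ex_l <- ellipse_x_extent(px(width_left_mm) / 2, px(height_left_mm) / 2,
                           roll_left_deg * pi / 180)
  ey <- max(ellipse_y_extent(px(width_right_mm) / 2, px(height_right_mm) / 2,
                             roll_right_deg * pi / 180),
            ellipse_y_extent(px(width_left_mm) / 2, px(height_left_mm) / 2,
                             roll_left_deg * pi / 180))
  margin <- 16
  if (is.null(image_px)) {
    # layout is symmetric about the vertical mid-line, so the half-width
    # must accommodate the larger aperture on either side
    w <- ceiling(max(px(columella_mm) + 4 * max(ex_r, ex_l), side_px) + 2 * margin)
    h <- ceiling(side_px + 2 * ey + 3 * margin)
    image_px <- c(w, h)
  }
  if (is.null(marker_center_px))
    marker_center_px <- c(image_px[1] / 2, margin + side_px / 2)
  if (is.null(nostril_center_y_px))
    nostril_center_y_px <- margin + side_px + margin + ey
  spec <- structure(list(
    mm_per_px = mm_per_px, marker_side_mm = marker_side_mm,
    width_right_mm = width_right_mm, height_right_mm = height_right_mm,
    width_left_mm = width_left_mm, height_left_mm = height_left_mm,
    columella_mm = columella_mm,
    roll_right_deg = roll_right_deg, roll_left_deg = roll_left_deg,
    image_px = as.integer(ceiling(image_px)),
    marker_center_px = marker_center_px,
    nostril_center_y_px = nostril_center_y_px,
    skin_rgb = skin_rgb, nostril_rgb = nostril_rgb, marker_rgb = marker_rgb,
    antialias = isTRUE(antialias), seed = as.integer(seed)
  ), class = "synthetic_face_spec")
  validate_face_spec(spec)
  spec
}

validate_face_spec <- function(spec) {
  px <- function(mm) mm / spec$mm_per_px
  side_px <- round(px(spec$marker_side_mm))
  w <- spec$image_px[1]; h <- spec$image_px[2]
  mc <- spec$marker_center_px
  m_top <- mc[2] - side_px / 2; m_bot <- mc[2] + side_px / 2
  if (mc[1] - side_px / 2 < 0 || mc[1] + side_px / 2 > w || m_top < 0 || m_bot > h)
    nf_stop("out_of_bounds", "marker square leaves the image canvas")
  geo <- nostril_geometry(spec)
  for (s in c("right", "left")) {
    g <- geo[[s]]
    if (g$cx - g$ex < 0 || g$cx + g$ex > w ||
        g$cy - g$ey < 0 || g$cy + g$ey > h)
      nf_stop("out_of_bounds", "%s nostril ellipse leaves the image canvas", s)
    if (g$cy - g$ey <= m_bot && g$cy + g$ey >= m_top &&
        g$cx + g$ex >= mc[1] - side_px / 2 && g$cx - g$ex <= mc[1] + side_px / 2)
      nf_stop("spec_overlap", "%s nostril ellipse overlaps the marker square", s)
  }
  invisible(spec)
}

# Pixel-space centres/extents of the two nostril ellipses.
nostril_geometry <- function(spec) {
  px <- function(mm) mm / spec$mm_per_px
  mid_x <- spec$image_px[1] / 2
  cy <- spec$nostril_center_y_px
  out <- list()
  for (s in c("right", "left")) {
    rx <- px(spec[[paste0("width_", s, "_mm")]]) / 2
    ry <- px(spec[[paste0("height_", s, "_mm")]]) / 2
    phi <- spec[[paste0("roll_", s, "_deg")]] * pi / 180
    ex <- ellipse_x_extent(rx, ry, phi)
    sign <- if (s == "right") -1 else 1     # anatomical right at negative x
    cx <- mid_x + sign * (px(spec$columella_mm) / 2 + ex)
    out[[s]] <- list(cx = cx, cy = cy, rx = rx, ry = ry, phi = phi,
                     ex = ex, ey = ellipse_y_extent(rx, ry, phi))
  }
  out
}

#' Render a synthetic basilar-view image with ground truth
#'
#' Rasterises the [synthetic_face_spec()]: shapes are filled by testing
#' pixel centres (pixel `(c, r)` has centre `(c + 0.5, r + 0.5)`), so with
#' anti-aliasing off the marker region's pixel count is exactly its side
#' squared. The ground truth carries the true scale, the rendered marker
#' side in pixels, every mm dimension, and the ideal [annotation_set()]
#' (calibrator spanning the top side of the square; width/height lines
#' along each aperture's rolled axes; columella line between the inner
#' extreme points of the two ellipses).
#'
#' @param spec a [synthetic_face_spec()].
#' @return List with `image` (a [raster_image()]) and `truth` (list with
#'   `annotations`, `mm_per_px`, `marker_side_px`, `marker_pixel_count`
#'   and the true mm dimensions).
#' @export
render_basilar <- function(spec) {
  stopifnot(inherits(spec, "synthetic_face_spec"))
  validate_face_spec(spec)
  w <- spec$image_px[1]; h <- spec$image_px[2]
  xc <- matrix(rep(seq_len(w) - 0.5, each = h), nrow = h)   # pixel-centre x
  yc <- matrix(rep(seq_len(h) - 0.5, times = w), nrow = h)  # pixel-centre y
  cover <- function(signed_dist) {
    # signed distance < 0 inside; AA feathers over ~1 px
    if (spec$antialias) pmin(pmax(0.5 - signed_dist, 0), 1) else (signed_dist < 0) * 1
  }
  px <- function(mm) mm / spec$mm_per_px
  side_px <- round(px(spec$marker_side_mm))
  c0 <- round(spec$marker_center_px[1] - side_px / 2)
  r0 <- round(spec$marker_center_px[2] - side_px / 2)
  d_marker <- pmax(pmax(c0 - xc, xc - (c0 + side_px)), pmax(r0 - yc, yc - (r0 + side_px)))
  a_marker <- cover(d_marker)

  geo <- nostril_geometry(spec)
  a_nostril <- matrix(0, h, w)
  for (g in geo) {
    u <- (xc - g$cx) * cos(g$phi) + (yc - g$cy) * sin(g$phi)
    v <- -(xc - g$cx) * sin(g$phi) + (yc - g$cy) * cos(g$phi)
    q <- sqrt((u / g$rx)^2 + (v / g$ry)^2)
    # approximate signed distance via local radius
    r_local <- 1 / sqrt((cos(atan2(v / g$ry, u / g$rx)) / g$rx)^2 +
                        (sin(atan2(v / g$ry, u / g$rx)) / g$ry)^2)
    a_nostril <- pmax(a_nostril, cover((q - 1) * r_local))
  }
  rgb <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) {
    base <- spec$skin_rgb[ch] * (1 - a_marker) + spec$marker_rgb[ch] * a_marker
    rgb[, , ch] <- round(base * (1 - a_nostril) + spec$nostril_rgb[ch] * a_nostril)
  }
  img <- raster_image(rgb)

  mk <- function(p1, p2, role) pixel_segment(p1[1], p1[2], p2[1], p2[2], role)
  segs <- list(mk(c(c0, r0), c(c0 + side_px, r0), "calibrator"))
  for (s in c("right", "left")) {
    g <- geo[[s]]
    ux <- c(cos(g$phi), sin(g$phi)); uy <- c(-sin(g$phi), cos(g$phi))
    cc <- c(g$cx, g$cy)
    segs <- c(segs, list(
      mk(cc - g$rx * ux, cc + g$rx * ux, paste0("width_", s)),
      mk(cc - g$ry * uy, cc + g$ry * uy, paste0("height_", s))))
  }
  mid_x <- w / 2; cy <- spec$nostril_center_y_px
  col_half <- px(spec$columella_mm) / 2
  segs <- c(segs, list(mk(c(mid_x - col_half, cy), c(mid_x + col_half, cy), "columella")))
  truth <- list(
    mm_per_px = spec$mm_per_px,
    marker_side_px = side_px,
    marker_pixel_count = side_px^2,
    marker_side_mm = spec$marker_side_mm,
    dims_mm = c(height_right_mm = spec$height_right_mm,
                height_left_mm = spec$height_left_mm,
                width_right_mm = spec$width_right_mm,
                width_left_mm = spec$width_left_mm,
                columella_mm = spec$columella_mm),
    annotations = annotation_set(segs, image_id = sprintf("synthetic-%d", spec$seed))
  )
  list(image = img, truth = truth)
}

#' Save a raster image as PNG
#' @param img a [raster_image()].
#' @param path output `.png` path.
#' @export
save_image <- function(img, path) {
  stopifnot(inherits(img, "raster_image"))
  png::writePNG(img$rgb / 255, path)
  invisible(path)
}

#' Jitter annotation endpoints
#'
#' Models human line-drawing error, the dominant source of discrepancy
#' between caliper and photograph measurements: every segment endpoint is
#' displaced by i.i.d. Gaussian noise in both axes. Deterministic per
#' seed; the caller's RNG state is untouched.
#'
#' @param ann an [annotation_set()] (e.g. the ideal one from
#'   [render_basilar()]).
#' @param jitter_px_sd standard deviation of the displacement in pixels.
#' @param seed integer seed.
#' @return A perturbed [annotation_set()].
#' @export
perturb_annotations <- function(ann, jitter_px_sd, seed) {
  stopifnot(inherits(ann, "annotation_set"), jitter_px_sd >= 0)
  if (jitter_px_sd == 0) return(ann)
  with_seed(seed, {
    segs <- lapply(unname(ann$segments), function(s) {
      e <- stats::rnorm(4, 0, jitter_px_sd)
      pixel_segment(s$p1[["x"]] + e[1], s$p1[["y"]] + e[2],
                    s$p2[["x"]] + e[3], s$p2[["y"]] + e[4], s$role)
    })
    annotation_set(segs, image_id = ann$image_id)
  })
}

#' Simulate a subjects-by-raters rating matrix
#'
#' Two-way random-effects model
#' `value[i, j] = true_mean + subject_i + bias_j + noise_ij` with
#' `subject_i ~ N(0, subject_sd^2)` and `noise_ij ~ N(0, error_sd^2)`;
#' rater biases are supplied fixed. The implied true ICC(2,1) is
#' `subject_sd^2 / (subject_sd^2 + var(bias) + error_sd^2)` where
#' `var(bias)` is the population variance of the supplied biases (the
#' rater variance component they realise).
#'
#' @param n_subjects number of subjects (rows).
#' @param k_raters number of raters (columns).
#' @param subject_sd_mm between-subject SD.
#' @param rater_bias_mm numeric vector of length `k_raters` (recycled).
#' @param error_sd_mm residual SD.
#' @param true_mean_mm grand mean.
#' @param seed integer seed.
#' @return List with `ratings` (matrix) and `true_icc`.
#' @export
simulate_raters <- function(n_subjects, k_raters, subject_sd_mm = 1,
                            rater_bias_mm = 0, error_sd_mm = 1,
                            true_mean_mm = 10, seed = 1L) {
  stopifnot(n_subjects >= 1, k_raters >= 1, subject_sd_mm >= 0, error_sd_mm >= 0)
  bias <- rep_len(rater_bias_mm, k_raters)
  var_bias <- mean((bias - mean(bias))^2)
  denom <- subject_sd_mm^2 + var_bias + error_sd_mm^2
  true_icc <- if (denom == 0) 1 else subject_sd_mm^2 / denom
  ratings <- with_seed(seed, {
    subj <- stats::rnorm(n_subjects, 0, subject_sd_mm)
    noise <- matrix(stats::rnorm(n_subjects * k_raters, 0, error_sd_mm),
                    n_subjects, k_raters)
    true_mean_mm + outer(subj, bias, `+`) + noise
  })
  list(ratings = ratings, true_icc = true_icc)
}

#' Random plausible face spec for simulation studies
#'
#' Draws the image scale uniformly from `scale_range` and the nostril and
#' columella dimensions from Gaussians representative of post-operative
#' cleft nares (heights 9.9 +/- 1.6 and 9.8 +/- 1.1 mm, widths
#' 6.8 +/- 0.8 and 7.0 +/- 1.5 mm, columella 5.8 +/- 0.9 mm), truncated
#' below at 2 mm to stay anatomically plausible.
#'
#' @param seed integer seed.
#' @param scale_range `c(min, max)` of mm per pixel.
#' @param marker_side_mm marker size used for every draw.
#' @return A [synthetic_face_spec()].
#' @export
random_face_spec <- function(seed, scale_range = c(0.05, 0.2), marker_side_mm = 5) {
  with_seed(seed, {
    draw <- function(m, s) max(2, stats::rnorm(1, m, s))
    synthetic_face_spec(
      mm_per_px = stats::runif(1, scale_range[1], scale_range[2]),
      marker_side_mm = marker_side_mm,
      width_right_mm = draw(6.8, 0.8), height_right_mm = draw(9.9, 1.6),
      width_left_mm = draw(7.0, 1.5), height_left_mm = draw(9.8, 1.1),
      columella_mm = draw(5.8, 0.9),
      seed = seed
    )
  })
}
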