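#' Retainer template parameters
#'
#' The canonical symmetric nostril retainer: two hollow elliptical crura
#' (one per nostril), closed at the superior (inserted) end by a rounded
#' cap, open at the inferior end with the rim filled as an annular face,
#' joined at the inferior end by a rectangular bridge bar spanning the
#' columella gap. All dimensions in mm. The width/height/columella
#' defaults are anchored to healthy adult nares means so an "average"
#' retainer needs no patient input.
#'
#' @param nominal_width_mm outer aperture width of each crus (x axis).
#' @param nominal_height_mm outer aperture height of each crus (y axis).
#' @param nominal_columella_mm gap between the inner-facing crus surfaces.
#' @param wall_mm tube wall thickness; must be < half the smaller aperture
#'   dimension.
#' @param depth_mm crus length along the insertion (+z) axis, cap included.
#' @param bridge_mm cross-section side of the square bridge bar.
#' @param segments angular resolution of the elliptical cross-section;
#'   must be a multiple of 4 and at least 8, so that the extreme-axis
#'   vertices exist at every resolution and the outer bounding box is
#'   resolution-independent.
#' @return A list of class `template_params`.
#' @export
template_params <- function(nominal_width_mm = 8.6, nominal_height_mm = 12.5,
                            nominal_columella_mm = 6.8, wall_mm = 1.5,
                            depth_mm = 12, bridge_mm = 2, segments = 48) {
  p <- list(nominal_width_mm = nominal_width_mm,
            nominal_height_mm = nominal_height_mm,
            nominal_columella_mm = nominal_columella_mm,
            wall_mm = wall_mm, depth_mm = depth_mm, bridge_mm = bridge_mm,
            segments = as.integer(segments))
  num <- unlist(p[1:6])
  if (any(!is.finite(num)) || any(num <= 0))
    nf_stop("invalid_params", "all template dimensions must be positive")
  if (wall_mm >= min(nominal_width_mm, nominal_height_mm) / 2)
    nf_stop("invalid_params", "wall (%g mm) must be < min(width, height)/2", wall_mm)
  if (p$segments < 8L || p$segments %% 4L != 0L)
    nf_stop("invalid_params", "segments must be a multiple of 4, >= 8")
  if (bridge_mm >= nominal_height_mm || bridge_mm >= depth_mm)
    nf_stop("invalid_params", "bridge bar must be smaller than the crus height and depth")
  structure(p, class = "template_params")
}

# Ring of n points on an ellipse of semi-axes (a, b) centred at (cx, 0),
# at height z. theta = 0 points +x; counter-clockwise seen from +z.
ellipse_ring <- function(n, cx, a, b, z) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  cbind(cx + a * cos(th), b * sin(th), z)
}

# Triangles of a quad band between two rings of equal length; lower/upper
# are vertex index vectors ordered counter-clockwise (from +z). With
# lower below upper this winds outward for a tube; reverse = TRUE flips
# orientation (used for the inner wall, whose outward side faces the axis).
band_faces <- function(lower, upper, reverse = FALSE) {
  n <- length(lower)
  k1 <- seq_len(n); k2 <- c(2:n, 1L)
  tri <- rbind(cbind(lower[k1], lower[k2], upper[k2]),
               cbind(lower[k1], upper[k2], upper[k1]))
  if (reverse) tri[, c(1, 3, 2)] else tri
}

fan_faces <- function(ring, apex, reverse = FALSE) {
  n <- length(ring)
  tri <- cbind(ring, c(ring[-1], ring[1]), apex)
  if (reverse) tri[, c(1, 3, 2)] else tri
}

# One hollow crus: outer wall + rounded superior cap, inner wall + flat
# inner ceiling, annular inferior rim. Closed, outward-oriented.
# Returns list(vertices, faces) with faces 1-based into its own vertices.
crus_mesh <- function(cx, a, b, wall, depth, n) {
  m <- max(2L, n %/% 8L)       # dome bands
  cap <- wall                  # rounded-cap height; keeps apex wall = wall_mm
  zc <- depth - cap            # dome base
  zi <- depth - wall           # inner ceiling
  verts <- ellipse_ring(n, cx, a, b, 0)                      # 1 outer bottom
  verts <- rbind(verts, ellipse_ring(n, cx, a, b, zc))       # 2 outer top
  for (j in seq_len(m - 1)) {                                # dome rings
    t <- j * (pi / 2) / m
    verts <- rbind(verts, ellipse_ring(n, cx, a * cos(t), b * cos(t), zc + cap * sin(t)))
  }
  apex <- nrow(verts) + 1L
  verts <- rbind(verts, c(cx, 0, depth))
  ib <- apex                                                  # inner bottom ring start - 0
  verts <- rbind(verts, ellipse_ring(n, cx, a - wall, b - wall, 0))
  verts <- rbind(verts, ellipse_ring(n, cx, a - wall, b - wall, zi))
  icap <- nrow(verts) + 1L
  verts <- rbind(verts, c(cx, 0, zi))

  ring <- function(i) ((i - 1L) * n) + seq_len(n)  # rings stacked before apex
  OB <- ring(1); OT <- ring(2)
  dome <- lapply(seq_len(m - 1), function(j) ring(2L + j))
  IB <- apex + seq_len(n); IT <- apex + n + seq_len(n)

  faces <- band_faces(OB, OT)                      # outer wall
  prev <- OT
  for (d in dome) { faces <- rbind(faces, band_faces(prev, d)); prev <- d }
  faces <- rbind(faces, fan_faces(prev, apex))     # dome apex fan
  faces <- rbind(faces, band_faces(IB, IT, reverse = TRUE))  # inner wall
  faces <- rbind(faces, fan_faces(IT, icap, reverse = TRUE)) # inner ceiling (faces cavity)
  n1 <- seq_len(n); n2 <- c(2:n, 1L)
  rim <- rbind(cbind(OB[n1], IB[n1], IB[n2]),      # inferior annular rim, -z
               cbind(OB[n1], IB[n2], OB[n2]))
  faces <- rbind(faces, rim)
  list(vertices = verts, faces = faces)
}

# Closed axis-aligned box, outward-oriented.
box_mesh <- function(xlim, ylim, zlim) {
  g <- expand.grid(x = xlim, y = ylim, z = zlim)   # binary order: x fastest
  v <- as.matrix(g)
  # vertex index = 1 + (x hi) + 2*(y hi) + 4*(z hi)
  f <- rbind(
    c(1, 3, 4), c(1, 4, 2),   # z = lo, normal -z
    c(5, 6, 8), c(5, 8, 7),   # z = hi, normal +z
    c(1, 2, 6), c(1, 6, 5),   # y = lo, normal -y
    c(3, 7, 8), c(3, 8, 4),   # y = hi, normal +y
    c(1, 5, 7), c(1, 7, 3),   # x = lo, normal -x
    c(2, 4, 8), c(2, 8, 6)    # x = hi, normal +x
  )
  list(vertices = v, faces = f)
}

assemble_retainer <- function(params, a_r, b_r, a_l, b_l, gap) {
  n <- params$segments; w <- params$wall_mm; depth <- params$depth_mm
  cx_r <- -(gap / 2 + a_r); cx_l <- gap / 2 + a_l
  right <- crus_mesh(cx_r, a_r, b_r, w, depth, n)
  left  <- crus_mesh(cx_l, a_l, b_l, w, depth, n)
  br <- box_mesh(c(-gap / 2 - w, gap / 2 + w),
                 c(-params$bridge_mm / 2, params$bridge_mm / 2),
                 c(0, params$bridge_mm))
  nv_r <- nrow(right$vertices); nv_l <- nrow(left$vertices)
  verts <- rbind(right$vertices, left$vertices, br$vertices)
  faces <- rbind(right$faces, left$faces + nv_r, br$faces + nv_r + nv_l)
  mesh <- tri_mesh(verts, faces)
  attr(mesh, "parts") <- list(
    right = list(vidx = seq_len(nv_r), center_x = cx_r),
    left = list(vidx = nv_r + seq_len(nv_l), center_x = cx_l),
    bridge = list(vidx = nv_r + nv_l + seq_len(nrow(br$vertices))),
    gap_mm = gap
  )
  attr(mesh, "params") <- params
  mesh
}

#' Build the symmetric retainer template mesh
#'
#' Constructs the canonical two-crura retainer described in
#' [template_params()]: each crus is a hollow elliptical tube whose outer
#' cross-section is `nominal_width_mm x nominal_height_mm`, wall
#' `wall_mm`, total length `depth_mm`, closed at the superior end by a
#' rounded cap of height `wall_mm` and sealed at the inferior end by an
#' annular rim face; the crura sit symmetrically about the mid-sagittal
#' plane `x = 0` with their inner-facing surfaces `nominal_columella_mm`
#' apart, and a square bridge bar spans the gap at the inferior end
#' (embedding one wall-thickness into each crus). The three solids are
#' each closed and outward-oriented, so the mesh as a whole is watertight.
#'
#' @param params a [template_params()].
#' @return A [tri_mesh()] carrying part metadata used by [apply_reshape()].
#' @export
build_template <- function(params = template_params()) {
  stopifnot(inherits(params, "template_params"))
  a <- params$nominal_width_mm / 2; b <- params$nominal_height_mm / 2
  assemble_retainer(params, a, b, a, b, params$nominal_columella_mm)
}

#' Plan the per-nostril reshape
#'
#' Converts patient measurements into per-side axis scale factors against
#' the template nominals: `fx = target_width / nominal_width`,
#' `fy = target_height / nominal_height` per side. A side with no
#' measurements keeps exact unit factors, so resizing one nostril never
#' touches the other (unilateral deformity case). Overcorrection offsets
#' are additive in mm (surgeons reason in mm of overcorrection), applied
#' to the targets before the factors are computed. The columella target
#' sets the inter-crus gap; when unmeasured it stays at the nominal.
#'
#' @param m a [nostril_measurements()].
#' @param params a [template_params()].
#' @param overcorrect list with optional elements `left` and `right`, each
#'   `c(dx_mm, dy_mm)` added to that side's width/height targets.
#' @return A list of class `reshape_plan` with `fx_left`, `fy_left`,
#'   `fx_right`, `fy_right`, `columella_target_mm` and target dims.
#' @export
plan_reshape <- function(m, params = template_params(),
                         overcorrect = list(left = c(0, 0), right = c(0, 0))) {
  stopifnot(inherits(m, "nostril_measurements"), inherits(params, "template_params"))
  v <- m$values_mm
  oc <- function(side) {
    o <- overcorrect[[side]] %||% c(0, 0)
    stopifnot(length(o) == 2, all(is.finite(o)))
    o
  }
  side_factors <- function(side) {
    w <- v[[paste0("width_", side, "_mm")]]
    h <- v[[paste0("height_", side, "_mm")]]
    o <- oc(side)
    tw <- if (is.na(w)) params$nominal_width_mm else w + o[1]
    th <- if (is.na(h)) params$nominal_height_mm else h + o[2]
    if (tw <= 0 || th <= 0)
      nf_stop("non_positive_measurement",
              "%s-side target dimensions must be positive after overcorrection", side)
    list(fx = if (is.na(w)) 1 else tw / params$nominal_width_mm,
         fy = if (is.na(h)) 1 else th / params$nominal_height_mm,
         target_w = tw, target_h = th)
  }
  L <- side_factors("left"); R <- side_factors("right")
  col <- if (is.na(v[["columella_mm"]])) params$nominal_columella_mm else v[["columella_mm"]]
  if (col <= 0) nf_stop("non_positive_measurement", "columella target must be positive")
  structure(list(fx_left = L$fx, fy_left = L$fy, fx_right = R$fx, fy_right = R$fy,
                 target_width_left_mm = L$fx * params$nominal_width_mm,
                 target_height_left_mm = L$fy * params$nominal_height_mm,
                 target_width_right_mm = R$fx * params$nominal_width_mm,
                 target_height_right_mm = R$fy * params$nominal_height_mm,
                 columella_target_mm = col),
            class = "reshape_plan")
}

#' Apply a reshape plan to the template
#'
#' Scales each crus's vertices by `(fx, fy)` in the cross-section plane
#' about that crus's own axis (so one nostril's resize never distorts the
#' other and z extents are untouched), translates the crura along x so
#' the inter-crus gap equals the columella target, and regenerates the
#' bridge bar to span the new gap. The result is re-validated; a failed
#' manifold check is an error, never a warning.
#'
#' @param template mesh from [build_template()] (its part metadata is
#'   required).
#' @param plan a `reshape_plan` from [plan_reshape()].
#' @return A [tri_mesh()] satisfying the same structural contract as the
#'   template, with each crus outer bounding box equal to
#'   `(fx * nominal_width, fy * nominal_height)`.
#' @export
apply_reshape <- function(template, plan) {
  stopifnot(inherits(template, "tri_mesh"), inherits(plan, "reshape_plan"))
  parts <- attr(template, "parts"); params <- attr(template, "params")
  if (is.null(parts) || is.null(params))
    nf_stop("invalid_params", "template must come from build_template()")
  a <- params$nominal_width_mm / 2
  gap <- plan$columella_target_mm
  v <- template$vertices

  move_crus <- function(vidx, old_cx, fx, fy, new_cx) {
    v[vidx, 1] <<- new_cx + fx * (v[vidx, 1] - old_cx)
    v[vidx, 2] <<- fy * v[vidx, 2]
  }
  cx_r <- -(gap / 2 + plan$fx_right * a)
  cx_l <- gap / 2 + plan$fx_left * a
  move_crus(parts$right$vidx, parts$right$center_x, plan$fx_right, plan$fy_right, cx_r)
  move_crus(parts$left$vidx, parts$left$center_x, plan$fx_left, plan$fy_left, cx_l)

  # drop the old bridge (its vertices form the trailing block) and refit
  keep_v <- setdiff(seq_len(nrow(v)), parts$bridge$vidx)
  crus_faces <- template$faces[apply(template$faces, 1, function(f)
    all(f %in% keep_v)), , drop = FALSE]
  br <- box_mesh(c(-gap / 2 - params$wall_mm, gap / 2 + params$wall_mm),
                 c(-params$bridge_mm / 2, params$bridge_mm / 2),
                 c(0, params$bridge_mm))
  nv <- length(keep_v)
  out <- tri_mesh(rbind(v[keep_v, , drop = FALSE], br$vertices),
                  rbind(crus_faces, br$faces + nv))
  attr(out, "parts") <- list(
    right = list(vidx = parts$right$vidx, center_x = cx_r),
    left = list(vidx = parts$left$vidx, center_x = cx_l),
    bridge = list(vidx = nv + seq_len(nrow(br$vertices))),
    gap_mm = gap
  )
  attr(out, "params") <- params
  val <- validate_mesh(out)
  if (!val$ok)
    nf_stop("broken_manifold", "reshaped mesh failed validation (watertight=%s wound=%s vol=%.3f)",
            val$watertight, val$consistently_wound, val$volume_mm3)
  out
}

#' Inter-crus gap of a retainer mesh
#'
#' Distance between the nearest facing vertices of the two crura across
#' the mid-sagittal plane — the realised columella width.
#'
#' @param mesh a retainer mesh with part metadata.
#' @return Gap in mm.
#' @export
retainer_gap_mm <- function(mesh) {
  parts <- attr(mesh, "parts")
  if (is.null(parts)) nf_stop("invalid_params", "mesh has no part metadata")
  max_r <- max(mesh$vertices[parts$right$vidx, 1])
  min_l <- min(mesh$vertices[parts$left$vidx, 1])
  min_l - max_r
}
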