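#' Triangle mesh container
#'
#' Vertices in millimetres in a right-handed frame, faces as 1-based
#' vertex-index triples wound counter-clockwise when seen from outside the
#' solid (outward orientation). The retainer frame convention is
#' `+z` = insertion direction into the nares, `+y` = nostril height axis,
#' `+x` = width axis, mid-sagittal plane `x = 0`. One STL unit = 1 mm.
#'
#' @param vertices numeric matrix `n x 3`.
#' @param faces integer matrix `m x 3` of 1-based vertex indices.
#' @return An object of class `tri_mesh`.
#' @export
tri_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices); storage.mode(vertices) <- "double"
  faces <- as.matrix(faces); storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L || ncol(faces) != 3L)
    nf_stop("invalid_mesh", "vertices and faces must have 3 columns")
  if (nrow(faces) && (min(faces) < 1L || max(faces) > nrow(vertices)))
    nf_stop("invalid_mesh", "face indices out of range")
  structure(list(vertices = vertices, faces = faces), class = "tri_mesh")
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("<tri_mesh: %d vertices, %d faces>\n", nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

face_cross <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  ab <- v[f[, 2], , drop = FALSE] - a
  ac <- v[f[, 3], , drop = FALSE] - a
  cbind(ab[, 2] * ac[, 3] - ab[, 3] * ac[, 2],
        ab[, 3] * ac[, 1] - ab[, 1] * ac[, 3],
        ab[, 1] * ac[, 2] - ab[, 2] * ac[, 1])
}

#' Signed enclosed volume of a closed mesh
#'
#' Divergence-theorem sum over faces; positive for a closed, outward-
#' oriented surface. For a mesh made of several disjoint closed solids the
#' volumes add.
#'
#' @param mesh a [tri_mesh()].
#' @return Volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  if (!nrow(f)) return(0)
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
      a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
      a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])) / 6
}

# Connected components of the face graph (faces sharing a vertex are
# connected). Returns an integer component id per face.
mesh_face_components <- function(mesh) {
  nv <- nrow(mesh$vertices)
  parent <- seq_len(nv)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (k in seq_len(nrow(mesh$faces))) {
    f <- mesh$faces[k, ]
    a <- find(f[1]); b <- find(f[2]); cc <- find(f[3])
    parent[a] <- b; parent[find(b)] <- find(cc)
  }
  vroot <- vapply(seq_len(nv), find, integer(1))
  froot <- vroot[mesh$faces[, 1]]
  match(froot, unique(froot))
}

#' Validate a triangle mesh for 3D-printability
#'
#' Checks the structural contract every exported retainer must satisfy:
#' every undirected edge shared by exactly two faces (watertight 2-manifold,
#' allowing several disjoint closed solids), consistent outward winding
#' (each shared edge traversed in opposite directions by its two faces),
#' positive signed volume, and no degenerate (near-zero-area) triangles.
#' Reports rather than raises.
#'
#' @param mesh a [tri_mesh()].
#' @param degenerate_area_mm2 area threshold below which a face counts as
#'   degenerate.
#' @return A list of class `mesh_validation` with flags `watertight`,
#'   `consistently_wound`, `positive_volume`, counts, the total
#'   `volume_mm3`, per-component volumes and an overall `ok`.
#' @export
validate_mesh <- function(mesh, degenerate_area_mm2 = 1e-9) {
  stopifnot(inherits(mesh, "tri_mesh"))
  f <- mesh$faces
  e_from <- c(f[, 1], f[, 2], f[, 3])
  e_to   <- c(f[, 2], f[, 3], f[, 1])
  lo <- pmin(e_from, e_to); hi <- pmax(e_from, e_to)
  key <- paste(lo, hi)
  cnt <- table(key)
  watertight <- all(cnt == 2L)
  # a shared edge must be traversed once as (a,b) and once as (b,a)
  dir_key <- paste(e_from, e_to)
  consistently_wound <- watertight && !anyDuplicated(dir_key)
  areas <- 0.5 * sqrt(rowSums(face_cross(mesh)^2))
  vol <- mesh_volume(mesh)
  comp <- mesh_face_components(mesh)
  comp_vol <- vapply(seq_len(max(comp, 0L)), function(ci)
    mesh_volume(tri_mesh(mesh$vertices, f[comp == ci, , drop = FALSE])),
    numeric(1))
  out <- list(
    watertight = watertight,
    consistently_wound = consistently_wound,
    positive_volume = vol > 0,
    degenerate_face_count = sum(areas <= degenerate_area_mm2),
    volume_mm3 = vol,
    component_volumes_mm3 = comp_vol,
    n_components = length(comp_vol)
  )
  out$ok <- out$watertight && out$consistently_wound && out$positive_volume &&
    out$degenerate_face_count == 0L
  structure(out, class = "mesh_validation")
}

#' @export
print.mesh_validation <- function(x, ...) {
  cat(sprintf(paste0(
    "<mesh_validation: %s>\n  watertight: %s  wound: %s  volume: %.3f mm^3",
    "  degenerate faces: %d  components: %d\n"),
    if (x$ok) "OK" else "FAILED", x$watertight, x$consistently_wound,
    x$volume_mm3, x$degenerate_face_count, x$n_components))
  invisible(x)
}

# Axis-aligned bounding box of a vertex subset: 2 x 3 matrix (min, max).
mesh_bbox <- function(mesh, vidx = seq_len(nrow(mesh$vertices))) {
  v <- mesh$vertices[vidx, , drop = FALSE]
  rbind(min = apply(v, 2, min), max = apply(v, 2, max))
}
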