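STL_HEADER_TAG <- "nariform binary STL; units = mm"

# float32 quantization of a numeric vector (round trip through 4-byte IEEE).
as_float32 <- function(x) readBin(writeBin(as.numeric(x), raw(), size = 4L,
                                           endian = "little"),
                                  numeric(), n = length(x), size = 4L,
                                  endian = "little")

stl_normals <- function(mesh) {
  cr <- face_cross(mesh)
  len <- sqrt(rowSums(cr^2))
  n <- cr / ifelse(len > 0, len, 1)
  n[len == 0, ] <- 0
  n
}

#' Write a mesh as an STL file
#'
#' Binary little-endian STL by default (80-byte constant header, so the
#' byte output for a fixed mesh is reproducible — no timestamps), or
#' ASCII for human inspection. Facet normals are computed from the vertex
#' winding by the right-hand rule. Coordinates are in mm; STL itself is
#' unitless, so the unit convention is recorded in a JSON sidecar when
#' `sidecar = TRUE`.
#'
#' @param mesh a [tri_mesh()]; must pass [validate_mesh()].
#' @param path output path.
#' @param format `"binary"` or `"ascii"`.
#' @param sidecar write `<path>.json` with unit and provenance metadata.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, format = c("binary", "ascii"), sidecar = FALSE) {
  format <- match.arg(format)
  stopifnot(inherits(mesh, "tri_mesh"))
  val <- validate_mesh(mesh)
  if (!val$ok)
    nf_stop("invalid_mesh", "refusing to export invalid mesh (watertight=%s, degenerate=%d)",
            val$watertight, val$degenerate_face_count)
  nf <- nrow(mesh$faces)
  normals <- stl_normals(mesh)
  v1 <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  v2 <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  v3 <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  if (format == "binary") {
    con <- file(path, "wb")
    on.exit(close(con))
    hdr <- charToRaw(STL_HEADER_TAG)
    writeBin(c(hdr, raw(80L - length(hdr))), con)
    writeBin(as.integer(nf), con, size = 4L, endian = "little")
    # 12 floats + 2-byte attribute count per triangle
    tri <- cbind(normals, v1, v2, v3)               # nf x 12
    for (i in seq_len(nf)) {
      writeBin(as.numeric(tri[i, ]), con, size = 4L, endian = "little")
      writeBin(as.raw(c(0L, 0L)), con)
    }
  } else {
    fmt <- function(x) sprintf("%.9e", x)
    lines <- character(7L * nf + 2L)
    lines[1] <- "solid nariform"
    for (i in seq_len(nf)) {
      j <- 2L + (i - 1L) * 7L
      lines[j - 0L] <- sprintf("  facet normal %s %s %s",
                               fmt(normals[i, 1]), fmt(normals[i, 2]), fmt(normals[i, 3]))
      lines[j + 1L] <- "    outer loop"
      lines[j + 2L] <- sprintf("      vertex %s %s %s", fmt(v1[i, 1]), fmt(v1[i, 2]), fmt(v1[i, 3]))
      lines[j + 3L] <- sprintf("      vertex %s %s %s", fmt(v2[i, 1]), fmt(v2[i, 2]), fmt(v2[i, 3]))
      lines[j + 4L] <- sprintf("      vertex %s %s %s", fmt(v3[i, 1]), fmt(v3[i, 2]), fmt(v3[i, 3]))
      lines[j + 5L] <- "    endloop"
      lines[j + 6L] <- "  endfacet"
    }
    lines[7L * nf + 2L] <- "endsolid nariform"
    writeLines(lines, path)
  }
  if (sidecar)
    jsonlite::write_json(
      list(units = "mm", format = format, triangle_count = nf,
           volume_mm3 = val$volume_mm3, generator = "nariform"),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

parse_ascii_stl <- function(lines) {
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vl) == 0L || length(vl) %% 3L != 0L)
    nf_stop("malformed_stl", "ASCII STL vertex count is %d (not a positive multiple of 3)",
            length(vl))
  num <- lapply(strsplit(trimws(vl), "\\s+"), function(p) suppressWarnings(as.numeric(p[2:4])))
  coords <- do.call(rbind, num)
  if (anyNA(coords)) nf_stop("malformed_stl", "unparseable vertex line in ASCII STL")
  coords
}

#' Read an STL file
#'
#' Auto-detects the dialect: a file whose first bytes spell `solid` and
#' whose body parses as ASCII facets is read as ASCII, anything else as
#' binary (where the byte size must equal `84 + 50 * n` exactly).
#' Vertices are deduplicated by exact float32 coordinate equality —
#' epsilon welding could silently fuse the thin walls this package
#' generates — and faces re-indexed with orientation preserved.
#'
#' @param path STL file path.
#' @return A [tri_mesh()].
#' @export
read_stl <- function(path) {
  if (!file.exists(path)) nf_stop("file_missing", "no such STL file: %s", path)
  sz <- file.size(path)
  if (sz < 15) nf_stop("malformed_stl", "file too small to be an STL (%d bytes)", sz)
  head_raw <- readBin(path, raw(), n = 5L)
  coords <- NULL
  if (identical(rawToChar(head_raw), "solid")) {
    coords <- tryCatch(parse_ascii_stl(readLines(path, warn = FALSE)),
                       nariform_error = function(e) NULL)
  }
  if (is.null(coords)) {
    if (sz < 84) nf_stop("malformed_stl", "binary STL shorter than its 84-byte preamble")
    con <- file(path, "rb")
    on.exit(close(con))
    invisible(readBin(con, raw(), n = 80L))
    nf <- readBin(con, integer(), n = 1L, size = 4L, endian = "little")
    if (nf < 0 || sz != 84 + 50 * nf)
      nf_stop("malformed_stl", "binary STL size %d != 84 + 50 * %d", sz, nf)
    body <- readBin(con, raw(), n = 50L * nf)
    m <- matrix(body, nrow = 50L)                       # one column per triangle
    floats <- readBin(as.vector(m[1:48, ]), numeric(), n = 12L * nf,
                      size = 4L, endian = "little")
    tri <- matrix(floats, ncol = 12L, byrow = TRUE)
    coords <- matrix(t(tri[, 4:12, drop = FALSE]), ncol = 3L, byrow = TRUE)
  }
  coords32 <- matrix(as_float32(coords), ncol = 3L)
  key <- paste(coords32[, 1], coords32[, 2], coords32[, 3], sep = "|")
  uk <- !duplicated(key)
  verts <- coords32[uk, , drop = FALSE]
  faces <- matrix(match(key, key[uk]), ncol = 3L, byrow = TRUE)
  tri_mesh(verts, faces)
}
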