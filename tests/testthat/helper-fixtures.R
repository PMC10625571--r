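# Shared in-code fixtures. Everything is generated at test time; nothing
# binary ships with the package.

# Unit right tetrahedron (legs on the axes), outward-oriented; volume 1/6.
unit_tetrahedron <- function() {
  tri_mesh(
    vertices = rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
    faces = rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4))
  )
}

# Flat-colour raster of the given size (w x h), colour as length-3 RGB.
flat_image <- function(w, h, col) {
  raster_image(array(rep(col, each = h * w), dim = c(h, w, 3)))
}

# Paint an axis-aligned rectangle of pixels (0-based indices, inclusive
# of x0/y0, exclusive of x0+side) onto an image; returns the new image.
paint_square <- function(img, x0, y0, side, col) {
  rgb <- img$rgb
  rows <- (y0 + 1):(y0 + side)
  cols <- (x0 + 1):(x0 + side)
  for (ch in 1:3) rgb[rows, cols, ch] <- col[ch]
  raster_image(rgb)
}

SKIN <- c(224, 172, 140)
GREEN <- c(0, 200, 0)

# Rigid in-plane motion of a pixel_segment: rotate by theta about (ox, oy)
# then translate by (tx, ty).
transform_segment <- function(seg, theta = 0, ox = 0, oy = 0, tx = 0, ty = 0) {
  rot <- function(p) {
    x <- p[["x"]] - ox; y <- p[["y"]] - oy
    c(ox + x * cos(theta) - y * sin(theta) + tx,
      oy + x * sin(theta) + y * cos(theta) + ty)
  }
  p1 <- rot(seg$p1); p2 <- rot(seg$p2)
  pixel_segment(p1[1], p1[2], p2[1], p2[2], seg$role)
}

measurement_values <- function(m) m$values_mm
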