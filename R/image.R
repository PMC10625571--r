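#' Raster image container
#'
#' An RGB raster with the conventions used throughout the package: the
#' origin is the top-left pixel, the column index grows rightward (x) and
#' the row index grows downward (y). Pixel indices are zero-based and the
#' centre of pixel `(c, r)` lies at `(c + 0.5, r + 0.5)` in continuous
#' pixel coordinates, so sub-pixel positions (centroids, annotation
#' endpoints) live on the same axes as the pixel grid.
#'
#' @param rgb numeric or integer array of dimension `height x width x 3`,
#'   8-bit samples in `[0, 255]`.
#' @return An object of class `raster_image` with fields `width_px`,
#'   `height_px` and `rgb` (integer array, `height x width x 3`).
#' @export
raster_image <- function(rgb) {
  if (!is.array(rgb) || length(dim(rgb)) != 3L || dim(rgb)[3] < 3L)
    nf_stop("decode_failure", "expected a height x width x 3 RGB array")
  rgb <- rgb[, , 1:3, drop = FALSE]
  storage.mode(rgb) <- "integer"
  if (anyNA(rgb) || min(rgb) < 0L || max(rgb) > 255L)
    nf_stop("decode_failure", "RGB samples must be integers in [0, 255]")
  if (dim(rgb)[1] < 1L || dim(rgb)[2] < 1L)
    nf_stop("decode_failure", "image has zero extent")
  structure(
    list(width_px = dim(rgb)[2], height_px = dim(rgb)[1], rgb = rgb),
    class = "raster_image"
  )
}

#' @export
print.raster_image <- function(x, ...) {
  cat(sprintf("<raster_image %d x %d px (w x h), RGB 8-bit>\n",
              x$width_px, x$height_px))
  invisible(x)
}

#' Load a photograph as a raster image
#'
#' Decodes a PNG or JPEG file (format chosen by file extension) into a
#' [raster_image()]. An alpha channel, if present, is dropped. Samples are
#' rescaled from the decoder's `[0, 1]` range to 8-bit integers.
#'
#' @param path path to a `.png`, `.jpg` or `.jpeg` file.
#' @return A [raster_image()].
#' @export
load_image <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    nf_stop("file_missing", "no such image file: %s", path)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png  = tryCatch(png::readPNG(path),
                    error = function(e) nf_stop("decode_failure",
                      "cannot decode PNG %s: %s", path, conditionMessage(e))),
    jpg  = ,
    jpeg = tryCatch(jpeg::readJPEG(path),
                    error = function(e) nf_stop("decode_failure",
                      "cannot decode JPEG %s: %s", path, conditionMessage(e))),
    nf_stop("unsupported_format", "unsupported image format '.%s' (PNG/JPEG only)", ext)
  )
  if (is.matrix(arr)) arr <- array(rep(arr, 3L), dim = c(dim(arr), 3L)) # greyscale
  raster_image(array(as.integer(round(arr[, , 1:3] * 255)), dim = c(dim(arr)[1:2], 3L)))
}
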