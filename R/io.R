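# Image containers and helpers.
#
# A topography image is a base array (H, W, 3) with values in [0, 1] and an
# attribute px_per_mm (default 50, i.e. 1 mm = 50 px in the topographer
# export). A region mask is an integer matrix (H, W) of 0/1 with a `role`
# attribute ("pupil" or "treatment_zone"). Coordinates follow the convention
# x = column, y = row, origin at the top-left pixel, 0-based.

#' Construct a topography image
#'
#' @param pixels numeric array (H, W, 3) in \[0, 1\].
#' @param px_per_mm physical scale of the export in pixels per millimetre.
#' @return a `topography_image` array.
#' @export
topography_image <- function(pixels, px_per_mm = 50) {
  stopifnot(is.numeric(pixels), length(dim(pixels)) == 3L, dim(pixels)[3] == 3L,
            dim(pixels)[1] >= 32L, dim(pixels)[2] >= 32L, px_per_mm > 0)
  structure(pixels, px_per_mm = px_per_mm, class = "topography_image")
}

#' Construct a region mask
#'
#' @param pixels matrix of 0/1 (anything non-zero is treated as foreground).
#' @param role which region the mask marks: `"pupil"` or `"treatment_zone"`.
#' @return a `region_mask` integer matrix.
#' @export
region_mask <- function(pixels, role = c("pupil", "treatment_zone")) {
  role <- match.arg(role)
  stopifnot(is.matrix(pixels))
  m <- matrix(as.integer(pixels != 0), nrow(pixels), ncol(pixels))
  structure(m, role = role, class = c("region_mask", class(m)))
}

as_binary_matrix <- function(mask) {
  stopifnot(is.matrix(mask))
  matrix(as.integer(unclass(mask) != 0), nrow(mask), ncol(mask))
}

#' Read / write topography images and masks as PNG
#'
#' Images are 8-bit RGB PNG; masks are single-channel PNG binarised at > 127.
#' (JPEG exports must be converted to PNG beforehand; only PNG I/O is built
#' in.)
#'
#' @param path file path.
#' @param px_per_mm scale recorded on the returned image.
#' @param role mask role, see [region_mask()].
#' @return `read_topography` returns a `topography_image`; `read_mask` a
#'   `region_mask`; the writers return `path` invisibly.
#' @export
read_topography <- function(path, px_per_mm = 50) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 2L) px <- array(rep(px, 3L), c(dim(px), 3L))
  if (dim(px)[3] > 3L) px <- px[, , 1:3, drop = FALSE]
  topography_image(px, px_per_mm)
}

#' @rdname read_topography
#' @param image a `topography_image` (or plain (H, W, 3) array in \[0, 1\]).
#' @export
write_topography <- function(image, path) {
  png::writePNG(pmin(pmax(unclass(image), 0), 1), path)
  invisible(path)
}

#' @rdname read_topography
#' @export
read_mask <- function(path, role = c("pupil", "treatment_zone")) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L) px <- px[, , 1]
  region_mask(px > 127 / 255, role = match.arg(role))
}

#' @rdname read_topography
#' @param mask a `region_mask` (or plain 0/1 matrix).
#' @export
write_mask <- function(mask, path) {
  png::writePNG(as_binary_matrix(mask) * 1.0, path)
  invisible(path)
}

# Bilinear resize for images ((H, W, C) or matrix), nearest for masks.
resize_bilinear <- function(x, h, w) {
  as.array(EBImage::resize(unclass(x), w = h, h = w, filter = "bilinear"))
}

resize_nearest <- function(x, h, w) {
  as.array(EBImage::resize(unclass(x), w = h, h = w, filter = "none"))
}

resize_mask <- function(mask, h, w, method = c("nearest", "bilinear")) {
  method <- match.arg(method)
  m <- if (method == "nearest") resize_nearest(as_binary_matrix(mask), h, w)
       else resize_bilinear(as_binary_matrix(mask) * 1.0, h, w) > 0.5
  matrix(as.integer(m != 0), h, w)
}
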