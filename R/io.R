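# Raster I/O: 8-bit RGB images and binary masks as PNG, plus contour
# overlays for visual inspection.

#' Read an 8-bit RGB image
#'
#' Reads a PNG (or, with the tiff package installed, a TIFF) file into a
#' `height x width x 3` array of 0--255 intensities. Grayscale files are
#' replicated to three channels; an alpha channel is dropped.
#'
#' @param path file path.
#' @return RGB image array.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("reading TIFF requires the 'tiff' package", call. = FALSE)
      tiff::readTIFF(path)
    },
    stop(sprintf("unsupported image format '%s'", ext), call. = FALSE))
  if (length(dim(raw)) == 2L) raw <- array(rep(raw, 3), c(dim(raw), 3))
  if (dim(raw)[3] > 3L) raw <- raw[, , 1:3, drop = FALSE]
  img <- floor(raw * 255 + 0.5)
  validate_rgb(img)
  img
}

#' Read a binary mask PNG
#'
#' Single-channel PNG with foreground stored as 255 (any value > 127 counts
#' as foreground).
#'
#' @param path file path.
#' @return Logical matrix.
#' @export
read_mask <- function(path) {
  raw <- png::readPNG(path)
  if (length(dim(raw)) == 3L) raw <- raw[, , 1]
  matrix(raw > 0.5, nrow(raw), ncol(raw))
}

#' Write a binary mask as PNG
#'
#' @param mask logical matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  validate_mask(mask)
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Write an RGB image as PNG
#'
#' @param image RGB image array (0--255).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  validate_rgb(image)
  png::writePNG(image / 255, path)
  invisible(path)
}

#' Write a segmentation overlay
#'
#' Draws the mask boundary on the image as a cyan contour (the usual visual
#' presentation of nucleus segmentations) and writes a PNG.
#'
#' @param image RGB image array.
#' @param mask logical matrix of the same spatial shape.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_overlay <- function(image, mask, path) {
  validate_rgb(image); validate_mask(mask)
  if (!identical(dim(image)[1:2], dim(mask)))
    stop("image/mask shape mismatch", call. = FALSE)
  border <- mask & !erode_once(mask)
  out <- image
  out[, , 1][border] <- 0
  out[, , 2][border] <- 255
  out[, , 3][border] <- 255
  write_image(out, path)
}

# one-pixel 4-neighbour erosion, used to trace mask boundaries
erode_once <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(FALSE, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- mask
  pad[2:(h + 1L), 2:(w + 1L)] &
    pad[1:h, 2:(w + 1L)] & pad[3:(h + 2L), 2:(w + 1L)] &
    pad[2:(h + 1L), 1:w] & pad[2:(h + 1L), 3:(w + 2L)]
}
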