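#' Read an image as a grayscale matrix on the 0-255 scale
#'
#' Reads an 8-bit grayscale or RGB PNG or TIFF and returns a matrix of gray
#' values in \code{[0, 255]} (rows = image rows, columns = image columns).
#' Color images are converted with the Rec. 601 luma weights
#' (0.299 R + 0.587 G + 0.114 B); supply pre-grayscaled images to bypass the
#' conversion. An alpha channel, if present, is ignored.
#'
#' @param path Path to a \code{.png}, \code{.tif} or \code{.tiff} file.
#' @return A numeric matrix of gray values in \code{[0, 255]}.
#' @export
read_image_gray <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                png = png::readPNG(path),
                tif = ,
                tiff = tiff::readTIFF(path),
                stop("unsupported image format: .", ext,
                     " (PNG and TIFF are supported)"))
  if (length(dim(img)) == 3L) {
    nc <- dim(img)[3L]
    if (nc >= 3L) {
      img <- 0.299 * img[, , 1L] + 0.587 * img[, , 2L] + 0.114 * img[, , 3L]
    } else {
      img <- img[, , 1L]  # gray + alpha
    }
  }
  img * 255
}

#' Extract a flank intensity profile from an image region
#'
#' Averages the pixels of each column inside a rectangular region of the
#' flank into one gray value per column, yielding the one-dimensional
#' anterior-to-posterior profile the bar-calling algorithm consumes. The
#' conventional region is 10 pixels high, spanning the flank between the
#' opercle and the dorsal fin, but any height of at least 1 is accepted.
#'
#' @param image A gray matrix from \code{\link{read_image_gray}} (values in
#'   \code{[0, 255]}), or a path to a PNG/TIFF file.
#' @param region Integer vector \code{c(row, col, height, width)}: the 1-based
#'   top-left pixel of the rectangle plus its size in pixels. Must lie fully
#'   inside the image.
#' @param scale_cm_per_px Centimeters per pixel.
#' @param flip If \code{TRUE}, reverse the profile left-to-right; use for
#'   images of right-facing fish so that stored profiles are always
#'   anterior to posterior.
#' @param ... Metadata passed to \code{\link{intensity_profile}} (\code{id},
#'   \code{group}, \code{sex}, \code{standard_length_cm}).
#' @return An \code{intensity_profile} with one value per region column.
#' @export
extract_profile <- function(image, region, scale_cm_per_px = 1,
                            flip = FALSE, ...) {
  if (is.character(image)) image <- read_image_gray(image)
  if (!is.matrix(image)) stop("image must be a matrix or a file path")
  region <- as.integer(region)
  if (length(region) != 4L)
    stop("region must be c(row, col, height, width)")
  r0 <- region[1L]; c0 <- region[2L]; h <- region[3L]; w <- region[4L]
  if (h < 1L) stop("region height must be at least 1 pixel")
  if (w < 1L) stop("region width must be at least 1 pixel")
  if (r0 < 1L || c0 < 1L || r0 + h - 1L > nrow(image) ||
      c0 + w - 1L > ncol(image))
    stop("region extends outside the image bounds")
  block <- image[r0:(r0 + h - 1L), c0:(c0 + w - 1L), drop = FALSE]
  vals <- colMeans(block)
  if (flip) vals <- rev(vals)
  intensity_profile(vals, scale_cm_per_px = scale_cm_per_px, ...)
}

#' Standard length from snout and caudal-peduncle landmarks
#'
#' Euclidean pixel distance between the two landmarks, converted to
#' centimeters via the image scale. Symmetric in its landmark arguments.
#'
#' @param snout_xy,caudal_peduncle_xy Numeric length-2 pixel coordinates.
#' @param scale_cm_per_px Centimeters per pixel.
#' @return Standard length in centimeters.
#' @export
standard_length_from_landmarks <- function(snout_xy, caudal_peduncle_xy,
                                           scale_cm_per_px) {
  stopifnot(length(snout_xy) == 2L, length(caudal_peduncle_xy) == 2L,
            scale_cm_per_px > 0)
  d <- sqrt(sum((as.numeric(snout_xy) - as.numeric(caudal_peduncle_xy))^2))
  if (d == 0) stop("landmarks coincide; cannot measure standard length")
  d * scale_cm_per_px
}
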