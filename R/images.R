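#' RGB image containers and I/O
#'
#' Images are plain numeric arrays of dimension `(H, W, 3)` holding 8-bit
#' intensities in `[0, 255]`, with the origin at the top-left corner, x
#' increasing rightwards (columns) and y downwards (rows). [EBImage] backs
#' all file I/O and resampling; these helpers convert between the two
#' conventions (EBImage stores images x-major and scaled to `[0, 1]`).
#'
#' @param x numeric array `(H, W, 3)`.
#' @return `as_rgb_image()` returns the validated array with class
#'   `rgb_image`.
#' @name rgb_image
NULL

#' @rdname rgb_image
#' @export
as_rgb_image <- function(x) {
  if (!is.array(x) || length(dim(x)) != 3L || dim(x)[3] != 3L)
    stop("an RGB image must be an (H, W, 3) array")
  if (anyNA(x) || min(x) < 0 || max(x) > 255)
    stop("RGB intensities must lie in [0, 255]")
  structure(x, class = "rgb_image")
}

#' @rdname rgb_image
#' @export
is_rgb_image <- function(x) {
  is.array(x) && length(dim(x)) == 3L && dim(x)[3] == 3L
}

# (H, W, 3) 0..255 -> EBImage Color Image, and back
to_ebimage <- function(img) {
  EBImage::Image(aperm(unclass(img), c(2, 1, 3)) / 255, colormode = "Color")
}

from_ebimage <- function(ebi) {
  d <- EBImage::imageData(ebi)
  if (length(dim(d)) == 2L) d <- array(d, c(dim(d), 3L))
  img <- aperm(d, c(2, 1, 3)) * 255
  img[img < 0] <- 0; img[img > 255] <- 255
  as_rgb_image(img)
}

#' Read and write plate photographs
#'
#' Thin wrappers over [EBImage::readImage()] / [EBImage::writeImage()] that
#' translate to the package's `(H, W, 3)` 8-bit array convention. JPEG and
#' PNG are supported; greyscale files are promoted to three channels.
#'
#' @param path file path.
#' @param img an `rgb_image` (or plain `(H, W, 3)` array in `[0, 255]`).
#' @param quality JPEG quality (ignored for PNG).
#' @return `read_rgb()` returns an `rgb_image`; `write_rgb()` returns `path`
#'   invisibly.
#' @export
read_rgb <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  ebi <- EBImage::readImage(path)
  d <- EBImage::imageData(ebi)
  if (length(dim(d)) == 2L) {
    d <- array(rep(d, 3L), c(dim(d), 3L))
  } else if (dim(d)[3] > 3L) {
    d <- d[, , 1:3, drop = FALSE]  # drop alpha
  }
  img <- aperm(d, c(2, 1, 3)) * 255
  as_rgb_image(round(img))
}

#' @rdname read_rgb
#' @export
write_rgb <- function(img, path, quality = 95L) {
  img <- as_rgb_image(unclass(img))
  EBImage::writeImage(to_ebimage(img), path, quality = quality)
  invisible(path)
}

#' Resize an image with bilinear interpolation
#'
#' @param img `rgb_image`.
#' @param h,w target height and width in pixels.
#' @return `rgb_image` of dimension `(h, w, 3)`.
#' @export
resize_rgb <- function(img, h, w) {
  stopifnot(h > 0, w > 0)
  ebi <- EBImage::resize(to_ebimage(img), w = w, h = h)
  from_ebimage(ebi)
}
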