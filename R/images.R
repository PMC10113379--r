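#' Construct a grayscale image
#'
#' Images are numeric matrices of intensities in \[0, 255\], row-major with
#' the origin at the top-left: x (columns) increases rightward along the
#' epipolar direction after calibration, y (rows) increases downward.
#'
#' @param pixels numeric matrix of intensities.
#' @return an object of class `gray_image` (a numeric matrix).
#' @export
gray_image <- function(pixels) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("'pixels' must be a numeric matrix", call. = FALSE)
  }
  structure(pixels, class = c("gray_image", class(pixels)))
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image %d x %d px, range [%.1f, %.1f]>\n",
              ncol(x), nrow(x), min(x, na.rm = TRUE), max(x, na.rm = TRUE)))
  invisible(x)
}

as_intensity_matrix <- function(img) {
  if (inherits(img, "gray_image")) return(unclass_matrix(img))
  if (is.matrix(img) && is.numeric(img)) return(img)
  stop("expected a gray_image or numeric matrix", call. = FALSE)
}

unclass_matrix <- function(x) {
  attr(x, "class") <- NULL
  x
}

#' Read a raster image as grayscale
#'
#' Reads a PNG (or TIFF, when the `tiff` package is available) raster file
#' and converts it to a `gray_image` with intensities in \[0, 255\]. Colour
#' images are converted to luma using Rec. 601 weights
#' (0.299 R + 0.587 G + 0.114 B).
#'
#' @param path path to the image file.
#' @return a [gray_image].
#' @export
read_gray_image <- function(path) {
  if (!file.exists(path)) stop("image not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        stop("reading TIFF requires the 'tiff' package", call. = FALSE)
      }
      tiff::readTIFF(path)
    },
    stop("unsupported image format: .", ext, call. = FALSE)
  )
  if (length(dim(arr)) == 3L) {
    if (dim(arr)[3] >= 3L) {
      arr <- 0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
    } else {
      arr <- arr[, , 1]
    }
  }
  gray_image(arr * 255)
}

#' Write a grayscale image
#'
#' Writes a `gray_image` (intensities 0-255) as an 8-bit grayscale PNG.
#'
#' @param img a [gray_image] or numeric matrix.
#' @param path output path (`.png`).
#' @return the path, invisibly.
#' @export
write_gray_image <- function(img, path) {
  m <- unclass(as_intensity_matrix(img))
  m[!is.finite(m)] <- 0
  m <- pmax(pmin(m / 255, 1), 0)
  png::writePNG(m, path)
  invisible(path)
}
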