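#' Read an RGB image
#'
#' Reads a PNG (or JPEG) file into the array convention used throughout the
#' package: a height x width x 3 numeric array with intensities in 0..255.
#'
#' @param path file path.
#' @return numeric array `c(height, width, 3)`, values in `[0, 255]`.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("jpg", "jpeg")) {
    stop("JPEG input requires the 'jpeg' package; convert to PNG")
  } else {
    png::readPNG(path)
  }
  if (length(dim(img)) == 2L) img <- array(img, c(dim(img), 1L))
  if (dim(img)[3] == 1L) img <- array(rep(img, 3L), c(dim(img)[1:2], 3L))
  if (dim(img)[3] == 4L) img <- img[, , 1:3, drop = FALSE]
  img * 255
}

#' Write an RGB image as PNG
#'
#' @param image height x width x 3 array in 0..255 (clipped on write).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  stopifnot(length(dim(image)) == 3L, dim(image)[3] == 3L)
  png::writePNG(clamp(image, 0, 255) / 255, path)
  invisible(path)
}

#' Convert an RGB array to grayscale
#'
#' Rec. 601 luma weighting. Accepts a matrix (returned unchanged).
#'
#' @param image RGB array in 0..255, or a matrix.
#' @return numeric matrix in 0..255.
#' @export
rgb_to_gray <- function(image) {
  if (is.matrix(image)) return(image)
  stopifnot(length(dim(image)) == 3L, dim(image)[3] == 3L)
  0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# round half-to-even and clip to the 8-bit range
quantize8 <- function(x) clamp(round(x), 0, 255)

# Shannon entropy (base 2) of the 256-bin grayscale intensity histogram
#' Histogram entropy of a grayscale image
#'
#' Shannon entropy (bits) of the 256-bin intensity histogram; used to verify
#' that contrast enhancement spreads the intensity distribution.
#'
#' @param gray matrix (or RGB array, converted by luma) in 0..255.
#' @return entropy in bits, in `[0, 8]`.
#' @export
hist_entropy <- function(gray) {
  gray <- rgb_to_gray(gray)
  b <- tabulate(quantize8(gray) + 1L, nbins = 256L)
  p <- b[b > 0] / sum(b)
  -sum(p * log2(p))
}
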