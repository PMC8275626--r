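#' Read a fundus image
#'
#' Reads a PNG/JPEG image into a numeric `H x W x 3` array with intensities
#' in `[0, 1]`. Grayscale images are replicated to three channels and an
#' alpha channel, if present, is dropped. Throughout the package the first
#' array index is the row and the second the column of the image.
#'
#' @param path Path to a PNG or JPEG file.
#' @return A numeric array of dimension `H x W x 3`.
#' @export
read_fundus <- function(path) {
  img <- EBImage::readImage(path)
  arr <- unclass(EBImage::imageData(img))
  if (length(dim(arr)) == 2L) arr <- array(arr, c(dim(arr), 3L))
  if (dim(arr)[3] == 4L) arr <- arr[, , 1:3, drop = FALSE]
  if (dim(arr)[3] == 1L) arr <- array(arr[, , 1], c(dim(arr)[1:2], 3L))
  storage.mode(arr) <- "double"
  arr
}

#' Write an image or mask to PNG
#'
#' Images are written as 8-bit PNG; binary masks become single-channel 0/255
#' PNG files.
#'
#' @param x Numeric array in `[0, 1]` (image) or 0/1 matrix (mask).
#' @param path Output file path (extension selects the format).
#' @return `path`, invisibly.
#' @export
write_image <- function(x, path) {
  x <- pmin(pmax(unclass(x), 0), 1)
  if (length(dim(x)) == 3L) {
    x <- EBImage::Image(x, colormode = "Color")  # one RGB image, not frames
  }
  EBImage::writeImage(x, path)
  invisible(path)
}

# Compact 8-bit storage for large in-memory datasets.
pack_array <- function(x) {
  r <- as.raw(pmin(pmax(round(x * 255), 0), 255))
  attr(r, "dim") <- dim(x)
  r
}

unpack_array <- function(r) {
  unpack_raw_cpp(r)
}
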