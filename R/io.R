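#' Read / write grayscale images
#'
#' PNG and TIFF, 8- or 16-bit. Images are returned as plain numeric
#' matrices on the 0-255 scale (16-bit files are rescaled); multi-channel
#' inputs are collapsed to their channel mean.
#'
#' @param path image path; format chosen by extension.
#' @return `read_gray_image()` returns a numeric matrix.
#' @export
read_gray_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext, " (use PNG or TIFF)")
  )
  if (length(dim(img)) == 3L) {
    img <- apply(img, c(1L, 2L), mean)
  }
  img * 255
}

#' @rdname read_gray_image
#' @param image numeric matrix on the 0-255 scale.
#' @export
write_gray_image <- function(image, path) {
  ext <- tolower(tools::file_ext(path))
  scaled <- pmin(pmax(image / 255, 0), 1)
  switch(ext,
    png = png::writePNG(scaled, path),
    tif = ,
    tiff = tiff::writeTIFF(scaled, path),
    stop("unsupported image format: .", ext, " (use PNG or TIFF)")
  )
  invisible(path)
}

#' Read / write binary masks as PNG
#'
#' @param path PNG path.
#' @return `read_mask_png()` returns an integer 0/1 matrix (any nonzero
#'   pixel counts as set).
#' @export
read_mask_png <- function(path) {
  m <- read_gray_image(path)
  matrix(as.integer(m > 127), nrow(m), ncol(m))
}

#' @rdname read_mask_png
#' @param mask integer/logical matrix.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask != 0), nrow(mask), ncol(mask)), path)
  invisible(path)
}
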