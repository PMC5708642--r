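#' Read an 8-bit RGB image
#'
#' Reads a TIFF or PNG file and returns a height x width x 3 numeric array on
#' the 0--255 scale (transmitted light, white background bright).
#'
#' @param path Path to a `.tif`/`.tiff` or `.png` file.
#' @return Numeric array `h x w x 3` with values in \[0, 255\].
#' @export
read_image_rgb <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = ,
    tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop("unsupported image format: .", ext, " (use TIFF or PNG)")
  )
  if (length(dim(img)) == 2L) stop("expected an RGB image, got a single channel")
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE] # drop alpha
  if (dim(img)[3] != 3L) stop("expected an RGB image with 3 channels")
  img * 255
}

#' Write an 8-bit RGB image
#'
#' @param img Numeric array `h x w x 3`, values in \[0, 255\].
#' @param path Output path; format chosen by extension (`.tif`/`.tiff`/`.png`).
#' @return `path`, invisibly.
#' @export
write_image_rgb <- function(img, path) {
  stopifnot(length(dim(img)) == 3L, dim(img)[3] == 3L)
  x <- pmin(pmax(img, 0), 255) / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = ,
    tiff = tiff::writeTIFF(x, path, bits.per.sample = 8L),
    png = png::writePNG(x, path),
    stop("unsupported image format: .", ext)
  )
  invisible(path)
}

#' Write an integer label image as 16-bit greyscale TIFF
#'
#' @param labels Integer matrix (0 = background).
#' @param path Output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_label_tiff <- function(labels, path) {
  stopifnot(is.matrix(labels), max(labels) < 65536)
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a gold-standard class image
#'
#' Reads an indexed greyscale PNG/TIFF whose pixel values encode the three
#' tissue classes: 0 background, 1 epithelium, 2 stroma.
#'
#' @param path Path to the annotation image.
#' @return Integer matrix of class codes.
#' @export
read_gold_standard <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = ,
    tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop("unsupported image format: .", ext)
  )
  if (length(dim(img)) == 3L) img <- img[, , 1]
  g <- round(img * 255)
  if (!all(g %in% 0:2)) stop("gold-standard pixel values must be 0, 1 or 2")
  storage.mode(g) <- "integer"
  g
}

#' Write a gold-standard class image
#'
#' @param gold Integer matrix with values 0 (background), 1 (epithelium),
#'   2 (stroma).
#' @param path Output `.png` path.
#' @return `path`, invisibly.
#' @export
write_gold_standard <- function(gold, path) {
  stopifnot(all(gold %in% 0:2))
  png::writePNG(gold / 255, path)
  invisible(path)
}
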