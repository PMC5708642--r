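#' Default haematoxylin/eosin stain vectors
#'
#' Returns the standard published H&E absorbance directions in RGB space
#' (Ruifrok-Johnston values), each normalised to unit length, plus a residual
#' direction given by the normalised cross product of the haematoxylin and
#' eosin vectors. Rows are stains (`haem`, `eosin`, `resid`), columns are the
#' R, G, B absorbance components.
#'
#' @return A 3 x 3 numeric matrix of unit-norm stain vectors.
#' @export
default_he_vectors <- function() {
  h <- c(0.650, 0.704, 0.286)
  e <- c(0.072, 0.990, 0.105)
  h <- h / sqrt(sum(h^2))
  e <- e / sqrt(sum(e^2))
  r <- c(
    h[2] * e[3] - h[3] * e[2],
    h[3] * e[1] - h[1] * e[3],
    h[1] * e[2] - h[2] * e[1]
  )
  r <- r / sqrt(sum(r^2))
  m <- rbind(haem = h, eosin = e, resid = r)
  colnames(m) <- c("R", "G", "B")
  m
}

check_stain_vectors <- function(vectors) {
  if (!is.matrix(vectors) || any(dim(vectors) != 3L))
    stop("stain vectors must be a 3 x 3 matrix (rows = stains)")
  if (abs(det(vectors)) < 1e-8)
    stop("stain vector matrix is singular; the three directions must be independent")
  vectors / sqrt(rowSums(vectors^2))
}

#' Colour deconvolution of an H&E image
#'
#' Separates an 8-bit RGB transmitted-light image into haematoxylin, eosin and
#' residual stain channels under the Beer-Lambert model. Each pixel's RGB
#' transmittance is converted to optical density
#' `OD = -log(max(v, eps) / 255)`, the 3 x 3 linear system of stain
#' absorbances is solved for per-stain densities (negative densities clipped
#' to 0), and each density is mapped back to a transmittance `255 * exp(-d)`.
#'
#' @param image Numeric array `h x w x 3`, values in \[0, 255\].
#' @param vectors Stain absorbance matrix as from [default_he_vectors()];
#'   rows are stains, columns RGB. Rows are re-normalised to unit length.
#' @param eps Transmittance floor (grey levels) so saturated (0) pixels keep a
#'   bounded optical density. Default 1.
#' @param quantise Round the output channels to 8-bit integers (default TRUE,
#'   matching an 8-bit stain image; set FALSE to keep double precision).
#' @return The stain image: array `h x w x 3` with per-stain transmittance in
#'   \[0, 255\], channels named `haem`, `eosin`, `resid`.
#' @export
deconvolve <- function(image, vectors = default_he_vectors(), eps = 1,
                       quantise = TRUE) {
  if (length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop("expected an RGB image array (h x w x 3)")
  vectors <- check_stain_vectors(vectors)
  d <- stain_densities(image, vectors, eps = eps)
  tr <- 255 * exp(-d)
  if (quantise) tr <- round(tr)
  dimnames(tr) <- list(NULL, NULL, rownames(vectors))
  tr
}

#' Per-pixel stain densities of an RGB image
#'
#' The optical-density half of [deconvolve()]: returns the per-stain densities
#' instead of transmittances. Used by the forward/inverse round-trip checks.
#'
#' @inheritParams deconvolve
#' @return Array `h x w x 3` of non-negative stain densities.
#' @export
stain_densities <- function(image, vectors = default_he_vectors(), eps = 1) {
  vectors <- check_stain_vectors(vectors)
  dm <- dim(image)
  v <- pmin(pmax(image, eps), 255)
  od <- -log(v / 255)
  odm <- matrix(od, ncol = 3L) # pixels x RGB
  dens <- odm %*% solve(vectors) # solve t(vectors) %*% d = od per pixel
  dens[dens < 0] <- 0
  array(dens, dm, dimnames = list(NULL, NULL, rownames(vectors)))
}

#' Compose an RGB image from per-stain densities
#'
#' Forward Beer-Lambert model: given per-pixel densities of each stain and the
#' stain absorbance directions, produces the 8-bit RGB transmittance image.
#' The inverse of [deconvolve()] (up to quantisation); used by the synthetic
#' image generator and the round-trip tests.
#'
#' @param densities Numeric array `h x w x 3` of non-negative stain densities
#'   (haematoxylin, eosin, residual).
#' @param vectors Stain absorbance matrix, rows = stains.
#' @param quantise Round to 8-bit integers (default TRUE).
#' @return RGB array `h x w x 3` in \[0, 255\].
#' @export
compose_stains <- function(densities, vectors = default_he_vectors(),
                           quantise = TRUE) {
  stopifnot(length(dim(densities)) == 3L, dim(densities)[3] == 3L)
  vectors <- check_stain_vectors(vectors)
  dm <- dim(densities)
  od <- matrix(densities, ncol = 3L) %*% vectors
  rgb <- 255 * exp(-od)
  if (quantise) rgb <- pmin(pmax(round(rgb), 0), 255)
  array(rgb, dm)
}

stain_channel <- function(stain, channel = c("haem", "eosin", "resid")) {
  channel <- match.arg(channel)
  stain[, , channel]
}
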