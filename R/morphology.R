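## Binary and greyscale morphology on plain matrices. Heavy primitives
## (reconstruction, labelling, priority-flood watershed) live in src/.

shift_matrix <- function(m, dr, dc, fill) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

#' Binary erosion / dilation with a 3 x 3 square structuring element
#'
#' Pixels outside the frame are treated as background.
#'
#' @param mask Logical matrix.
#' @param times Number of successive erosions/dilations.
#' @return Logical matrix.
#' @export
erode3 <- function(mask, times = 1L) {
  stopifnot(is.matrix(mask), times >= 0L)
  out <- mask
  for (i in seq_len(times)) {
    acc <- out
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0L && dc == 0L) next
      acc <- acc & shift_matrix(out, dr, dc, FALSE)
    }
    out <- acc
  }
  out
}

#' @rdname erode3
#' @export
dilate3 <- function(mask, times = 1L) {
  stopifnot(is.matrix(mask), times >= 0L)
  out <- mask
  for (i in seq_len(times)) {
    acc <- out
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0L && dc == 0L) next
      acc <- acc | shift_matrix(out, dr, dc, FALSE)
    }
    out <- acc
  }
  out
}

#' Greyscale morphological reconstruction by dilation
#'
#' Iteratively dilates `marker` while staying below `mask`, to stability.
#'
#' @param marker,mask Numeric matrices of equal size with `marker <= mask`
#'   everywhere.
#' @param conn Pixel connectivity, 4 or 8 (default 8).
#' @return Numeric matrix: the reconstruction of `marker` under `mask`.
#' @export
reconstruct_dilate <- function(marker, mask, conn = 8L) {
  stopifnot(is.matrix(marker), is.matrix(mask), all(dim(marker) == dim(mask)))
  if (any(marker > mask + 1e-9)) stop("marker must lie below mask everywhere")
  if (!conn %in% c(4L, 8L)) stop("conn must be 4 or 8")
  cpp_reconstruct_dilate(marker, mask, as.integer(conn))
}

#' Binary opening by reconstruction
#'
#' Erodes a binary image `e` times with a 3 x 3 square element, then
#' reconstructs under the original image. Connected components that vanish
#' under the erosions are removed; every surviving component keeps its exact
#' original shape.
#'
#' @param mask Logical matrix.
#' @param e Number of erosions (>= 0; 0 is a no-op).
#' @param conn Connectivity for the reconstruction (default 8).
#' @return Logical matrix.
#' @export
opening_by_reconstruction <- function(mask, e, conn = 8L) {
  stopifnot(is.matrix(mask), e >= 0L)
  if (e == 0L) return(mask)
  seed <- erode3(mask, e)
  rec <- reconstruct_dilate(seed * 1, mask * 1, conn)
  rec > 0.5
}

#' h-minima transform
#'
#' Fills every intensity basin of depth less than `h` and truncates deeper
#' basins by `h`, via reconstruction-by-erosion of `grey + h` over `grey`
#' (computed through the dilation dual). The image border is treated as an
#' outlet (drainage convention): water escaping past the frame is lost, so a
#' flat image has no basins and a lone basin fills only to its pour level.
#' Realistic images, whose frame-touching background is their brightest
#' region, are unaffected by the convention.
#'
#' @param grey Numeric matrix (greyscale image).
#' @param h Basin depth in grey levels, in \[1, 255\].
#' @param conn Connectivity (default 8).
#' @return Numeric matrix.
#' @export
hmin <- function(grey, h, conn = 8L) {
  stopifnot(is.matrix(grey))
  if (!is.numeric(h) || length(h) != 1L || h < 1 || h > 255)
    stop("h must be a single depth in [1, 255]")
  # border outlet: pad the dual marker/mask with a flood source ring
  nr <- nrow(grey) + 2L
  nc <- ncol(grey) + 2L
  hi <- max(-grey) + 1
  marker <- matrix(hi, nr, nc)
  mask <- matrix(hi, nr, nc)
  marker[2:(nr - 1L), 2:(nc - 1L)] <- -(grey + h)
  mask[2:(nr - 1L), 2:(nc - 1L)] <- -grey
  rec <- cpp_reconstruct_dilate(marker, mask, as.integer(conn))
  -rec[2:(nr - 1L), 2:(nc - 1L)]
}

#' h-concave transform
#'
#' `hmin(grey, h) - grey`: non-negative everywhere, positive exactly inside
#' intensity basins, with value `min(depth, h)` at the bottom of a basin.
#' This is the dark-basin detector used to find nuclear seeds in the
#' haematoxylin channel.
#'
#' @inheritParams hmin
#' @return Non-negative numeric matrix.
#' @export
hconcave <- function(grey, h, conn = 8L) {
  hmin(grey, h, conn) - grey
}

#' Huang's fuzzy-entropy global threshold
#'
#' Minimises the measure of fuzziness of the thresholded image over all
#' candidate thresholds of the 256-bin histogram (Huang & Wang). Ties are
#' broken toward the lower threshold.
#'
#' @param x Numeric matrix or vector with values in \[0, 255\] (rounded to
#'   integer bins internally).
#' @return The threshold `t` (integer grey level); foreground is conventionally
#'   the set of pixels with value `<= t`.
#' @export
huang_threshold <- function(x) {
  g <- as.integer(round(x))
  if (any(g < 0L | g > 255L)) stop("values must lie in [0, 255]")
  counts <- tabulate(g + 1L, nbins = 256L)
  nz <- which(counts > 0L)
  first <- nz[1] - 1L
  last <- nz[length(nz)] - 1L
  if (first == last)
    stop("degenerate histogram: image has no contrast, cannot threshold")

  lev <- 0:255
  w <- cumsum(counts * lev) # weighted cumulative sums
  s <- cumsum(counts)
  total_w <- w[256]
  total_s <- s[256]
  cc <- last - first # normaliser of the membership function

  best_t <- NA_integer_
  best_ent <- Inf
  for (t in first:(last - 1L)) {
    i <- t + 1L
    mu0 <- w[i] / s[i]
    mu1 <- (total_w - w[i]) / (total_s - s[i])
    mu <- ifelse(lev <= t, 1 / (1 + abs(lev - mu0) / cc),
                 1 / (1 + abs(lev - mu1) / cc))
    # Shannon entropy of the membership grades, weighted by the histogram
    hmu <- -mu * log(mu) - (1 - mu) * log(pmax(1 - mu, .Machine$double.eps))
    hmu[mu >= 1 - 1e-12] <- 0
    ent <- sum(counts * hmu)
    if (ent < best_ent - 1e-12) {
      best_ent <- ent
      best_t <- t
    }
  }
  best_t
}

#' Tissue foreground mask from a stain image
#'
#' Thresholds the per-pixel minimum of the haematoxylin and eosin
#' transmittance channels with Huang's fuzzy threshold; stained tissue
#' transmits less light, so foreground is the set of pixels at or below the
#' threshold. The residual channel is not used.
#'
#' @param stain Stain image from [deconvolve()].
#' @return Logical matrix (TRUE = stained tissue).
#' @export
tissue_mask <- function(stain) {
  stopifnot(length(dim(stain)) == 3L)
  m <- pmin(stain_channel(stain, "haem"), stain_channel(stain, "eosin"))
  t <- huang_threshold(m)
  mask <- m <= t
  if (!any(mask)) stop("degenerate threshold: no foreground tissue found")
  mask
}

#' Crop an image to its stained-tissue bounding box
#'
#' Thresholds a grey version of the image (Huang), keeps only large stained
#' portions via opening by reconstruction, and crops to the bounding box of
#' the remaining foreground. Large empty background borders around a tissue
#' core are removed before any further processing.
#'
#' @param image RGB array `h x w x 3` in \[0, 255\].
#' @param e Erosions used by the opening (size filter for "large portions").
#' @param gold Optional gold-standard class matrix cropped with the same
#'   frame.
#' @return The cropped image, with attribute `offset = c(row0, col0)` (0-based
#'   offsets of the crop) and, when `gold` is given, attribute `gold` holding
#'   the identically cropped annotation.
#' @export
crop_to_tissue <- function(image, e = 5L, gold = NULL) {
  stopifnot(length(dim(image)) == 3L)
  grey <- (image[, , 1] + image[, , 2] + image[, , 3]) / 3
  t <- tryCatch(huang_threshold(grey),
    error = function(err) stop("no tissue found: ", conditionMessage(err))
  )
  fg <- grey <= t
  fg <- opening_by_reconstruction(fg, e)
  if (!any(fg)) stop("no tissue found: foreground empty after opening")
  rows <- range(which(rowSums(fg) > 0))
  cols <- range(which(colSums(fg) > 0))
  out <- image[rows[1]:rows[2], cols[1]:cols[2], , drop = FALSE]
  attr(out, "offset") <- c(rows[1] - 1L, cols[1] - 1L)
  if (!is.null(gold)) {
    stopifnot(all(dim(gold) == dim(image)[1:2]))
    attr(out, "gold") <- gold[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE]
  }
  out
}

#' Nuclear seed extraction
#'
#' Finds dark basins of depth at least 1 (truncated at `h`) in the
#' haematoxylin transmittance channel with the h-concave transform, keeps
#' those inside the tissue mask, and removes small noise components with a
#' binary opening by reconstruction (`e` erosions): components that vanish
#' under the erosions are deleted, survivors keep their exact shape.
#'
#' @param haem Haematoxylin channel matrix (transmittance, 0--255).
#' @param mask Tissue mask from [tissue_mask()].
#' @param h Basin depth parameter (default 30).
#' @param e Number of erosions in the size filter (default 3; 0 disables it).
#' @param conn Connectivity (default 8).
#' @return Logical seed image; connected components are the nuclear markers.
#' @export
nuclear_seeds <- function(haem, mask, h = 30, e = 3L, conn = 8L) {
  stopifnot(is.matrix(haem), is.matrix(mask), all(dim(haem) == dim(mask)))
  if (e < 0L) stop("e must be >= 0")
  seeds <- (hconcave(haem, h, conn) > 0) & mask
  opening_by_reconstruction(seeds, e, conn)
}

#' Partition the tissue mask into virtual cells
#'
#' Marker-controlled watershed: each connected seed component is imposed as a
#' minimum and mask pixels are flooded into exclusive zones of influence, one
#' virtual cell per seed. In `"intensity"` mode (default) the flooding
#' landscape is the haematoxylin transmittance channel (dark nuclei are
#' basins); in `"distance"` mode flooding is over a flat landscape, giving
#' geodesic influence zones. No watershed-line pixels are produced: the
#' non-zero labels exactly tile the mask.
#'
#' @param mask Logical tissue mask.
#' @param seeds Logical seed image from [nuclear_seeds()].
#' @param haem Haematoxylin channel (required for `"intensity"` mode).
#' @param mode Flooding landscape, `"intensity"` or `"distance"`.
#' @param conn Connectivity (default 8).
#' @return A `vcell_map`: list with integer matrices `labels` (v-cell ids,
#'   0 = background) and `nuclei` (seed components carrying the id of their
#'   enclosing v-cell), and `n`, the number of v-cells.
#' @export
partition_vcells <- function(mask, seeds, haem = NULL,
                             mode = c("intensity", "distance"), conn = 8L) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(mask), is.matrix(seeds), all(dim(mask) == dim(seeds)))
  seed_lab <- cpp_label_components(seeds & mask, as.integer(conn))
  n <- max(seed_lab)
  if (n == 0L) stop("empty partition: no seeds inside the tissue mask")
  landscape <- if (mode == "intensity") {
    if (is.null(haem)) stop("intensity mode requires the haematoxylin channel")
    stopifnot(all(dim(haem) == dim(mask)))
    haem
  } else {
    matrix(0, nrow(mask), ncol(mask))
  }
  labels <- cpp_marker_watershed(landscape, seed_lab, mask, as.integer(conn))
  new_vcell_map(labels, seed_lab, n)
}

new_vcell_map <- function(labels, nuclei, n) {
  structure(list(labels = labels, nuclei = nuclei, n = as.integer(n)),
            class = "vcell_map")
}

#' @export
print.vcell_map <- function(x, ...) {
  cat("<vcell_map> ", nrow(x$labels), "x", ncol(x$labels), " pixels, ",
      x$n, " virtual cells\n", sep = "")
  invisible(x)
}

#' Pixel areas of the virtual cells
#'
#' @param vcells A `vcell_map`.
#' @return Integer vector of length `vcells$n`: pixels per v-cell id.
#' @export
vcell_areas <- function(vcells) {
  stopifnot(inherits(vcells, "vcell_map"))
  tabulate(vcells$labels[vcells$labels > 0L], nbins = vcells$n)
}
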