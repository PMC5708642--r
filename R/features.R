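## Colour and shape descriptors of virtual cells and their nuclei.
## Geometry works on pixel centres: the perimeter is the length of the
## boundary polygon traced through centres (diagonal steps weighted sqrt(2)),
## the convex hull is taken over centres, and the hull area is the count of
## pixel centres inside/on the hull polygon so that solidity is exactly 1 for
## convex digital regions.

#' Feature column names
#'
#' The 63 descriptor columns of a feature table: 11 colour statistics for each
#' of the three stain channels, 22 v-cell shape descriptors and 8 nucleus
#' shape descriptors.
#'
#' @return Character vector of length 63.
#' @export
feature_column_names <- function() {
  stats <- c("mode", "median", "mean", "avgdev", "sd", "min", "max",
             "var", "skew", "kurt", "entropy")
  colour <- as.vector(t(outer(c("haem", "eosin", "resid"), stats, paste, sep = "_")))
  vc <- paste0("vc_", c(
    "perimeter", "area", "minr", "maxr", "feret", "breadth",
    "chull_perimeter", "chull_area", "aspect_ratio", "circularity",
    "roundness", "area_eq_diameter", "perim_eq_diameter", "eq_ellipse_area",
    "compactness", "solidity", "shape", "rfactor", "modification_ratio",
    "sphericity", "arbbox", "rectangularity"
  ))
  nuc <- paste0("nuc_", c(
    "perimeter", "area", "chull_area", "circularity", "solidity",
    "concavity", "convexity", "shape"
  ))
  c(colour, vc, nuc)
}

#' Eleven colour statistics of a pixel region
#'
#' Statistics of the intensity values of one region in one stain channel:
#' mode and entropy use the 256-bin integer histogram (entropy in bits),
#' `avgdev` is the mean absolute deviation from the mean, `sd`/`var` are the
#' sample statistics, and skewness/kurtosis are the population moment ratios
#' (kurtosis as excess); degenerate (constant) regions report 0 for the
#' dispersion-normalised statistics.
#'
#' @param x Numeric vector of intensities in \[0, 255\].
#' @return Named numeric vector of length 11.
#' @export
colour_stats <- function(x) {
  if (length(x) == 0L) stop("empty region")
  g <- as.integer(round(pmin(pmax(x, 0), 255)))
  counts <- tabulate(g + 1L, nbins = 256L)
  mode_v <- which.max(counts) - 1L # ties -> lowest value
  p <- counts[counts > 0L] / length(g)
  entropy <- -sum(p * log2(p))
  m <- mean(x)
  n <- length(x)
  v <- if (n > 1L) var(x) else 0
  m2 <- mean((x - m)^2)
  skew <- if (m2 > 0) mean((x - m)^3) / m2^1.5 else 0
  kurt <- if (m2 > 0) mean((x - m)^4) / m2^2 - 3 else 0
  c(
    mode = as.numeric(mode_v), median = median(x), mean = m,
    avgdev = mean(abs(x - m)), sd = sqrt(v), min = min(x), max = max(x),
    var = v, skew = skew, kurt = kurt, entropy = entropy
  )
}

## ---- geometry helpers ------------------------------------------------------

# Moore-neighbour boundary trace of an 8-connected region given as pixel
# coordinates; returns the ordered boundary polygon (matrix of row, col).
trace_boundary <- function(rows, cols) {
  r0 <- min(rows); c0 <- min(cols)
  nr <- max(rows) - r0 + 3L
  nc <- max(cols) - c0 + 3L
  m <- matrix(FALSE, nr, nc)
  m[cbind(rows - r0 + 2L, cols - c0 + 2L)] <- TRUE

  # start: first foreground pixel in column-major order; its W and N
  # neighbours are then guaranteed background
  start <- which(m)[1]
  sr <- (start - 1L) %% nr + 1L
  sc <- (start - 1L) %/% nr + 1L
  # Moore neighbourhood in a fixed rotational order starting from "W"
  dr <- c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L)
  dc <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
  dir_index <- function(from, to) {
    which(dr == (to[1] - from[1]) & dc == (to[2] - from[2]))
  }

  path <- matrix(0L, 4L * length(rows) + 8L, 2L)
  path[1L, ] <- c(sr, sc)
  np <- 1L
  cur <- c(sr, sc)
  back <- c(sr, sc - 1L) # background by construction
  first_k <- NA_integer_
  repeat {
    b <- dir_index(cur, back)
    k_found <- NA_integer_
    for (i in 0:7) {
      k <- (b - 1L + i) %% 8L + 1L
      cell <- c(cur[1] + dr[k], cur[2] + dc[k])
      if (m[cell[1], cell[2]]) {
        k_found <- k
        if (i > 0L) {
          kprev <- (b - 1L + i - 1L) %% 8L + 1L
          back <- c(cur[1] + dr[kprev], cur[2] + dc[kprev])
        }
        break
      }
    }
    if (is.na(k_found)) break # isolated pixel
    # Jacob's criterion: back at the start pixel, about to repeat the first move
    if (np > 1L && cur[1] == sr && cur[2] == sc && k_found == first_k) break
    if (is.na(first_k)) first_k <- k_found
    cur <- c(cur[1] + dr[k_found], cur[2] + dc[k_found])
    np <- np + 1L
    path[np, ] <- cur
    if (np >= nrow(path)) break # safety cap; cannot trigger for valid regions
  }
  # drop a duplicated closing vertex if the trace ended back on the start
  if (np > 1L && path[np, 1] == sr && path[np, 2] == sc) np <- np - 1L
  path[seq_len(np), , drop = FALSE] +
    matrix(c(r0 - 2L, c0 - 2L), np, 2L, byrow = TRUE)
}

polygon_length <- function(pts, closed = TRUE) {
  n <- nrow(pts)
  if (n < 2L) return(0)
  d <- sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2)
  tot <- sum(d)
  if (closed) tot <- tot + sqrt(sum((pts[n, ] - pts[1, ])^2))
  tot
}

# perimeter of the region boundary polygon; 1-pixel regions fall back to 4
region_perimeter <- function(rows, cols) {
  if (length(rows) == 1L) return(4)
  pts <- trace_boundary(rows, cols)
  if (nrow(pts) == 1L) return(4)
  polygon_length(pts)
}

# convex hull of pixel centres: vertices (x = col, y = row), ccw
region_hull <- function(rows, cols) {
  pts <- cbind(x = cols, y = rows)
  idx <- grDevices::chull(pts) # clockwise in standard orientation
  pts[rev(idx), , drop = FALSE]
}

hull_perimeter <- function(hull) {
  if (nrow(hull) < 2L) return(0)
  polygon_length(hull)
}

# number of pixel centres of the bounding-box grid inside or on the hull
hull_pixel_area <- function(hull, eps = 1e-9) {
  nv <- nrow(hull)
  if (nv == 1L) return(1)
  xr <- range(hull[, 1]); yr <- range(hull[, 2])
  gx <- seq(ceiling(xr[1] - eps), floor(xr[2] + eps))
  gy <- seq(ceiling(yr[1] - eps), floor(yr[2] + eps))
  px <- rep(gx, each = length(gy))
  py <- rep(gy, times = length(gx))
  inside <- rep(TRUE, length(px))
  if (nv == 2L) {
    # degenerate (collinear) hull: points on the segment
    dx <- hull[2, 1] - hull[1, 1]; dy <- hull[2, 2] - hull[1, 2]
    cross <- (px - hull[1, 1]) * dy - (py - hull[1, 2]) * dx
    t <- ((px - hull[1, 1]) * dx + (py - hull[1, 2]) * dy) / (dx^2 + dy^2)
    inside <- abs(cross) < eps & t >= -eps & t <= 1 + eps
  } else {
    for (i in seq_len(nv)) {
      j <- if (i == nv) 1L else i + 1L
      ex <- hull[j, 1] - hull[i, 1]; ey <- hull[j, 2] - hull[i, 2]
      cross <- ex * (py - hull[i, 2]) - ey * (px - hull[i, 1])
      inside <- inside & (cross >= -eps)
      if (!any(inside)) break
    }
  }
  sum(inside)
}

# feret (max caliper) and breadth (max extent perpendicular to the feret axis)
feret_breadth <- function(hull) {
  n <- nrow(hull)
  if (n < 2L) return(c(feret = 0, breadth = 0))
  dx <- outer(hull[, 1], hull[, 1], "-")
  dy <- outer(hull[, 2], hull[, 2], "-")
  d2 <- dx^2 + dy^2
  best <- which.max(d2)
  feret <- sqrt(d2[best])
  if (feret == 0) return(c(feret = 0, breadth = 0))
  i <- (best - 1L) %% n + 1L
  j <- (best - 1L) %/% n + 1L
  ux <- (hull[j, 1] - hull[i, 1]) / feret
  uy <- (hull[j, 2] - hull[i, 2]) / feret
  # projections onto the perpendicular of the feret direction
  proj <- -uy * hull[, 1] + ux * hull[, 2]
  c(feret = feret, breadth = max(proj) - min(proj))
}

safe_ratio <- function(num, den) if (is.na(den) || den <= 0) 0 else num / den

#' Shape descriptors of a virtual cell
#'
#' The 22 morphological descriptors of a pixel region: perimeter, area, radii
#' of the inscribed/enclosing circles centred at the centre of mass (MinR,
#' MaxR), feret and breadth calipers, convex-hull perimeter and area, and the
#' derived ratios (`circularity = 4*pi*area/perimeter^2`,
#' `roundness = 4*area/(pi*feret^2)`, `sphericity = MinR/MaxR`,
#' `rectangularity = area/(feret*breadth)`, ...). Ratios with zero
#' denominators are reported as 0; a 1-pixel region has perimeter 4, area 1.
#'
#' @param rows,cols Integer pixel coordinates of the region (8-connected).
#' @return Named numeric vector of length 22.
#' @export
vcell_shape <- function(rows, cols) {
  n <- length(rows)
  if (n == 0L) stop("empty region")
  area <- n
  perim <- region_perimeter(rows, cols)
  hull <- region_hull(rows, cols)
  hp <- hull_perimeter(hull)
  ha <- hull_pixel_area(hull)
  fb <- feret_breadth(hull)
  feret <- fb[["feret"]]; breadth <- fb[["breadth"]]
  cen_r <- mean(rows); cen_c <- mean(cols)
  dr2 <- (rows - cen_r)^2 + (cols - cen_c)^2
  maxr <- sqrt(max(dr2))
  bnd <- boundary_pixels(rows, cols)
  minr <- sqrt(min((bnd[, 1] - cen_r)^2 + (bnd[, 2] - cen_c)^2))
  arbbox <- feret * breadth
  c(
    perimeter = perim, area = area, minr = minr, maxr = maxr,
    feret = feret, breadth = breadth,
    chull_perimeter = hp, chull_area = ha,
    aspect_ratio = safe_ratio(feret, breadth),
    circularity = safe_ratio(4 * pi * area, perim^2),
    roundness = safe_ratio(4 * area, pi * feret^2),
    area_eq_diameter = sqrt(4 / pi * area),
    perim_eq_diameter = perim / pi,
    eq_ellipse_area = pi * feret * breadth / 4,
    compactness = safe_ratio(sqrt(4 / pi * area), feret),
    solidity = safe_ratio(area, ha),
    shape = safe_ratio(perim^2, area),
    rfactor = safe_ratio(hp, feret * pi),
    modification_ratio = safe_ratio(2 * minr, feret),
    sphericity = safe_ratio(minr, maxr),
    arbbox = arbbox,
    rectangularity = safe_ratio(area, arbbox)
  )
}

# region pixels adjacent (4-connectivity) to background
boundary_pixels <- function(rows, cols) {
  r0 <- min(rows); c0 <- min(cols)
  nr <- max(rows) - r0 + 3L
  nc <- max(cols) - c0 + 3L
  m <- matrix(FALSE, nr, nc)
  rr <- rows - r0 + 2L; cc <- cols - c0 + 2L
  m[cbind(rr, cc)] <- TRUE
  interior <- m[cbind(rr - 1L, cc)] & m[cbind(rr + 1L, cc)] &
    m[cbind(rr, cc - 1L)] & m[cbind(rr, cc + 1L)]
  cbind(rows[!interior], cols[!interior])
}

#' Shape descriptors of a nuclear marker
#'
#' The 8 nucleus descriptors: perimeter, area, convex-hull area, circularity,
#' solidity, `concavity = chullArea - area`,
#' `convexity = hull perimeter / perimeter`, and `shape = perimeter^2/area`.
#'
#' @inheritParams vcell_shape
#' @return Named numeric vector of length 8.
#' @export
nucleus_shape <- function(rows, cols) {
  n <- length(rows)
  if (n == 0L) stop("empty region")
  area <- n
  perim <- region_perimeter(rows, cols)
  hull <- region_hull(rows, cols)
  hp <- hull_perimeter(hull)
  ha <- hull_pixel_area(hull)
  c(
    perimeter = perim, area = area, chull_area = ha,
    circularity = safe_ratio(4 * pi * area, perim^2),
    solidity = safe_ratio(area, ha),
    concavity = ha - area,
    convexity = safe_ratio(hp, perim),
    shape = safe_ratio(perim^2, area)
  )
}

#' Build the per-v-cell feature table
#'
#' One row per virtual cell, ordered by ascending v-cell id: 11 colour
#' statistics on each of the three stain channels over the v-cell's pixels,
#' 22 v-cell shape descriptors and 8 shape descriptors of the enclosed
#' (same-id) nucleus — 63 feature columns plus the `vcell` id column.
#'
#' @param vcells A `vcell_map` from [partition_vcells()].
#' @param stain Stain image from [deconvolve()] with the same frame.
#' @return A tibble with `vcells$n` rows and 64 columns.
#' @export
build_feature_table <- function(vcells, stain) {
  stopifnot(inherits(vcells, "vcell_map"))
  stopifnot(all(dim(stain)[1:2] == dim(vcells$labels)))
  n <- vcells$n
  lab <- vcells$labels
  nuc <- vcells$nuclei
  nr <- nrow(lab)

  vc_idx <- split(which(lab > 0L), lab[lab > 0L])
  nuc_idx <- split(which(nuc > 0L), nuc[nuc > 0L])
  if (length(vc_idx) != n || length(nuc_idx) != n ||
      !identical(names(vc_idx), as.character(seq_len(n))) ||
      !identical(names(nuc_idx), as.character(seq_len(n))))
    stop("pairing error: every v-cell id must appear in both labels and nuclei")

  haem <- stain[, , "haem"]; eos <- stain[, , "eosin"]; res <- stain[, , "resid"]
  rows_list <- lapply(vc_idx, function(i) (i - 1L) %% nr + 1L)
  cols_list <- lapply(vc_idx, function(i) (i - 1L) %/% nr + 1L)

  feats <- vapply(seq_len(n), function(id) {
    i <- vc_idx[[id]]
    ni <- nuc_idx[[id]]
    c(
      colour_stats(haem[i]), colour_stats(eos[i]), colour_stats(res[i]),
      vcell_shape(rows_list[[id]], cols_list[[id]]),
      nucleus_shape((ni - 1L) %% nr + 1L, (ni - 1L) %/% nr + 1L)
    )
  }, numeric(63L))

  out <- as_tibble(t(feats), .name_repair = "minimal")
  names(out) <- feature_column_names()
  dplyr::bind_cols(tibble(vcell = seq_len(n)), out)
}

#' Z-standardise feature columns
#'
#' Centres and scales every feature column to mean 0 and sd 1 (columns with
#' zero spread are set to 0). Mixed units — pixels, dimensionless ratios,
#' intensities — make this necessary before distance-based clustering.
#'
#' @param features Feature table (tibble) from [build_feature_table()]; an
#'   optional `vcell` id column is preserved unscaled.
#' @return Tibble of the same shape.
#' @export
standardize_features <- function(features) {
  stopifnot(is.data.frame(features))
  dplyr::mutate(features, dplyr::across(
    -dplyr::any_of("vcell"),
    function(x) {
      s <- sd(x)
      if (is.na(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
    }
  ))
}

# matrix of standardised features, id column dropped
feature_matrix <- function(features) {
  x <- features[setdiff(names(features), "vcell")]
  as.matrix(x)
}
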