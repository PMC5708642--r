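## Synthetic H&E-like tissue images with known gold standards, and planted
## feature-space datasets. The image generator composes per-stain density
## fields (dark elliptical nuclei in haematoxylin, compartment-dependent
## diffuse eosin) and pushes them through the forward Beer-Lambert model with
## Gaussian pixel noise, so every pipeline stage can be tested against exact
## ground truth.

#' Specification of a synthetic tissue image
#'
#' Defines a circular tissue core on a bright background, split into an
#' epithelium and a stroma compartment by a wavy vertical boundary.
#' Epithelium carries denser, rounder nuclei; stroma carries sparser,
#' elongated nuclei and stronger eosin uptake — the contrast the segmentation
#' method exploits. Nuclei are placed by dart-throwing with a minimum-spacing
#' constraint so that seeds never merge. Densities are nuclei per 1e4 px^2;
#' optical densities (OD) are dimensionless Beer-Lambert absorbances.
#'
#' @param size Image side in pixels (square image).
#' @param core_radius_frac Core radius as a fraction of `size`.
#' @param boundary_amp_frac,boundary_waves Amplitude (fraction of `size`) and
#'   number of sine waves of the compartment boundary.
#' @param epi_density,str_density Nuclei per 1e4 px^2 in each compartment.
#' @param epi_radius,str_radius Nucleus equivalent-radius range (px).
#' @param epi_ecc,str_ecc Nucleus axis-ratio range (1 = circle).
#' @param epi_haem_od,str_haem_od Cytoplasm haematoxylin OD per compartment.
#' @param epi_eosin_od,str_eosin_od Cytoplasm eosin OD per compartment.
#' @param nucleus_haem_od Haematoxylin OD inside nuclei (both compartments;
#'   stroma nuclei take 90% of it).
#' @param nucleus_eosin_od Eosin OD inside nuclei.
#' @param background_od Residual OD of the glass background.
#' @param noise_sd Gaussian noise sd added to the final RGB (grey levels).
#' @param min_spacing_pad Extra clearance (px) added to the nucleus spacing.
#' @param seed RNG seed; all randomness flows from it.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(size = 512L,
                           core_radius_frac = 0.47,
                           boundary_amp_frac = 0.08,
                           boundary_waves = 2,
                           epi_density = 16,
                           str_density = 7,
                           epi_radius = c(5, 6.5),
                           str_radius = c(6, 7.5),
                           epi_ecc = c(1, 1.25),
                           str_ecc = c(1.5, 1.9),
                           epi_haem_od = 0.25,
                           str_haem_od = 0.12,
                           epi_eosin_od = 0.35,
                           str_eosin_od = 0.6,
                           nucleus_haem_od = 1.0,
                           nucleus_eosin_od = 0.15,
                           background_od = 0.02,
                           noise_sd = 2,
                           min_spacing_pad = 3,
                           seed = 1L) {
  stopifnot(size >= 64L, epi_density > 0, str_density > 0)
  structure(as.list(environment()), class = "synthetic_spec")
}

# dart-throwing placement of `target` points inside `eligible` (logical
# matrix), at least `spacing[i]+spacing[j])/2`... enforced via per-point
# spacing: accepted point must be >= (s_new + s_old)/2 from every old point
place_nuclei <- function(eligible, target, spacing, existing = NULL) {
  idx <- which(eligible)
  nr <- nrow(eligible)
  pts <- if (is.null(existing)) matrix(numeric(0), 0L, 3L) else existing
  if (length(idx) == 0L || target == 0L) {
    return(list(placed = matrix(numeric(0), 0L, 2L), all = pts))
  }
  placed <- matrix(numeric(0), 0L, 2L)
  tries <- 0L
  max_tries <- 200L * target
  while (nrow(placed) < target && tries < max_tries) {
    tries <- tries + 1L
    p <- idx[sample.int(length(idx), 1L)]
    r <- (p - 1L) %% nr + 1L
    c <- (p - 1L) %/% nr + 1L
    if (nrow(pts) > 0L) {
      need <- (spacing + pts[, 3L]) / 2
      d2 <- (pts[, 1L] - r)^2 + (pts[, 2L] - c)^2
      if (any(d2 < need^2)) next
    }
    pts <- rbind(pts, c(r, c, spacing))
    placed <- rbind(placed, c(r, c))
  }
  list(placed = placed, all = pts)
}

rasterise_ellipse <- function(size, r0, c0, a, b, theta) {
  rr <- max(1L, floor(r0 - a)):min(size, ceiling(r0 + a))
  cc <- max(1L, floor(c0 - a)):min(size, ceiling(c0 + a))
  dr <- outer(rr - r0, rep(1, length(cc)))
  dc <- outer(rep(1, length(rr)), cc - c0)
  u <- (dr * cos(theta) + dc * sin(theta)) / a
  v <- (-dr * sin(theta) + dc * cos(theta)) / b
  sel <- which(u^2 + v^2 <= 1, arr.ind = TRUE)
  cbind(row = rr[sel[, 1]], col = cc[sel[, 2]])
}

#' Generate a synthetic H&E tissue image
#'
#' Renders the scene described by a [synthetic_spec()]: compartment masks,
#' per-stain optical-density fields, nuclei as dark ellipses in the
#' haematoxylin field, then the forward Beer-Lambert composition to an 8-bit
#' RGB image with Gaussian noise. Bit-identical for a fixed spec seed.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `image` (RGB array, 0-255), `gold` (integer class matrix:
#'   0 background, 1 epithelium, 2 stroma), `nuclei` (tibble of planted
#'   nucleus centres and shapes), and `spec`.
#' @export
generate_tissue_image <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n <- spec$size
  centre <- (n + 1) / 2
  radius <- spec$core_radius_frac * n

  rowm <- matrix(seq_len(n), n, n)
  colm <- matrix(seq_len(n), n, n, byrow = TRUE)
  core <- (rowm - centre)^2 + (colm - centre)^2 <= radius^2

  # wavy vertical boundary: epithelium left, stroma right
  phase <- runif(spec$boundary_waves, 0, 2 * pi)
  amp <- spec$boundary_amp_frac * n
  split_col <- centre + rowSums(vapply(seq_len(spec$boundary_waves), function(w) {
    amp / w * sin(2 * pi * w * seq_len(n) / n + phase[w])
  }, numeric(n)))
  epi <- core & (colm < split_col[rowm])
  str_ <- core & !epi

  gold <- matrix(0L, n, n)
  gold[epi] <- 1L
  gold[str_] <- 2L

  # nucleus placement: margin keeps the whole ellipse inside its compartment
  place_compartment <- function(mask, density, rad_range, ecc_range, spacing,
                                existing) {
    margin <- ceiling(rad_range[2] * sqrt(ecc_range[2])) + 1L
    interior <- erode3(mask, margin)
    target <- round(density * sum(mask) / 1e4)
    place_nuclei(interior, target, spacing, existing)
  }
  epi_major <- spec$epi_radius[2] * sqrt(spec$epi_ecc[2])
  str_major <- spec$str_radius[2] * sqrt(spec$str_ecc[2])
  epi_sp <- 2 * epi_major + spec$min_spacing_pad
  str_sp <- 2 * str_major + spec$min_spacing_pad

  pe <- place_compartment(epi, spec$epi_density, spec$epi_radius, spec$epi_ecc,
                          epi_sp, NULL)
  ps <- place_compartment(str_, spec$str_density, spec$str_radius, spec$str_ecc,
                          str_sp, pe$all)

  draw <- function(centres, rad_range, ecc_range) {
    m <- nrow(centres)
    if (m == 0L) {
      return(tibble(row = numeric(0), col = numeric(0), a = numeric(0),
                    b = numeric(0), angle = numeric(0)))
    }
    r <- runif(m, rad_range[1], rad_range[2])
    ecc <- runif(m, ecc_range[1], ecc_range[2])
    tibble(
      row = centres[, 1], col = centres[, 2],
      a = r * sqrt(ecc), b = r / sqrt(ecc),
      angle = runif(m, 0, pi)
    )
  }
  nuc_epi <- draw(pe$placed, spec$epi_radius, spec$epi_ecc)
  nuc_str <- draw(ps$placed, spec$str_radius, spec$str_ecc)

  # optical-density fields
  haem <- matrix(spec$background_od, n, n)
  eosin <- matrix(spec$background_od, n, n)
  resid <- matrix(spec$background_od, n, n)
  haem[epi] <- spec$epi_haem_od
  haem[str_] <- spec$str_haem_od
  eosin[epi] <- spec$epi_eosin_od
  eosin[str_] <- spec$str_eosin_od
  resid[core] <- spec$background_od + 0.02

  paint <- function(nuc, haem_od) {
    for (i in seq_len(nrow(nuc))) {
      px <- rasterise_ellipse(n, nuc$row[i], nuc$col[i], nuc$a[i], nuc$b[i],
                              nuc$angle[i])
      haem[px] <<- haem_od * runif(1, 0.9, 1.1)
      eosin[px] <<- spec$nucleus_eosin_od
    }
  }
  paint(nuc_epi, spec$nucleus_haem_od)
  paint(nuc_str, 0.9 * spec$nucleus_haem_od)

  dens <- array(c(haem, eosin, resid), c(n, n, 3L))
  img <- compose_stains(dens, quantise = FALSE)
  img <- img + array(rnorm(length(img), 0, spec$noise_sd), dim(img))
  img <- round(pmin(pmax(img, 0), 255))

  nuclei <- dplyr::bind_rows(
    dplyr::mutate(nuc_epi, compartment = "epithelium"),
    dplyr::mutate(nuc_str, compartment = "stroma")
  )
  list(image = img, gold = gold, nuclei = nuclei, spec = spec)
}

#' Planted two-cluster feature data
#'
#' Two spherical Gaussian clusters in the 63-dimensional feature space, with
#' centroid distance `separation * noise_sd` along a random direction. At
#' separation 0 the labels are unrecoverable; at separation 10 any reasonable
#' clusterer recovers them exactly.
#'
#' @param n Number of objects (balanced across the two clusters).
#' @param k Number of clusters (only 2 supported).
#' @param separation Centroid distance in units of `noise_sd`.
#' @param noise_sd Within-cluster standard deviation.
#' @param seed RNG seed.
#' @param d Dimensionality (default 63, the feature-table width).
#' @return List with `features` (tibble, `d` columns named as in
#'   [feature_column_names()]) and `labels` (integer vector).
#' @export
generate_planted_features <- function(n, k = 2L, separation, noise_sd = 1,
                                      seed = 1L, d = 63L) {
  stopifnot(k == 2L, n >= 2L * k)
  set.seed(seed)
  labels <- rep(seq_len(k), length.out = n)
  u <- rnorm(d)
  u <- u / sqrt(sum(u^2))
  shift <- separation * noise_sd
  x <- matrix(rnorm(n * d, 0, noise_sd), n, d)
  x[labels == 2L, ] <- x[labels == 2L, , drop = FALSE] +
    matrix(shift * u, sum(labels == 2L), d, byrow = TRUE)
  colnames(x) <- feature_column_names()[seq_len(d)]
  list(features = as_tibble(x), labels = labels)
}
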