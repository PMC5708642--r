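# Independent oracles used across the suite. These never call the code paths
# they check.

# Rand index by exhaustive pair enumeration
ri_brute <- function(a, b) {
  n <- length(a)
  agree <- 0L
  total <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      same_a <- a[i] == a[j]
      same_b <- b[i] == b[j]
      agree <- agree + as.integer(same_a == same_b)
      total <- total + 1L
    }
  }
  agree / total
}

# Jaccard overlap of two clusters by explicit weighted set arithmetic
ji_brute <- function(a, ci, b, cj, areas) {
  ia <- which(a == ci)
  ib <- which(b == cj)
  uni <- union(ia, ib)
  if (length(uni) == 0L) return(0)
  sum(areas[intersect(ia, ib)]) / sum(areas[uni])
}

# all 2-cluster labellings of n objects (up to label symmetry both orders kept)
all_two_cluster_partitions <- function(n) {
  out <- list()
  for (code in 1:(2^n - 2)) {
    bits <- as.integer(intToBits(code))[seq_len(n)]
    out[[length(out) + 1L]] <- bits + 1L
  }
  out
}

# convex-hull pixel count via Pick's theorem: lattice points inside or on a
# lattice polygon = A + B/2 + 1
hull_area_pick <- function(rows, cols) {
  pts <- cbind(cols, rows)
  idx <- grDevices::chull(pts)
  h <- pts[idx, , drop = FALSE]
  nv <- nrow(h)
  if (nv == 1L) return(1)
  if (nv == 2L) {
    return(as.numeric(gcd2(abs(h[2, 1] - h[1, 1]), abs(h[2, 2] - h[1, 2])) + 1))
  }
  a2 <- 0
  bpts <- 0
  for (i in seq_len(nv)) {
    j <- if (i == nv) 1L else i + 1L
    a2 <- a2 + h[i, 1] * h[j, 2] - h[j, 1] * h[i, 2]
    bpts <- bpts + gcd2(abs(h[j, 1] - h[i, 1]), abs(h[j, 2] - h[i, 2]))
  }
  as.numeric(abs(a2) / 2 + bpts / 2 + 1)
}

gcd2 <- function(a, b) {
  while (b != 0) {
    t <- b
    b <- a %% b
    a <- t
  }
  a
}

# disc region pixel coordinates
disc_region <- function(r, size = 2L * r + 41L) {
  centre <- (size + 1) / 2
  m <- expand.grid(row = seq_len(size), col = seq_len(size))
  m[(m$row - centre)^2 + (m$col - centre)^2 <= r^2, ]
}

# flat grey image with a square basin of given depth
basin_image <- function(size = 40L, at = 15:25, level = 200, depth = 50) {
  g <- matrix(level, size, size)
  g[at, at] <- level - depth
  g
}

# small noiseless stain-image fixture: dark tissue disc on bright background
flat_stain_fixture <- function(size = 64L, tissue_level = 80, bg_level = 250) {
  centre <- (size + 1) / 2
  rowm <- matrix(seq_len(size), size, size)
  colm <- matrix(seq_len(size), size, size, byrow = TRUE)
  tissue <- (rowm - centre)^2 + (colm - centre)^2 <= (0.3 * size)^2
  ch <- matrix(bg_level, size, size)
  ch[tissue] <- tissue_level
  stain <- array(0, c(size, size, 3L),
                 dimnames = list(NULL, NULL, c("haem", "eosin", "resid")))
  stain[, , "haem"] <- ch
  stain[, , "eosin"] <- ch
  stain[, , "resid"] <- 255
  list(stain = stain, tissue = tissue)
}

# manual ensemble from a list of assignment vectors
manual_ensemble <- function(assignments, replaceable = FALSE) {
  parts <- lapply(seq_along(assignments), function(i) {
    p <- new_partition(assignments[[i]], algorithm = paste0("manual", i),
                      replaceable = replaceable)
    attr(p, "origin_index") <- i
    p
  })
  vcellseg:::new_ensemble(parts)
}
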