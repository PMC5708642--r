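test_that("h-concave transform is zero on flat images", {
  g <- matrix(120, 30, 30)
  expect_true(all(hconcave(g, 30) == 0))
})

test_that("h-concave fills a deep basin by exactly h", {
  g <- basin_image(depth = 50)
  hc <- hconcave(g, 30)
  expect_true(all(hc[15:25, 15:25] == 30))
  expect_true(all(hc[-(15:25), ] == 0))
})

test_that("a basin shallower than h fills to its own depth", {
  # a deeper companion basin acts as the drain, so the shallow basin's fill
  # is capped at its pour level (the standard reconstruction convention)
  g <- basin_image(depth = 10)
  g[30:38, 30:38] <- 100
  hc <- hconcave(g, 30)
  expect_true(all(hc[15:25, 15:25] == 10))
  expect_true(all(hc[1:10, 1:10] == 0))
})

test_that("h-concave rejects out-of-range depths", {
  g <- matrix(10, 5, 5)
  expect_error(hconcave(g, 0), "h must be")
  expect_error(hconcave(g, 300), "h must be")
})

test_that("Huang threshold separates a noiseless bimodal stain image", {
  fx <- flat_stain_fixture()
  mask <- tissue_mask(fx$stain)
  expect_identical(mask, fx$tissue)
})

test_that("the residual channel does not influence the tissue mask", {
  fx <- flat_stain_fixture()
  st2 <- fx$stain
  st2[, , "resid"] <- matrix(sample(0:255, length(st2[, , 3]), TRUE),
                             nrow(st2[, , 3]))
  expect_identical(tissue_mask(st2), tissue_mask(fx$stain))
})

test_that("constant images raise a degenerate-threshold error", {
  st <- array(240, c(8, 8, 3), dimnames = list(NULL, NULL, c("haem", "eosin", "resid")))
  expect_error(tissue_mask(st), "degenerate")
})

test_that("cropping recovers the bounding box of a planted tissue disc", {
  size <- 120L
  img <- array(250, c(size, size, 3))
  centre <- 60.5; r <- 25
  rowm <- matrix(seq_len(size), size, size)
  colm <- matrix(seq_len(size), size, size, byrow = TRUE)
  disc <- (rowm - centre)^2 + (colm - centre)^2 <= r^2
  for (ch in 1:3) {
    pl <- img[, , ch]
    pl[disc] <- 90
    img[, , ch] <- pl
  }
  crp <- crop_to_tissue(img)
  rows <- range(which(rowSums(disc) > 0))
  expect_equal(dim(crp)[1], diff(rows) + 1L)
  expect_equal(attr(crp, "offset")[1], rows[1] - 1L)
  # an already tight image comes back unchanged
  again <- crop_to_tissue(crp)
  expect_equal(dim(again), dim(crp))
  expect_equal(attr(again, "offset"), c(0L, 0L))
})

test_that("an all-background image raises a no-tissue error", {
  img <- array(255, c(40, 40, 3))
  expect_error(crop_to_tissue(img), "no tissue")
})

test_that("seed extraction keeps large blobs unchanged and drops small ones", {
  size <- 60L
  haem <- matrix(200, size, size)
  mask <- matrix(TRUE, size, size)
  rowm <- matrix(seq_len(size), size, size)
  colm <- matrix(seq_len(size), size, size, byrow = TRUE)
  big <- (rowm - 20)^2 + (colm - 20)^2 <= 8^2
  small <- (rowm - 45)^2 + (colm - 45)^2 <= 2^2
  haem[big] <- 150
  haem[small] <- 150
  seeds <- nuclear_seeds(haem, mask, h = 30, e = 3)
  expect_identical(seeds, big) # big blob survives with its exact shape
  raw <- nuclear_seeds(haem, mask, h = 30, e = 0)
  expect_identical(raw, big | small) # e = 0 is a no-op opening
})

test_that("opening by reconstruction never deforms surviving components", {
  set.seed(3)
  m <- matrix(FALSE, 50, 50)
  m[5:20, 5:20] <- TRUE   # survives 3 erosions
  m[30:32, 30:32] <- TRUE # dies
  op <- opening_by_reconstruction(m, 3)
  expect_true(all(op[5:20, 5:20]))
  expect_false(any(op[30:32, 30:32]))
  expect_equal(sum(op), 16L * 16L)
})

test_that("watershed with two seeds on a flat landscape splits equidistantly", {
  mask <- matrix(TRUE, 11, 21)
  seeds <- matrix(FALSE, 11, 21)
  seeds[6, 4] <- TRUE
  seeds[6, 18] <- TRUE
  vm <- partition_vcells(mask, seeds, mode = "distance")
  expect_equal(vm$n, 2L)
  expect_true(all(vm$labels[, 1:10] == 1L))
  expect_true(all(vm$labels[, 12:21] == 2L))
})

test_that("a single seed claims the whole mask", {
  fx <- flat_stain_fixture()
  seeds <- matrix(FALSE, nrow(fx$tissue), ncol(fx$tissue))
  seeds[32, 32] <- TRUE
  vm <- partition_vcells(fx$tissue, seeds, fx$stain[, , "haem"])
  expect_equal(vm$n, 1L)
  expect_identical(vm$labels == 1L, fx$tissue)
})

test_that("v-cells exactly tile the mask and contain their seeds", {
  set.seed(7)
  size <- 80L
  haem <- matrix(210, size, size) + matrix(rnorm(size^2, 0, 1), size)
  mask <- matrix(FALSE, size, size)
  mask[8:72, 8:72] <- TRUE
  centres <- expand.grid(r = c(20, 40, 60), c = c(20, 40, 60))
  rowm <- matrix(seq_len(size), size, size)
  colm <- matrix(seq_len(size), size, size, byrow = TRUE)
  for (i in seq_len(nrow(centres))) {
    sel <- (rowm - centres$r[i])^2 + (colm - centres$c[i])^2 <= 5^2
    haem[sel] <- 100
  }
  seeds <- nuclear_seeds(round(haem), mask, h = 30, e = 3)
  vm <- partition_vcells(mask, seeds, round(haem))
  expect_equal(vm$n, nrow(centres))
  expect_identical(vm$labels > 0L, mask) # tiling
  expect_equal(sum(vcell_areas(vm)), sum(mask))
  expect_true(all(vm$labels[vm$nuclei > 0L] == vm$nuclei[vm$nuclei > 0L]))
})

test_that("seed count is non-increasing in h on basins of graded depth", {
  size <- 50L
  haem <- matrix(220, size, size)
  mask <- matrix(TRUE, size, size)
  depths <- c(15, 35, 60, 90)
  at <- list(8:12, 8:12, 38:42, 38:42)
  atc <- list(8:12, 38:42, 8:12, 38:42)
  for (i in seq_along(depths)) haem[at[[i]], atc[[i]]] <- 220 - depths[i]
  counts <- vapply(c(5, 25, 45, 80), function(h) {
    s <- nuclear_seeds(haem, mask, h = h, e = 0)
    max(vcellseg:::cpp_label_components(s))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("partitioning without seeds raises an empty-partition error", {
  mask <- matrix(TRUE, 5, 5)
  expect_error(partition_vcells(mask, matrix(FALSE, 5, 5), mask * 0),
               "empty partition")
})

test_that("greyscale reconstruction agrees with iterative dilation", {
  set.seed(11)
  mask <- matrix(sample(0:255, 400, TRUE), 20, 20)
  marker <- pmax(mask - sample(0:60, 400, TRUE), 0)
  fast <- reconstruct_dilate(marker, mask)
  # naive fixed-point iteration as oracle
  ref <- marker
  repeat {
    d <- ref
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      d <- pmax(d, vcellseg:::shift_matrix(ref, dr, dc, -Inf))
    }
    d <- pmin(d, mask)
    if (all(d == ref)) break
    ref <- d
  }
  expect_identical(fast, ref)
})
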