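test_that("colour statistics match direct summation on simple samples", {
  cs <- colour_stats(rep(100, 20))
  expect_equal(unname(cs[c("mean", "median", "mode", "min", "max")]),
               rep(100, 5))
  expect_equal(unname(cs[c("var", "sd", "entropy", "skew", "kurt")]),
               rep(0, 5))

  x <- c(0, 0, 255, 255)
  cs2 <- colour_stats(x)
  expect_equal(unname(cs2["mean"]), 127.5)
  expect_equal(unname(cs2["var"]), var(x))
  expect_equal(unname(cs2["avgdev"]), mean(abs(x - mean(x))))
  expect_equal(unname(cs2["entropy"]), 1) # two equiprobable values = 1 bit
  expect_equal(unname(cs2["mode"]), 0)    # tie broken to the lower level

  sym <- c(10, 20, 30, 40, 50)
  expect_lt(abs(colour_stats(sym)[["skew"]]), 1e-9)
  expect_error(colour_stats(numeric(0)), "empty")
})

test_that("a large digital disc approaches the continuous-circle limits", {
  reg <- disc_region(30)
  vs <- vcell_shape(reg$row, reg$col)
  expect_equal(unname(vs["circularity"]), 1, tolerance = 0.1)
  expect_equal(unname(vs["sphericity"]), 1, tolerance = 0.05)
  expect_equal(unname(vs["solidity"]), 1, tolerance = 0.02)
  expect_equal(unname(vs["roundness"]), 1, tolerance = 0.05)
  ns <- nucleus_shape(reg$row, reg$col)
  expect_equal(unname(ns["convexity"]), 1, tolerance = 0.07)
  expect_equal(unname(ns["concavity"]), 0, tolerance = 1e-9)
})

test_that("an axis-aligned square matches its closed-form geometry", {
  a <- 200L
  sq <- expand.grid(row = seq_len(a), col = seq_len(a))
  vs <- vcell_shape(sq$row, sq$col)
  expect_equal(unname(vs["perimeter"]), 4 * (a - 1))
  expect_equal(unname(vs["area"]), a^2)
  expect_equal(unname(vs["circularity"]), pi / 4, tolerance = 0.02)
  expect_equal(unname(vs["feret"]), sqrt(2) * (a - 1), tolerance = 1e-9)
  expect_equal(unname(vs["rectangularity"]),
               a^2 / (2 * (a - 1)^2), tolerance = 1e-9)
  expect_equal(unname(vs["solidity"]), 1)
})

test_that("solidity is 1 for convex regions and below 1 for concave ones", {
  reg <- disc_region(12)
  expect_equal(unname(vcell_shape(reg$row, reg$col)["solidity"]), 1)
  cshape <- subset(expand.grid(row = 1:30, col = 1:30),
    (row - 15)^2 + (col - 15)^2 <= 170 & !(col > 15 & abs(row - 15) < 5))
  expect_lt(vcell_shape(cshape$row, cshape$col)[["solidity"]], 0.95)
})

test_that("hull area and concavity agree with the Pick's-theorem oracle", {
  set.seed(5)
  for (rep in 1:5) {
    pts <- unique(data.frame(
      row = sample(1:25, 60, TRUE), col = sample(1:25, 60, TRUE)
    ))
    # make the pixel set 8-connected enough for tracing by taking a blob
    reg <- subset(expand.grid(row = 1:30, col = 1:30),
      (row - sample(10:20, 1))^2 / runif(1, 1, 3) +
        (col - sample(10:20, 1))^2 <= sample(40:90, 1))
    ns <- nucleus_shape(reg$row, reg$col)
    pick <- hull_area_pick(reg$row, reg$col)
    expect_equal(unname(ns["chull_area"]), pick)
    expect_equal(unname(ns["concavity"]), pick - nrow(reg))
  }
})

test_that("one-pixel regions use the documented fallbacks", {
  vs <- vcell_shape(7, 9)
  expect_equal(unname(vs["perimeter"]), 4)
  expect_equal(unname(vs["area"]), 1)
  expect_equal(unname(vs[c("aspect_ratio", "roundness", "rfactor")]),
               c(0, 0, 0))
})

test_that("table identities hold exactly", {
  reg <- subset(expand.grid(row = 1:40, col = 1:40),
    (row - 20)^2 / 4 + (col - 18)^2 <= 120)
  vs <- vcell_shape(reg$row, reg$col)
  expect_equal(unname(vs["arbbox"]), unname(vs["feret"] * vs["breadth"]))
  expect_equal(unname(vs["aspect_ratio"]), unname(vs["feret"] / vs["breadth"]))
  expect_equal(unname(vs["shape"]), unname(vs["perimeter"]^2 / vs["area"]))
  expect_equal(unname(vs["area_eq_diameter"]), sqrt(4 / pi * vs[["area"]]))
  expect_equal(unname(vs["eq_ellipse_area"]),
               pi * vs[["feret"]] * vs[["breadth"]] / 4)
  ns <- nucleus_shape(reg$row, reg$col)
  expect_equal(unname(ns["concavity"]), unname(ns["chull_area"] - ns["area"]))
})

test_that("dimensionless descriptors are scale-stable; area and perimeter scale", {
  small <- disc_region(10)
  big <- disc_region(20)
  vs <- vcell_shape(small$row, small$col)
  vb <- vcell_shape(big$row, big$col)
  for (f in c("circularity", "roundness", "solidity", "sphericity",
              "aspect_ratio", "rectangularity")) {
    expect_equal(unname(vb[f]), unname(vs[f]), tolerance = 0.06)
  }
  expect_equal(unname(vb["area"] / vs["area"]), 4, tolerance = 0.05)
  expect_equal(unname(vb["perimeter"] / vs["perimeter"]), 2, tolerance = 0.05)
})

make_tiny_vcell_map <- function() {
  lab <- matrix(0L, 12, 22)
  lab[3:9, 3:9] <- 1L
  lab[3:9, 14:20] <- 2L
  nuc <- matrix(0L, 12, 22)
  nuc[5:7, 5:7] <- 1L
  nuc[5:7, 16:18] <- 2L
  vcellseg:::new_vcell_map(lab, nuc, 2L)
}

test_that("the feature table has one row per v-cell and 63 feature columns", {
  vm <- make_tiny_vcell_map()
  stain <- array(200, c(12, 22, 3),
                 dimnames = list(NULL, NULL, c("haem", "eosin", "resid")))
  stain[, , "haem"][vm$nuclei > 0L] <- 90
  ft <- build_feature_table(vm, stain)
  expect_equal(nrow(ft), 2L)
  expect_identical(names(ft), c("vcell", feature_column_names()))
  expect_equal(length(feature_column_names()), 63L)
  expect_false(anyNA(ft))
})

test_that("translated copies of a v-cell produce identical feature rows", {
  vm <- make_tiny_vcell_map()
  stain <- array(180, c(12, 22, 3),
                 dimnames = list(NULL, NULL, c("haem", "eosin", "resid")))
  stain[, , "haem"][vm$nuclei > 0L] <- 70
  ft <- build_feature_table(vm, stain)
  expect_equal(unlist(ft[1, -1]), unlist(ft[2, -1]), tolerance = 1e-12)
})

test_that("standardisation yields zero mean and unit sd per column", {
  set.seed(2)
  vm <- make_tiny_vcell_map()
  stain <- array(round(runif(12 * 22 * 3, 60, 250)), c(12, 22, 3),
                 dimnames = list(NULL, NULL, c("haem", "eosin", "resid")))
  ft <- build_feature_table(vm, stain)
  ft <- dplyr::bind_rows(ft, dplyr::mutate(ft, haem_mean = haem_mean + 5))
  z <- standardize_features(ft)
  expect_equal(nrow(z), nrow(ft))
  expect_equal(mean(z$haem_mean), 0, tolerance = 1e-12)
  expect_equal(sd(z$haem_mean), 1, tolerance = 1e-12)
  expect_identical(z$vcell, ft$vcell) # ids pass through unscaled
})
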