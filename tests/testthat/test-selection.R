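test_that("the Rand index matches hand-enumerated and brute-force values", {
  expect_equal(rand_index(c(1, 1, 2, 2), c(1, 2, 2, 2)), 0.5) # TP=1 TN=2 of 6
  expect_equal(rand_index(1:2, c(5, 9)), 1)
  a <- c(1, 1, 2, 2, 3)
  expect_equal(rand_index(a, a), 1)
  expect_equal(rand_index(a, c(3, 3, 1, 1, 2)), 1) # label permutation
  expect_error(rand_index(1:3, 1:4), "different numbers")
})

test_that("rand_index equals exhaustive pair enumeration for all small partitions", {
  parts6 <- all_two_cluster_partitions(6)
  set.seed(14)
  pick <- sample(seq_along(parts6), 12)
  for (i in pick) {
    for (j in sample(seq_along(parts6), 6)) {
      expect_equal(rand_index(parts6[[i]], parts6[[j]]),
                   ri_brute(parts6[[i]], parts6[[j]]))
    }
  }
  # up to 4 clusters over 8 objects
  for (rep in 1:20) {
    a <- sample(1:4, 8, replace = TRUE)
    b <- sample(1:4, 8, replace = TRUE)
    expect_equal(rand_index(a, b), ri_brute(a, b))
  }
})

test_that("rand_index is symmetric", {
  set.seed(8)
  for (rep in 1:10) {
    a <- sample(1:3, 10, TRUE)
    b <- sample(1:3, 10, TRUE)
    expect_equal(rand_index(a, b), rand_index(b, a))
  }
})

test_that("ensemble similarity averages pairwise Rand indices", {
  l <- c(1, 1, 2, 2)
  lp <- c(1, 2, 2, 2) # RI(l, lp) = 0.5
  E <- manual_ensemble(list(l, l, lp))
  expect_equal(ensemble_similarity(1L, E), (1 + 0.5) / 2)
  expect_equal(ensemble_similarity(3L, E), 0.5)
  Eid <- manual_ensemble(list(l, l, l))
  for (i in 1:3) expect_equal(ensemble_similarity(i, Eid), 1)
})

test_that("similarity of a member lies within the pairwise RI bounds", {
  set.seed(4)
  parts <- lapply(1:5, function(i) sample(1:2, 12, TRUE))
  E <- manual_ensemble(parts)
  ris <- sapply(2:5, function(j) rand_index(parts[[1]], parts[[j]]))
  s <- ensemble_similarity(1L, E)
  expect_gte(s, min(ris))
  expect_lte(s, max(ris))
})

test_that("an all-identical ensemble empties under selection", {
  l <- rep(1:2, each = 10)
  E <- manual_ensemble(list(l, l, l, l))
  expect_error(select_ensemble(E), "empty ensemble")
})

test_that("a moderately diverse ensemble passes selection unchanged", {
  set.seed(2)
  base <- rep(1:2, each = 20)
  parts <- lapply(1:6, function(i) {
    flip <- sample(40, 8)
    out <- base
    out[flip] <- 3 - out[flip]
    out
  })
  E <- manual_ensemble(parts)
  sims <- sapply(seq_along(E), ensemble_similarity, ensemble = E)
  expect_true(all(sims >= 0.5 & sims <= 0.9))
  sel <- select_ensemble(E)
  expect_length(sel$ensemble, 6L)
  expect_true(all(sel$report$status == "kept"))
})

test_that("adversarial members fall outside the window and are excluded", {
  set.seed(6)
  base <- rep(1:2, each = 25)
  near <- lapply(1:5, function(i) {
    out <- base
    flip <- sample(50, 6)
    out[flip] <- 3 - out[flip]
    out
  })
  skew <- c(rep(1, 48), 2, 2) # degenerate partition, similarity below D1
  E <- manual_ensemble(c(near, list(skew)))
  sel <- select_ensemble(E, D1 = 0.6, D2 = 0.95)
  expect_equal(sel$report$status[6], "removed")
  expect_length(sel$ensemble, 5L)
  # every selected member satisfies the window against the original E
  kept_sims <- sel$report$similarity[sel$report$status == "kept"]
  expect_true(all(kept_sims >= 0.6 & kept_sims <= 0.95))
})

test_that("replacements are drawn from the same algorithm and screened vs E", {
  pf <- generate_planted_features(60, separation = 2, seed = 9)
  E <- generate_ensemble(pf$features, seed = 13)
  sel <- select_ensemble(E, regenerate = make_regenerator(E), seed = 5)
  rep_rows <- sel$report[sel$report$status == "replaced", ]
  if (nrow(rep_rows) > 0) {
    expect_true(all(rep_rows$final_similarity >= 0.5 &
                      rep_rows$final_similarity <= 0.9))
  }
  kept_alg <- vapply(sel$ensemble, attr, character(1), "algorithm")
  expect_true(all(kept_alg %in% c("kmeans", "em", "lvq", "mdb", "ah")))
})

test_that("selection rejects invalid thresholds", {
  E <- manual_ensemble(list(c(1, 1, 2), c(1, 2, 2)))
  expect_error(select_ensemble(E, D1 = 0.9, D2 = 0.5), "D1 < D2")
})
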