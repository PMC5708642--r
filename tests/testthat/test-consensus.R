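test_that("the co-association matrix counts pairwise co-clusterings", {
  l <- c(1, 1, 2, 2)
  E <- manual_ensemble(list(l, l, l))
  M <- coassociation(E)
  expect_equal(M, outer(l, l, "==") * 1)
  # i,j together in 2 of 4 partitions -> 0.5
  E2 <- manual_ensemble(list(c(1, 1, 2), c(1, 1, 2), c(1, 2, 2), c(1, 2, 1)))
  M2 <- coassociation(E2)
  expect_equal(M2[1, 2], 0.5)
  expect_true(all(diag(M2) == 1))
  expect_identical(M2, t(M2))
})

test_that("EAC recovers the common partition of an identical ensemble", {
  l <- c(1, 2, 1, 2, 2, 1)
  E <- manual_ensemble(list(l, l, l))
  res <- eac_consensus(E)
  expect_equal(rand_index(res$partition, l), 1)
})

test_that("EAC cuts exact blocks of the co-association matrix", {
  M <- rbind(c(1, 1, 0), c(1, 1, 0), c(0, 0, 1))
  res <- eac_consensus(M)
  cl <- as.integer(res$partition)
  expect_equal(cl[1], cl[2])
  expect_false(cl[1] == cl[3])
})

test_that("Jaccard cluster overlap follows weighted set arithmetic", {
  a <- c(1, 1, 2, 2)
  b <- c(2, 1, 2, 1)
  areas <- c(10, 10, 10, 30)
  # c = a's cluster 1 = v-cells {1,2} (areas 10,10); c' = b's cluster 1 =
  # v-cells {2,4} (areas 10,30); shared v-cell 2 -> JI = 10 / 50
  expect_equal(jaccard_cluster_overlap(a, 1, b, 1, areas = areas), 10 / 50)
  expect_equal(jaccard_cluster_overlap(a, 1, a, 1, areas = areas), 1)
  expect_equal(jaccard_cluster_overlap(a, 1, b, 99, areas = areas), 0)
  expect_equal(ji_brute(a, 1, b, 1, areas), 10 / 50)
})

test_that("area-weighted and pixel-rasterised Jaccard agree exactly", {
  lab <- matrix(0L, 10, 16)
  lab[2:5, 2:5] <- 1L
  lab[2:8, 8:10] <- 2L
  lab[7:9, 2:4] <- 3L
  nuc <- matrix(0L, 10, 16)
  nuc[3, 3] <- 1L; nuc[3, 9] <- 2L; nuc[8, 3] <- 3L
  vm <- vcellseg:::new_vcell_map(lab, nuc, 3L)
  a <- c(1, 1, 2)
  b <- c(1, 2, 2)
  for (ci in 1:2) for (cj in 1:2) {
    expect_equal(
      jaccard_cluster_overlap(a, ci, b, cj, vcells = vm, method = "area"),
      jaccard_cluster_overlap(a, ci, b, cj, vcells = vm, method = "pixel")
    )
  }
})

test_that("label alignment undoes a pure label swap and keeps identity", {
  ref <- c(1, 1, 2, 2, 1)
  E <- manual_ensemble(list(ref, 3 - ref, ref))
  al <- align_labels(E, reference = 1L)
  expect_equal(as.integer(al[[2]]), ref)
  expect_equal(as.integer(al[[3]]), ref)
})

test_that("alignment picks the mapping of maximal Jaccard overlap (brute force)", {
  set.seed(12)
  areas <- sample(5:20, 10, TRUE)
  ref <- rep(1:2, each = 5)
  for (rep in 1:10) {
    lj <- sample(1:2, 10, TRUE)
    E <- manual_ensemble(list(ref, lj))
    al <- align_labels(E, reference = 1L, areas = areas)
    got <- as.integer(al[[2]])
    ji_id <- ji_brute(ref, 1, lj, 1, areas)
    ji_sw <- ji_brute(ref, 1, lj, 2, areas)
    expected <- if (ji_sw > ji_id) 3 - lj else lj
    expect_equal(got, expected)
  }
})

test_that("voting consensus is the majority label after alignment", {
  ref <- c(1, 1, 2, 2, 1, 2)
  dissent <- ref
  dissent[3] <- 1
  E <- manual_ensemble(list(ref, ref, dissent))
  v <- voting_consensus(E)
  expect_equal(as.integer(v$partition), ref) # 2-vs-1 on object 3
  # unanimous ensembles return their common partition
  Eu <- manual_ensemble(list(ref, ref, ref))
  expect_equal(as.integer(voting_consensus(Eu)$partition), ref)
})

test_that("vote ties go to the member with the highest ensemble similarity", {
  # two members disagreeing on one v-cell: similarity computed against a
  # 4-member original ensemble decides the tie
  a <- c(1, 1, 2, 2, 2)
  b <- c(1, 1, 1, 2, 2) # differs from a on v-cell 3
  orig <- manual_ensemble(list(a, b, a, a))
  sel <- manual_ensemble(list(a, b))
  sims <- vapply(sel, ensemble_similarity, numeric(1), ensemble = orig)
  expect_gt(sims[1], sims[2]) # a agrees with more of the original ensemble
  v <- voting_consensus(sel, orig)
  expect_equal(as.integer(v$partition)[3], a[3])
})

test_that("consensus outputs are invariant to member label permutations", {
  set.seed(5)
  base <- rep(1:2, each = 8)
  parts <- lapply(1:5, function(i) {
    out <- base
    out[sample(16, 2)] <- sample(1:2, 2, TRUE)
    out
  })
  E1 <- manual_ensemble(parts)
  flipped <- parts
  flipped[[2]] <- 3 - flipped[[2]]
  flipped[[4]] <- 3 - flipped[[4]]
  E2 <- manual_ensemble(flipped)
  expect_equal(rand_index(voting_consensus(E1)$partition,
                          voting_consensus(E2)$partition), 1)
  expect_equal(rand_index(eac_consensus(E1)$partition,
                          eac_consensus(E2)$partition), 1)
})

test_that("voting consensus handles thousands of v-cells without pairwise work", {
  set.seed(3)
  n <- 4000L
  base <- rep(1:2, length.out = n)
  parts <- lapply(1:7, function(i) {
    out <- base
    out[sample(n, 50)] <- sample(1:2, 50, TRUE)
    out
  })
  E <- manual_ensemble(parts)
  t0 <- proc.time()[["elapsed"]]
  v <- voting_consensus(E)
  # alignment + voting only; the similarity report against E is O(C^2 n)
  expect_length(as.integer(v$partition), n)
  expect_lt(proc.time()[["elapsed"]] - t0, 10)
  expect_gte(rand_index(v$partition, base), 0.999)
})

test_that("consensus objects expose tidy/glance accessors", {
  l <- c(1, 1, 2, 2)
  E <- manual_ensemble(list(l, l, l))
  v <- voting_consensus(E)
  td <- tidy(v)
  expect_identical(names(td), c("vcell", "cluster"))
  expect_equal(nrow(td), 4L)
  gl <- glance(v)
  expect_equal(gl$method, "voting")
  expect_equal(gl$cluster1_size + gl$cluster2_size, 4L)
})
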