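## Diversity-based ensemble selection: members whose average Rand index
## against the original ensemble falls outside [D1, D2] are replaced (new
## random seed) or removed.

#' Rand index between two partitions
#'
#' Fraction of object pairs on which the two partitions agree (grouped
#' together in both, or apart in both): `RI = (TP + TN) / (n choose 2)`.
#' Invariant under any relabelling of either partition; 1 means identical
#' partitions.
#'
#' @param a,b Partitions over the same objects (`vc_partition`, integer or
#'   factor vectors).
#' @return Similarity in \[0, 1\].
#' @export
rand_index <- function(a, b) {
  a <- partition_assignments(a)
  b <- partition_assignments(b)
  if (length(a) != length(b)) stop("partitions cover different numbers of objects")
  n <- length(a)
  if (n < 2L) stop("need at least 2 objects")
  tab <- table(a, b)
  pairs <- function(x) sum(x * (x - 1) / 2)
  total <- n * (n - 1) / 2
  tp <- pairs(tab)
  fp <- pairs(rowSums(tab)) - tp # same under a, different under b
  fn <- pairs(colSums(tab)) - tp
  tn <- total - tp - fp - fn
  (tp + tn) / total
}

#' Average Rand index of a partition against an ensemble
#'
#' `similarity(Li, E) = mean over j != i of RI(Li, Lj)`. For a member of the
#' ensemble, its own slot is excluded; for an external candidate, `exclude`
#' names the member slot it would replace.
#'
#' @param partition A `vc_partition` or integer index into `ensemble`.
#' @param ensemble A `vc_ensemble`.
#' @param exclude Optional member index excluded from the average (the
#'   candidate's own slot).
#' @return Mean Rand index in \[0, 1\].
#' @export
ensemble_similarity <- function(partition, ensemble, exclude = NULL) {
  stopifnot(inherits(ensemble, "vc_ensemble"))
  if (length(ensemble) < 2L) stop("ensemble must have at least 2 members")
  if (is.numeric(partition) && length(partition) == 1L &&
      partition == round(partition) && partition <= length(ensemble)) {
    exclude <- as.integer(partition)
    partition <- ensemble[[exclude]]
  } else if (is.null(exclude)) {
    exclude <- attr(partition, "origin_index")
  }
  others <- setdiff(seq_along(ensemble), exclude)
  mean(vapply(others, function(j) rand_index(partition, ensemble[[j]]),
              numeric(1)))
}

#' Select a moderate-diversity sub-ensemble
#'
#' Keeps every member whose average Rand index against the *original* ensemble
#' lies in `[D1, D2]` (inclusive). A rejected member is replaced by fresh runs
#' of the same algorithm with new seeds (via `regenerate`), up to
#' `max_attempts` tries, accepting the first replacement whose similarity —
#' still measured against the original ensemble, excluding the replaced slot —
#' satisfies the criterion; otherwise the member is removed without
#' replacement. Deterministic members (AH) cannot produce new solutions and
#' are removed directly.
#'
#' @param ensemble A `vc_ensemble` (the original ensemble E).
#' @param D1,D2 Minimum and maximum accepted similarity, `0 <= D1 < D2 <= 1`.
#' @param regenerate `NULL` or a function `(partition, seed) -> vc_partition`
#'   producing a fresh run of the same algorithm; see [make_regenerator()].
#' @param max_attempts Replacement attempts per rejected member.
#' @param seed RNG seed for the replacement seeds.
#' @return List with `ensemble` (the selected `vc_ensemble`) and `report`
#'   (tibble: per-member algorithm, similarity, and kept/replaced/removed
#'   status).
#' @export
select_ensemble <- function(ensemble, D1 = 0.5, D2 = 0.9, regenerate = NULL,
                            max_attempts = 5L, seed = 1L) {
  stopifnot(inherits(ensemble, "vc_ensemble"))
  if (!(D1 >= 0 && D1 < D2 && D2 <= 1)) stop("need 0 <= D1 < D2 <= 1")
  set.seed(seed)
  sims <- vapply(seq_along(ensemble), ensemble_similarity, numeric(1),
                 ensemble = ensemble)
  status <- character(length(ensemble))
  final_sim <- sims
  kept <- vector("list", 0L)
  for (i in seq_along(ensemble)) {
    if (sims[i] >= D1 && sims[i] <= D2) {
      status[i] <- "kept"
      kept <- c(kept, list(ensemble[[i]]))
      next
    }
    member <- ensemble[[i]]
    if (!isTRUE(attr(member, "replaceable")) || is.null(regenerate)) {
      status[i] <- "removed"
      next
    }
    status[i] <- "removed"
    for (att in seq_len(max_attempts)) {
      new_seed <- sample.int(.Machine$integer.max - 1L, 1L)
      cand <- regenerate(member, new_seed)
      s <- ensemble_similarity(cand, ensemble, exclude = i)
      if (s >= D1 && s <= D2) {
        attr(cand, "origin_index") <- i
        kept <- c(kept, list(cand))
        status[i] <- "replaced"
        final_sim[i] <- s
        break
      }
    }
  }
  report <- tibble(
    index = seq_along(ensemble),
    algorithm = vapply(ensemble, attr, character(1), "algorithm"),
    similarity = sims,
    status = status,
    final_similarity = final_sim
  )
  if (length(kept) == 0L)
    stop("empty ensemble after selection: no member satisfies [D1, D2]")
  list(ensemble = new_ensemble(kept, seed = attr(ensemble, "seed")),
       report = report)
}

#' Replacement-run factory for ensemble selection
#'
#' Returns a function that re-runs a rejected member's algorithm, with its
#' original parameters but a fresh seed, on the same standardised feature
#' matrix the ensemble was generated from.
#'
#' @param ensemble A `vc_ensemble` from [generate_ensemble()] (carries its
#'   feature matrix), or `NULL` to build from `x`.
#' @param x Standardised feature matrix (used when `ensemble` is NULL).
#' @param k Number of clusters.
#' @return Function `(partition, seed) -> vc_partition`.
#' @export
make_regenerator <- function(ensemble = NULL, x = NULL, k = 2L) {
  if (is.null(x)) {
    stopifnot(inherits(ensemble, "vc_ensemble"))
    x <- attr(ensemble, "data")
    if (is.null(x)) stop("ensemble carries no feature matrix; supply x")
  }
  cfg <- if (!is.null(ensemble)) attr(ensemble, "config") else NULL
  function(partition, seed) {
    alg <- attr(partition, "algorithm")
    params <- attr(partition, "params")
    switch(alg,
      kmeans = kmeans_partition(x, k, params$n_starts, seed),
      em = em_partition(x, k, params$n_starts, seed),
      lvq = lvq_partition(x, k, params$learning_rate,
                          if (!is.null(params$epochs)) params$epochs else 100L,
                          seed),
      mdb = mdb_partition(x, k, seed),
      stop("algorithm '", alg, "' is deterministic; cannot regenerate")
    )
  }
}
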