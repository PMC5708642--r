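## Base clusterers and ensemble generation. All partitions use k = 2: the
## two tissue compartments (epithelium vs stroma) are the only classes the
## method distinguishes.

#' Construct a partition
#'
#' A partition is an integer vector of cluster ids (1..k) over the n objects,
#' carrying provenance: the generating algorithm, its parameters, the RNG
#' seed, and whether a fresh run with a new seed can produce a different
#' solution (`replaceable`; FALSE for deterministic algorithms).
#'
#' @param assignments Integer-like vector of cluster ids.
#' @param algorithm Name of the generating algorithm.
#' @param params Named list of algorithm parameters.
#' @param seed RNG seed used, or NA for deterministic algorithms.
#' @param replaceable Can a re-run with a new seed give a new solution?
#' @return A `vc_partition`.
#' @export
new_partition <- function(assignments, algorithm = "manual", params = list(),
                          seed = NA_integer_, replaceable = FALSE) {
  a <- as.integer(assignments)
  if (anyNA(a)) stop("assignments must be complete (no NA)")
  structure(a,
    class = "vc_partition", algorithm = algorithm, params = params,
    seed = seed, replaceable = replaceable
  )
}

#' @export
print.vc_partition <- function(x, ...) {
  cat("<vc_partition> ", length(x), " objects, k = ", length(unique(unclass(x))),
      ", algorithm = ", attr(x, "algorithm"), "\n", sep = "")
  invisible(x)
}

partition_assignments <- function(x) {
  if (inherits(x, "vc_partition")) return(as.integer(unclass(x)))
  if (is.numeric(x)) return(as.integer(x)) # cluster ids kept verbatim
  as.integer(as.factor(x))
}

#' k-means base clusterer
#'
#' Standard k-means with `n_starts` random initial-centre draws; the start
#' with the lowest within-cluster sum of squares is kept.
#'
#' @param x Numeric matrix (objects x features), already standardised.
#' @param k Number of clusters.
#' @param n_starts Number of random initialisations evaluated.
#' @param seed RNG seed.
#' @return A `vc_partition`.
#' @export
kmeans_partition <- function(x, k = 2L, n_starts = 10L, seed = 1L) {
  set.seed(seed)
  km <- kmeans(x, centers = k, nstart = n_starts, iter.max = 100L)
  new_partition(km$cluster, "kmeans", list(n_starts = n_starts), seed, TRUE)
}

#' EM Gaussian-mixture base clusterer
#'
#' Diagonal-covariance Gaussian mixture fitted by EM. `n_starts` random hard
#' assignments (nearest of k randomly chosen rows) are scored by one M+E step;
#' EM iterates from the best candidate (at most 100 iterations, log-likelihood
#' tolerance 1e-6). Falls back to the best candidate's hard assignment if EM
#' degenerates.
#'
#' @inheritParams kmeans_partition
#' @return A `vc_partition`.
#' @export
em_partition <- function(x, k = 2L, n_starts = 10L, seed = 1L) {
  set.seed(seed)
  # zero-spread columns carry no information and break the Gaussian M-step
  keep <- apply(x, 2L, sd) > 0
  x <- x[, keep, drop = FALSE]
  if (ncol(x) == 0L) stop("no informative feature columns")
  n <- nrow(x)
  best <- NULL
  best_ll <- -Inf
  for (s in seq_len(n_starts)) {
    centres <- x[sample.int(n, k), , drop = FALSE]
    d <- vapply(seq_len(k), function(j) rowSums(sweep(x, 2, centres[j, ])^2),
                numeric(n))
    hard <- apply(d, 1L, which.min)
    if (length(unique(hard)) < k) next
    z <- matrix(0, n, k)
    z[cbind(seq_len(n), hard)] <- 1
    ll <- tryCatch({
      ms <- mclust::mstepVVI(data = x, z = z)
      es <- mclust::estepVVI(data = x, parameters = ms$parameters)
      es$loglik
    }, error = function(e) NA_real_)
    if (!is.na(ll) && ll > best_ll) {
      best_ll <- ll
      best <- z
    }
  }
  if (is.null(best)) stop("EM initialisation failed: no valid candidate start")
  fit <- tryCatch(
    mclust::meVVI(data = x, z = best,
               control = mclust::emControl(itmax = 100L, tol = 1e-6)),
    error = function(e) NULL
  )
  cl <- if (!is.null(fit) && !is.null(fit$z) && !anyNA(fit$z)) {
    apply(fit$z, 1L, which.max)
  } else {
    apply(best, 1L, which.max)
  }
  new_partition(cl, "em", list(n_starts = n_starts), seed, TRUE)
}

#' Unsupervised LVQ base clusterer
#'
#' Competitive winner-take-all prototype learning: k prototypes are
#' initialised from random data rows; on each presentation the nearest
#' prototype moves toward the sample by `rate * (x - w)`, with the rate
#' decaying linearly to 0 over the epochs. Objects are finally assigned to
#' their nearest prototype.
#'
#' @inheritParams kmeans_partition
#' @param learning_rate Initial learning rate in (0, 1); 0 disables updates.
#' @param epochs Passes over the data (presentation order reshuffled each
#'   pass).
#' @return A `vc_partition`.
#' @export
lvq_partition <- function(x, k = 2L, learning_rate = 0.05, epochs = 100L,
                          seed = 1L) {
  if (nrow(x) == 0L) stop("empty feature matrix")
  if (learning_rate < 0 || learning_rate >= 1) stop("learning_rate must be in [0, 1)")
  set.seed(seed)
  n <- nrow(x)
  w <- x[sample.int(n, k), , drop = FALSE]
  if (learning_rate > 0) {
    total <- as.numeric(epochs) * n
    step <- 0
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      for (i in ord) {
        xi <- x[i, ]
        d2 <- rowSums((w - matrix(xi, k, ncol(x), byrow = TRUE))^2)
        win <- which.min(d2)
        rate <- learning_rate * (1 - step / total)
        w[win, ] <- w[win, ] + rate * (xi - w[win, ])
        step <- step + 1
      }
    }
  }
  d <- vapply(seq_len(k), function(j) rowSums(sweep(x, 2, w[j, ])^2), numeric(n))
  cl <- apply(d, 1L, which.min)
  new_partition(cl, "lvq",
                list(learning_rate = learning_rate, epochs = epochs), seed, TRUE)
}

#' Density-based reassignment clusterer (MDB)
#'
#' Fits a base k-means partition, models each cluster with independent
#' per-feature normal densities and a cluster prior, and reassigns every
#' object to the cluster of maximal posterior density (ties broken toward the
#' lower cluster index). Per-cluster variances are floored at `var_floor_frac`
#' of the global feature variance.
#'
#' @inheritParams kmeans_partition
#' @param var_floor_frac Variance floor, as a fraction of each feature's
#'   global variance.
#' @return A `vc_partition`.
#' @export
mdb_partition <- function(x, k = 2L, seed = 1L, n_starts = 10L,
                          var_floor_frac = 1e-6) {
  if (nrow(x) <= k) stop("need more objects than clusters")
  set.seed(seed)
  km <- kmeans(x, centers = k, nstart = n_starts, iter.max = 100L)
  cl0 <- km$cluster
  gvar <- apply(x, 2L, var)
  floor_v <- pmax(var_floor_frac * gvar, 1e-12)
  n <- nrow(x)
  ll <- matrix(-Inf, n, k)
  for (j in seq_len(k)) {
    idx <- cl0 == j
    mu <- colMeans(x[idx, , drop = FALSE])
    vv <- apply(x[idx, , drop = FALSE], 2L, function(col) {
      if (length(col) > 1L) var(col) else 0
    })
    vv <- pmax(vv, floor_v)
    prior <- mean(idx)
    centred <- sweep(x, 2L, mu)
    ll[, j] <- log(prior) -
      0.5 * sum(log(2 * pi * vv)) -
      0.5 * colSums(t(centred^2) / vv)
  }
  cl <- apply(ll, 1L, which.max) # which.max takes the first (lowest) index on ties
  new_partition(cl, "mdb", list(var_floor_frac = var_floor_frac), seed, TRUE)
}

#' Agglomerative hierarchical base clusterer
#'
#' `stats::hclust` on the chosen pairwise distance, cut at k clusters.
#' Deterministic for a fixed link/distance, so not replaceable in ensemble
#' selection.
#'
#' @inheritParams kmeans_partition
#' @param link `"complete"` or `"mean"` (average) linkage.
#' @param distance `"euclidean"`, `"manhattan"` or `"minkowski"` (p = 3).
#' @param p Minkowski exponent.
#' @return A `vc_partition`.
#' @export
ah_partition <- function(x, k = 2L, link = c("complete", "mean"),
                         distance = c("euclidean", "manhattan", "minkowski"),
                         p = 3) {
  link <- match.arg(link)
  distance <- match.arg(distance)
  d <- dist(x, method = distance, p = p)
  method <- c(complete = "complete", mean = "average")[[link]]
  cl <- cutree(hclust(d, method = method), k = k)
  new_partition(cl, "ah", list(link = link, distance = distance, p = p),
                NA_integer_, FALSE)
}

#' Ensemble configuration
#'
#' The base-clusterer grid: k-means x10 and EM x10 (random initialisations,
#' initial-candidate counts drawn uniformly from `seed_range`), LVQ x4
#' (learning rates 0.05, 0.07, 0.09, 0.1), MDB x1, and AH x6
#' (complete/mean link x Euclidean/Manhattan/Minkowski-3 distance) — 31
#' partitions in total, all with k = 2.
#'
#' @param kmeans_runs,em_runs,mdb_runs Number of runs per algorithm.
#' @param lvq_rates LVQ learning rates (one run each).
#' @param lvq_epochs LVQ training epochs.
#' @param ah_links,ah_distances AH grid (crossed).
#' @param seed_range Range the per-run random-initialisation counts are drawn
#'   from, for k-means and EM.
#' @param minkowski_p Minkowski exponent for the AH runs.
#' @return A list of class `ensemble_config`.
#' @export
ensemble_config <- function(kmeans_runs = 10L, em_runs = 10L,
                            lvq_rates = c(0.05, 0.07, 0.09, 0.1),
                            lvq_epochs = 100L, mdb_runs = 1L,
                            ah_links = c("complete", "mean"),
                            ah_distances = c("euclidean", "manhattan", "minkowski"),
                            seed_range = c(10L, 200L), minkowski_p = 3) {
  structure(list(
    kmeans_runs = kmeans_runs, em_runs = em_runs, lvq_rates = lvq_rates,
    lvq_epochs = lvq_epochs, mdb_runs = mdb_runs, ah_links = ah_links,
    ah_distances = ah_distances, seed_range = seed_range,
    minkowski_p = minkowski_p
  ), class = "ensemble_config")
}

#' Generate the cluster ensemble
#'
#' Runs the full base-clusterer grid over the feature table and collects all
#' partitions (31 under the default grid) with provenance. All randomness is
#' derived from `seed`, so the same seed reproduces the ensemble exactly.
#'
#' @param features Feature table (tibble with optional `vcell` id column) or
#'   numeric matrix.
#' @param k Number of clusters (2: epithelium vs stroma).
#' @param config An [ensemble_config()].
#' @param seed Master RNG seed.
#' @param standardise Z-score the features first (default TRUE).
#' @return A `vc_ensemble`: list of `vc_partition`s with attributes `n` and
#'   `seed`.
#' @export
generate_ensemble <- function(features, k = 2L, config = ensemble_config(),
                              seed = 1L, standardise = TRUE) {
  x <- if (is.matrix(features)) features else feature_matrix(features)
  if (nrow(x) < k) stop("insufficient data: need at least k objects")
  if (standardise) x <- scale_matrix(x)
  set.seed(seed)
  total_random <- config$kmeans_runs + config$em_runs +
    length(config$lvq_rates) + config$mdb_runs
  seeds <- sample.int(.Machine$integer.max - 1L, total_random)
  starts <- sample(seq(config$seed_range[1], config$seed_range[2]),
                   config$kmeans_runs + config$em_runs, replace = TRUE)
  parts <- vector("list", 0L)
  si <- 0L
  for (i in seq_len(config$kmeans_runs)) {
    si <- si + 1L
    parts <- c(parts, list(kmeans_partition(x, k, starts[si], seeds[si])))
  }
  for (i in seq_len(config$em_runs)) {
    si <- si + 1L
    parts <- c(parts, list(em_partition(x, k, starts[si], seeds[si])))
  }
  for (rate in config$lvq_rates) {
    si <- si + 1L
    parts <- c(parts, list(lvq_partition(x, k, rate, config$lvq_epochs, seeds[si])))
  }
  for (i in seq_len(config$mdb_runs)) {
    si <- si + 1L
    parts <- c(parts, list(mdb_partition(x, k, seeds[si])))
  }
  for (link in config$ah_links) {
    for (distance in config$ah_distances) {
      parts <- c(parts, list(ah_partition(x, k, link, distance, config$minkowski_p)))
    }
  }
  for (i in seq_along(parts)) attr(parts[[i]], "origin_index") <- i
  new_ensemble(parts, seed = seed, data = x, config = config)
}

new_ensemble <- function(partitions, seed = NA_integer_, data = NULL,
                         config = NULL) {
  stopifnot(length(partitions) >= 1L)
  n <- length(partitions[[1]])
  ok <- vapply(partitions, length, integer(1)) == n
  if (!all(ok)) stop("all partitions must cover the same n objects")
  structure(partitions,
    class = "vc_ensemble", n = n, seed = seed, data = data, config = config
  )
}

#' @export
print.vc_ensemble <- function(x, ...) {
  cat("<vc_ensemble> ", length(x), " partitions over ", attr(x, "n"),
      " objects\n", sep = "")
  invisible(x)
}

#' Provenance table of an ensemble
#'
#' @param ensemble A `vc_ensemble`.
#' @return Tibble with one row per member: index, algorithm, parameter string
#'   and seed.
#' @export
ensemble_provenance <- function(ensemble) {
  stopifnot(inherits(ensemble, "vc_ensemble"))
  tibble(
    index = seq_along(ensemble),
    algorithm = vapply(ensemble, attr, character(1), "algorithm"),
    params = vapply(ensemble, function(p) {
      pr <- attr(p, "params")
      if (length(pr) == 0L) return("")
      paste(names(pr), unlist(pr), sep = "=", collapse = ", ")
    }, character(1)),
    seed = vapply(ensemble, function(p) as.integer(attr(p, "seed")), integer(1))
  )
}

scale_matrix <- function(x) {
  s <- apply(x, 2L, sd)
  s[is.na(s) | s == 0] <- Inf # zero-spread columns map to 0
  scale(x, center = TRUE, scale = s)
}
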