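## Consensus functions: evidence accumulation over the co-association matrix,
## and majority voting after Jaccard label alignment.

#' Co-association matrix of an ensemble
#'
#' `M[i, j]` is the fraction of ensemble members that group objects i and j in
#' the same cluster. Symmetric with unit diagonal.
#'
#' @param ensemble A `vc_ensemble`.
#' @return An n x n numeric matrix.
#' @export
coassociation <- function(ensemble) {
  stopifnot(inherits(ensemble, "vc_ensemble"))
  n <- attr(ensemble, "n")
  m <- matrix(0, n, n)
  for (p in ensemble) {
    z <- partition_assignments(p)
    m <- m + outer(z, z, "==")
  }
  m / length(ensemble)
}

new_consensus <- function(assignments, method, k, details = list()) {
  structure(list(
    partition = new_partition(assignments, algorithm = method),
    method = method, k = k, n = length(assignments), details = details
  ), class = "vc_consensus")
}

#' @export
print.vc_consensus <- function(x, ...) {
  sizes <- table(unclass(x$partition))
  cat("<vc_consensus> method = ", x$method, ", n = ", x$n,
      ", cluster sizes: ", paste(sizes, collapse = " / "), "\n", sep = "")
  invisible(x)
}

#' Evidence-accumulation consensus (EAC)
#'
#' Treats `1 - M` (co-association dissimilarity) as a pairwise distance, runs
#' agglomerative hierarchical clustering (average linkage by default) and cuts
#' the tree at k clusters.
#'
#' @param x A `vc_ensemble` or an n x n co-association matrix.
#' @param k Number of consensus clusters.
#' @param linkage `"average"` or `"complete"`.
#' @return A `vc_consensus`.
#' @export
eac_consensus <- function(x, k = 2L, linkage = c("average", "complete")) {
  linkage <- match.arg(linkage)
  m <- if (inherits(x, "vc_ensemble")) coassociation(x) else x
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  if (nrow(m) < k) stop("fewer objects than clusters")
  hc <- hclust(stats::as.dist(1 - m), method = linkage)
  new_consensus(cutree(hc, k = k), "eac", k, details = list(linkage = linkage))
}

#' Jaccard overlap of two clusters rendered on the virtual-cell map
#'
#' The Jaccard index of the pixel sets covered by the member v-cells of
#' cluster `ci` of partition `a` and cluster `cj` of partition `b`. Computed
#' by area-weighted set arithmetic over v-cell ids (exactly equal to pixel
#' rasterisation, which is retained as `method = "pixel"` for conformance);
#' with no areas available every v-cell counts 1. Two empty clusters give 0.
#'
#' @param a,b Partitions over the same v-cells.
#' @param ci,cj Cluster labels within `a` and `b`.
#' @param vcells Optional `vcell_map` (required for `method = "pixel"`,
#'   supplies areas otherwise).
#' @param areas Optional vector of per-v-cell pixel areas.
#' @param method `"area"` (default) or `"pixel"`.
#' @return Jaccard index in \[0, 1\].
#' @export
jaccard_cluster_overlap <- function(a, ci, b, cj, vcells = NULL, areas = NULL,
                                    method = c("area", "pixel")) {
  method <- match.arg(method)
  a <- partition_assignments(a)
  b <- partition_assignments(b)
  stopifnot(length(a) == length(b))
  in_a <- a == ci
  in_b <- b == cj
  if (method == "pixel") {
    stopifnot(inherits(vcells, "vcell_map"))
    lab <- vcells$labels
    pa <- lab > 0L & in_a[pmax(lab, 1L)]
    pb <- lab > 0L & in_b[pmax(lab, 1L)]
    uni <- sum(pa | pb)
    if (uni == 0L) return(0)
    return(sum(pa & pb) / uni)
  }
  if (is.null(areas)) {
    areas <- if (!is.null(vcells)) vcell_areas(vcells) else rep(1, length(a))
  }
  uni <- sum(areas[in_a | in_b])
  if (uni == 0) return(0)
  sum(areas[in_a & in_b]) / uni
}

#' Align cluster labels across an ensemble
#'
#' Resolves the arbitrary-label mismatch between partitions by image overlap:
#' for each non-reference member, each cluster of the reference partition is
#' matched to the member cluster of maximal Jaccard overlap (v-cell areas as
#' weights), and the member's labels are swapped when the best match carries
#' the other label. The reference partition is never modified.
#'
#' @param ensemble A `vc_ensemble` with k = 2 members.
#' @param reference Index of the reference partition.
#' @param vcells Optional `vcell_map` supplying v-cell areas.
#' @param areas Optional per-v-cell areas (unit weights if neither given).
#' @return The ensemble with labels aligned to the reference.
#' @export
align_labels <- function(ensemble, reference = 1L, vcells = NULL, areas = NULL) {
  stopifnot(inherits(ensemble, "vc_ensemble"))
  if (is.null(areas)) {
    areas <- if (!is.null(vcells)) vcell_areas(vcells) else rep(1, attr(ensemble, "n"))
  }
  ref <- ensemble[[reference]]
  out <- ensemble
  for (j in seq_along(ensemble)) {
    if (j == reference) next
    lj <- ensemble[[j]]
    ji_same <- jaccard_cluster_overlap(ref, 1L, lj, 1L, areas = areas)
    ji_swap <- jaccard_cluster_overlap(ref, 1L, lj, 2L, areas = areas)
    if (ji_swap > ji_same) {
      swapped <- partition_assignments(lj)
      swapped <- 3L - swapped
      attrs <- attributes(lj)
      new_lj <- new_partition(swapped,
        algorithm = attrs$algorithm, params = attrs$params,
        seed = attrs$seed, replaceable = attrs$replaceable
      )
      attr(new_lj, "origin_index") <- attrs$origin_index
      out[[j]] <- new_lj
    }
  }
  out
}

#' Voting-based consensus
#'
#' Aligns all member labels to the reference partition (the member with the
#' highest average Rand index against the original ensemble) by Jaccard image
#' overlap, then assigns each v-cell the majority label. An exact vote tie
#' takes the label given by the member of maximal ensemble similarity; a
#' residual tie (equal votes and equal similarity with disagreement) takes the
#' lower cluster label. Performs no pairwise n x n work: cost is linear in n.
#'
#' @param selected The selected ensemble (a `vc_ensemble`).
#' @param original The original ensemble similarities are measured against
#'   (defaults to `selected`).
#' @param vcells Optional `vcell_map` supplying the v-cell areas used by the
#'   alignment.
#' @param areas Optional per-v-cell areas.
#' @return A `vc_consensus`; `details` holds the reference index, member
#'   similarities and the aligned ensemble.
#' @export
voting_consensus <- function(selected, original = selected, vcells = NULL,
                             areas = NULL) {
  stopifnot(inherits(selected, "vc_ensemble"))
  if (length(selected) < 1L) stop("empty ensemble")
  n <- attr(selected, "n")
  ks <- vapply(selected, function(p) max(partition_assignments(p)), integer(1))
  if (any(ks > 2L)) stop("voting consensus requires k = 2 partitions")
  sims <- vapply(selected, ensemble_similarity, numeric(1), ensemble = original)
  reference <- which.max(sims)
  aligned <- align_labels(selected, reference, vcells = vcells, areas = areas)
  lab <- vapply(aligned, partition_assignments, integer(n))
  if (n == 1L) lab <- matrix(lab, nrow = 1L)
  votes1 <- rowSums(lab == 1L)
  votes2 <- rowSums(lab == 2L)
  cl <- ifelse(votes1 > votes2, 1L, 2L)
  ties <- which(votes1 == votes2)
  if (length(ties) > 0L) {
    best <- which(sims == max(sims))
    cl[ties] <- apply(lab[ties, best, drop = FALSE], 1L, min)
  }
  new_consensus(cl, "voting", 2L, details = list(
    reference = reference, similarities = sims, aligned = aligned
  ))
}
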