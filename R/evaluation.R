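## Scoring a consensus partition against a pixel-level gold standard.
## Class codes: 0 background, 1 epithelium, 2 stroma.

gold_class_names <- c(`0` = "background", `1` = "epithelium", `2` = "stroma")

#' Transfer a pixel-level gold standard onto the virtual cells
#'
#' Each v-cell takes the most prevalent pixel class of the annotation image
#' over its pixels; ties are broken by the fixed priority epithelium, then
#' stroma, then background.
#'
#' @param gold Integer matrix of per-pixel classes (0 background, 1
#'   epithelium, 2 stroma), same frame as the v-cell map.
#' @param vcells A `vcell_map`.
#' @return Tibble with columns `vcell` and `gold` (factor with the three class
#'   levels).
#' @export
transfer_gold <- function(gold, vcells) {
  stopifnot(inherits(vcells, "vcell_map"))
  if (!all(dim(gold) == dim(vcells$labels)))
    stop("gold standard and v-cell map dimensions differ")
  if (!all(gold %in% 0:2)) stop("gold classes must be 0, 1 or 2")
  lab <- vcells$labels
  sel <- lab > 0L
  counts <- table(factor(lab[sel], levels = seq_len(vcells$n)),
                  factor(gold[sel], levels = 0:2))
  # tie priority: epithelium (1) > stroma (2) > background (0)
  priority <- c("1", "2", "0")
  cls <- apply(counts[, priority, drop = FALSE], 1L, function(x) {
    priority[which.max(x)]
  })
  tibble(
    vcell = seq_len(vcells$n),
    gold = factor(gold_class_names[cls], levels = unname(gold_class_names))
  )
}

#' Evaluate a consensus partition against the v-cell gold standard
#'
#' The two prediction clusters are first mapped onto \{epithelium, stroma\} by
#' maximal pixel overlap. Reported measures: the Rand index between the
#' predicted and gold v-cell partitions; precision, recall and F1 with
#' epithelium as the positive class (v-cell counts); and the pixel-wise
#' Jaccard index of the rendered epithelium maps (computed exactly as
#' area-weighted v-cell set arithmetic). V-cells whose gold class is
#' background are excluded from all counts.
#'
#' @param pred A `vc_consensus` or `vc_partition` over the v-cells (k = 2).
#' @param gold Result of [transfer_gold()] (tibble with `vcell`, `gold`), or a
#'   vector of per-v-cell class labels.
#' @param vcells Optional `vcell_map` supplying pixel areas; unit areas
#'   otherwise.
#' @return One-row tibble: `rand_index`, `precision`, `recall`, `f1`,
#'   `jaccard`, and the cluster id mapped to epithelium.
#' @export
evaluate_consensus <- function(pred, gold, vcells = NULL) {
  if (inherits(pred, "vc_consensus")) pred <- pred$partition
  cl <- partition_assignments(pred)
  g <- if (is.data.frame(gold)) as.character(gold$gold) else as.character(gold)
  if (length(cl) != length(g))
    stop("prediction and gold standard cover different v-cell sets")
  areas <- if (!is.null(vcells)) vcell_areas(vcells) else rep(1, length(cl))

  fg <- g != "background"
  if (sum(fg) < 2L) stop("fewer than 2 foreground v-cells to evaluate")
  cl <- cl[fg]; gf <- g[fg]; areas <- areas[fg]

  # cluster -> class mapping by maximal pixel overlap
  ov1 <- sum(areas[cl == 1L & gf == "epithelium"]) +
    sum(areas[cl == 2L & gf == "stroma"])
  ov2 <- sum(areas[cl == 2L & gf == "epithelium"]) +
    sum(areas[cl == 1L & gf == "stroma"])
  epi_cluster <- if (ov1 >= ov2) 1L else 2L
  pred_epi <- cl == epi_cluster
  gold_epi <- gf == "epithelium"

  tp <- sum(pred_epi & gold_epi)
  fp <- sum(pred_epi & !gold_epi)
  fn <- sum(!pred_epi & gold_epi)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0

  uni <- sum(areas[pred_epi | gold_epi])
  ji <- if (uni > 0) sum(areas[pred_epi & gold_epi]) / uni else 0

  tibble(
    rand_index = rand_index(cl, as.integer(factor(gf))),
    precision = precision, recall = recall, f1 = f1, jaccard = ji,
    epithelium_cluster = epi_cluster
  )
}
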