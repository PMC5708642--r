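## Rendering and broom-style accessors for the result objects.

# boundary pixels between differently-labelled v-cells (4-neighbour test)
label_boundaries <- function(labels) {
  b <- matrix(FALSE, nrow(labels), ncol(labels))
  for (d in list(c(1L, 0L), c(0L, 1L))) {
    s <- shift_matrix(labels, d[1], d[2], 0L)
    b <- b | (labels != s & labels > 0L & s > 0L)
  }
  b
}

#' Render the v-cell partition as an RGB overlay
#'
#' The source image with black segmentation lines along v-cell boundaries.
#'
#' @param vcells A `vcell_map`.
#' @param image Optional RGB array; white canvas if missing.
#' @return RGB array in \[0, 255\].
#' @export
render_vcell_overlay <- function(vcells, image = NULL) {
  lab <- vcells$labels
  if (is.null(image)) {
    image <- array(255, c(dim(lab), 3L))
    for (ch in 1:3) {
      pl <- image[, , ch]
      pl[lab > 0L] <- 220
      image[, , ch] <- pl
    }
  }
  b <- label_boundaries(lab)
  out <- image
  for (ch in 1:3) {
    pl <- out[, , ch]
    pl[b] <- 0
    out[, , ch] <- pl
  }
  out
}

#' Render a consensus result as a class map
#'
#' Magenta epithelium-like cluster 1, green cluster 2, white background and
#' black v-cell boundary lines.
#'
#' @param consensus A `vc_consensus` (or `vc_partition`).
#' @param vcells The `vcell_map` the partition lives on.
#' @return RGB array in \[0, 255\].
#' @export
render_consensus_map <- function(consensus, vcells) {
  cl <- if (inherits(consensus, "vc_consensus")) {
    partition_assignments(consensus$partition)
  } else {
    partition_assignments(consensus)
  }
  lab <- vcells$labels
  stopifnot(max(lab) <= length(cl))
  palette <- rbind(
    `1` = c(255, 0, 255), # magenta
    `2` = c(0, 200, 0)    # green
  )
  out <- array(255, c(dim(lab), 3L))
  sel <- lab > 0L
  for (ch in 1:3) {
    pl <- out[, , ch]
    pl[sel] <- palette[cl[lab[sel]], ch]
    out[, , ch] <- pl
  }
  b <- label_boundaries(lab)
  for (ch in 1:3) {
    pl <- out[, , ch]
    pl[b] <- 0
    out[, , ch] <- pl
  }
  out
}

#' @describeIn tidy-vcellseg Per-v-cell consensus labels.
#' @method tidy vc_consensus
#' @export
tidy.vc_consensus <- function(x, ...) {
  tibble(vcell = seq_len(x$n), cluster = partition_assignments(x$partition))
}

#' Tidiers for vcellseg objects
#'
#' @name tidy-vcellseg
#' @param x A fitted object.
#' @param ... Unused.
NULL

#' @describeIn tidy-vcellseg One-row summary of a consensus result.
#' @method glance vc_consensus
#' @export
glance.vc_consensus <- function(x, ...) {
  sizes <- tabulate(partition_assignments(x$partition), nbins = x$k)
  tibble(
    method = x$method, k = x$k, n_vcells = x$n,
    cluster1_size = sizes[1], cluster2_size = sizes[2]
  )
}

#' @describeIn tidy-vcellseg Per-member selection report of a pipeline run.
#' @method tidy vc_pipeline_result
#' @export
tidy.vc_pipeline_result <- function(x, ...) x$selection$report

#' @describeIn tidy-vcellseg One-row pipeline summary (evaluation measures
#'   when a gold standard was supplied).
#' @method glance vc_pipeline_result
#' @export
glance.vc_pipeline_result <- function(x, ...) {
  base <- tibble(
    n_vcells = x$vcells$n,
    ensemble_size = length(x$ensemble),
    selected_size = length(x$selection$ensemble)
  )
  if (is.null(x$evaluation)) return(base)
  dplyr::bind_cols(base, tidyr::pivot_wider(
    x$evaluation[, c("method", "rand_index", "f1", "jaccard")],
    names_from = "method",
    values_from = c("rand_index", "f1", "jaccard")
  ))
}

raster_df <- function(img) {
  tibble(
    row = as.vector(row(img[, , 1])),
    col = as.vector(col(img[, , 1])),
    colour = grDevices::rgb(as.vector(img[, , 1]), as.vector(img[, , 2]),
                            as.vector(img[, , 3]), maxColorValue = 255)
  )
}

#' @describeIn tidy-vcellseg Plot a consensus class map (requires the
#'   `vcells` map the labels live on).
#' @param vcells A `vcell_map` for rendering.
#' @method autoplot vc_consensus
#' @export
autoplot.vc_consensus <- function(x, vcells = NULL, ...) {
  if (is.null(vcells)) {
    df <- dplyr::count(tidy(x), .data$cluster)
    return(
      ggplot2::ggplot(df, ggplot2::aes(factor(.data$cluster), .data$n)) +
        ggplot2::geom_col(fill = c("magenta3", "green4")[seq_len(nrow(df))]) +
        ggplot2::labs(x = "consensus cluster", y = "v-cells") +
        ggplot2::theme_minimal()
    )
  }
  img <- render_consensus_map(x, vcells)
  df <- raster_df(img)
  ggplot2::ggplot(df, ggplot2::aes(.data$col, -.data$row, fill = .data$colour)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_identity() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}

#' @describeIn tidy-vcellseg Plot the v-cell partition overlay.
#' @method autoplot vcell_map
#' @export
autoplot.vcell_map <- function(x, image = NULL, ...) {
  img <- render_vcell_overlay(x, image)
  df <- raster_df(img)
  ggplot2::ggplot(df, ggplot2::aes(.data$col, -.data$row, fill = .data$colour)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_identity() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}
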