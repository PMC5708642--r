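## End-to-end orchestration: crop -> deconvolve -> mask -> seeds -> v-cells ->
## features -> ensemble -> selection -> consensus (-> evaluation).

#' Pipeline configuration
#'
#' All tunable parameters of the end-to-end run. Defaults follow the method's
#' operating point: segmentation depth `h = 30` grey levels and `e = 3`
#' erosions, diversity window `[D1, D2] = [0.5, 0.9]`, `k = 2` clusters.
#'
#' @param h Basin depth for nuclear seed detection (grey levels).
#' @param e Erosions of the seed size filter.
#' @param D1,D2 Ensemble-selection similarity window.
#' @param k Number of clusters.
#' @param stain_vectors 3 x 3 stain absorbance matrix (rows = stains).
#' @param ensemble An [ensemble_config()].
#' @param consensus `"voting"`, `"eac"` or `"both"`.
#' @param watershed_mode `"intensity"` or `"distance"`.
#' @param crop Crop background borders before processing.
#' @param max_replacement_attempts Replacement tries per rejected member.
#' @param seed Master RNG seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(h = 30, e = 3L, D1 = 0.5, D2 = 0.9, k = 2L,
                            stain_vectors = default_he_vectors(),
                            ensemble = ensemble_config(),
                            consensus = c("voting", "eac", "both"),
                            watershed_mode = c("intensity", "distance"),
                            crop = TRUE, max_replacement_attempts = 5L,
                            seed = 1L) {
  consensus <- match.arg(consensus)
  watershed_mode <- match.arg(watershed_mode)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Load a pipeline configuration from YAML or JSON
#'
#' Unknown keys are rejected; `stain_vectors` may be given as a 9-element
#' row-major vector or 3 x 3 matrix.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `pipeline_config`.
#' @export
pipeline_config_from_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = ,
    yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("config must be YAML or JSON")
  )
  allowed <- names(formals(pipeline_config))
  bad <- setdiff(names(raw), allowed)
  if (length(bad) > 0L) stop("unknown config keys: ", paste(bad, collapse = ", "))
  if (!is.null(raw$stain_vectors)) {
    raw$stain_vectors <- matrix(as.numeric(unlist(raw$stain_vectors)), 3L, 3L,
                                byrow = TRUE,
                                dimnames = list(c("haem", "eosin", "resid"),
                                                c("R", "G", "B")))
  }
  if (!is.null(raw$ensemble)) raw$ensemble <- do.call(ensemble_config, raw$ensemble)
  do.call(pipeline_config, raw)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("[stage ", name, "] ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full segmentation pipeline on one image
#'
#' Executes every stage in order and returns the artefact bundle. With a gold
#' standard, the bundle also carries the evaluation report for each consensus
#' method. All randomness flows from `config$seed`, so identical invocations
#' produce identical consensus labels.
#'
#' @param image RGB array in \[0, 255\], or a path readable by
#'   [read_image_rgb()].
#' @param config A [pipeline_config()].
#' @param gold Optional gold-standard class matrix (0/1/2) or path.
#' @param output_dir Optional directory: writes the intermediate images, the
#'   feature CSV, consensus CSVs, rendered class maps and a JSON run log.
#' @return List of class `vc_pipeline_result`: `vcells`, `stain`, `mask`,
#'   `seeds`, `features`, `ensemble`, `selection`, `consensus` (named list),
#'   `evaluation` (tibble or NULL), `gold_vcells`, `config`.
#' @export
run_pipeline <- function(image, config = pipeline_config(), gold = NULL,
                         output_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(image)) image <- stage("read", read_image_rgb(image))
  if (is.character(gold)) gold <- stage("read", read_gold_standard(gold))

  if (isTRUE(config$crop)) {
    image <- stage("crop", crop_to_tissue(image, gold = gold))
    if (!is.null(gold)) gold <- attr(image, "gold")
  }
  stain <- stage("deconvolve", deconvolve(image, config$stain_vectors))
  mask <- stage("mask", tissue_mask(stain))
  haem <- stain[, , "haem"]
  seeds <- stage("seeds", nuclear_seeds(haem, mask, h = config$h, e = config$e))
  vcells <- stage("vcells", partition_vcells(mask, seeds, haem,
                                             mode = config$watershed_mode))
  features <- stage("features", build_feature_table(vcells, stain))

  ensemble <- stage("ensemble",
    generate_ensemble(features, k = config$k, config = config$ensemble,
                      seed = config$seed))
  selection <- stage("selection",
    select_ensemble(ensemble, D1 = config$D1, D2 = config$D2,
                    regenerate = make_regenerator(ensemble, k = config$k),
                    max_attempts = config$max_replacement_attempts,
                    seed = config$seed))

  methods <- if (config$consensus == "both") c("eac", "voting") else config$consensus
  consensus <- list()
  for (m in methods) {
    consensus[[m]] <- stage(m, switch(m,
      eac = eac_consensus(selection$ensemble, k = config$k),
      voting = voting_consensus(selection$ensemble, ensemble, vcells = vcells)
    ))
  }

  evaluation <- NULL
  gold_vcells <- NULL
  if (!is.null(gold)) {
    gold_vcells <- stage("gold-transfer", transfer_gold(gold, vcells))
    evaluation <- dplyr::bind_rows(lapply(names(consensus), function(m) {
      dplyr::mutate(
        stage("evaluate", evaluate_consensus(consensus[[m]], gold_vcells, vcells)),
        method = m, .before = 1L
      )
    }))
  }

  result <- structure(list(
    vcells = vcells, stain = stain, mask = mask, seeds = seeds,
    features = features, ensemble = ensemble, selection = selection,
    consensus = consensus, evaluation = evaluation,
    gold_vcells = gold_vcells, config = config
  ), class = "vc_pipeline_result")

  if (!is.null(output_dir)) write_pipeline_bundle(result, image, output_dir)
  result
}

#' @export
print.vc_pipeline_result <- function(x, ...) {
  cat("<vc_pipeline_result> ", x$vcells$n, " v-cells, ",
      length(x$ensemble), " ensemble members, ",
      length(x$selection$ensemble), " selected; consensus: ",
      paste(names(x$consensus), collapse = ", "), "\n", sep = "")
  if (!is.null(x$evaluation)) print(x$evaluation)
  invisible(x)
}

write_pipeline_bundle <- function(result, image, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(output_dir, ...)
  write_image_rgb(image, fp("cropped.png"))
  write_image_rgb(result$stain, fp("stain.png"))
  write_label_tiff(result$vcells$labels, fp("vcells.tif"))
  write_image_rgb(render_vcell_overlay(result$vcells, image), fp("vcells_overlay.png"))
  utils::write.csv(result$features, fp("features.csv"), row.names = FALSE)
  prov <- ensemble_provenance(result$ensemble)
  jsonlite::write_json(prov, fp("ensemble_provenance.json"), dataframe = "rows")
  jsonlite::write_json(result$selection$report, fp("selection_report.json"),
                       dataframe = "rows")
  for (m in names(result$consensus)) {
    utils::write.csv(tidy(result$consensus[[m]]),
                     fp(paste0("consensus_", m, ".csv")), row.names = FALSE)
    write_image_rgb(render_consensus_map(result$consensus[[m]], result$vcells),
                    fp(paste0("consensus_", m, ".png")))
  }
  if (!is.null(result$evaluation)) {
    jsonlite::write_json(result$evaluation, fp("evaluation.json"),
                         dataframe = "rows")
  }
  cfg <- result$config
  cfg$stain_vectors <- as.vector(t(cfg$stain_vectors))
  cfg$ensemble <- unclass(cfg$ensemble)
  jsonlite::write_json(unclass(cfg), fp("run_log.json"), auto_unbox = TRUE)
  invisible(output_dir)
}
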