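## One-shot pipeline: matrix -> preprocessing -> association grid ->
## ordering/selection -> all four figures, driven by a strict YAML (or
## in-memory list) configuration. Any stage error halts with the stage
## named and partial outputs removed; identical config + seed reproduce
## identical artifacts.

.configSchema <- list(
  top = c("seed", "out_dir", "study", "panel", "preprocess", "ordering",
          "plot", "log_level"),
  study = c("synth", "files"),
  synth = c("preset", "seed", "n_samples", "n_metabolites", "mz_range",
            "missing_rate", "missing_mode", "noise_sd"),
  files = c("abundance", "phenotypes", "annotations"),
  preprocess = c("sd_denominator", "max_missing_frac"),
  ordering = c("method", "anchor", "linkage", "distance", "top_k"),
  plot = c("format", "alpha", "size_mode", "cap_sig", "radius_range",
           "barscatter_outcome"))

.checkKeys <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad))
    stop("unknown configuration key(s) in '", where, "': ",
         paste(bad, collapse = ", "), call. = FALSE)
}

#' Validate a pipeline configuration
#'
#' Checks a configuration list (or YAML file) against the strict schema:
#' unknown keys are rejected, the study source must be either a synthetic
#' design or a triple of existing input files, and option values are
#' normalized with their defaults filled in. Validation happens before any
#' compute, so a broken config fails fast.
#'
#' @param config path to a YAML file, or the equivalent nested list.
#' @return the normalized configuration list.
#' @export
validateRunConfig <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop("config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  .checkKeys(config, .configSchema$top, "config")
  if (is.null(config$study))
    stop("config requires a 'study' section", call. = FALSE)
  .checkKeys(config$study, .configSchema$study, "study")
  if (!xor(is.null(config$study$synth), is.null(config$study$files)))
    stop("'study' must contain exactly one of 'synth' or 'files'",
         call. = FALSE)
  if (!is.null(config$study$synth))
    .checkKeys(config$study$synth, .configSchema$synth, "study.synth")
  if (!is.null(config$study$files)) {
    .checkKeys(config$study$files, .configSchema$files, "study.files")
    for (k in c("abundance", "phenotypes", "annotations")) {
      p <- config$study$files[[k]]
      if (is.null(p))
        stop("study.files requires '", k, "'", call. = FALSE)
      if (!file.exists(p))
        stop("study.files.", k, ": file not found: ", p, call. = FALSE)
    }
  }
  for (sec in c("preprocess", "ordering", "plot"))
    if (!is.null(config[[sec]]))
      .checkKeys(config[[sec]], .configSchema[[sec]], sec)
  config$seed <- as.integer(config$seed %||% 1L)
  config$out_dir <- config$out_dir %||% "."
  pp <- config$preprocess %||% list()
  config$preprocess <- list(
    sd_denominator = pp$sd_denominator %||% "n-1",
    max_missing_frac = pp$max_missing_frac)
  od <- config$ordering %||% list()
  config$ordering <- list(
    method = od$method %||% "pvalue",
    anchor = od$anchor,
    linkage = od$linkage %||% "average",
    distance = od$distance %||% "euclidean",
    top_k = od$top_k %||% 50)
  pl <- config$plot %||% list()
  config$plot <- list(
    format = pl$format %||% "svg",
    alpha = pl$alpha %||% 0.05,
    size_mode = pl$size_mode %||% "radius",
    cap_sig = pl$cap_sig,
    radius_range = unlist(pl$radius_range) %||% c(0.08, 0.45),
    barscatter_outcome = pl$barscatter_outcome)
  config
}

.panelFromConfig <- function(panel) {
  if (is.null(panel) || identical(panel, "default")) return(framinghamPanel())
  ModelPanel(lapply(panel, function(s)
    ModelSpec(s$outcome, s$family %||% "linear",
              covariates = unlist(s$covariates) %||% character(),
              displayIndex = as.integer(s$display_index))))
}

.studyFromConfig <- function(config) {
  if (!is.null(config$study$synth)) {
    sy <- config$study$synth
    if (identical(sy$preset, "cohort_shape")) {
      design <- fixtureCohortShape(seed = as.integer(sy$seed %||% config$seed))
    } else {
      design <- SyntheticDesign(
        nSamples = as.integer(sy$n_samples %||% 300L),
        nMetabolites = as.integer(sy$n_metabolites %||% 100L),
        mzRange = unlist(sy$mz_range) %||% c(225, 650),
        missingRate = sy$missing_rate %||% 0.05,
        missingMode = sy$missing_mode %||% "mcar",
        noiseSd = sy$noise_sd %||% 1,
        panel = .panelFromConfig(config$panel),
        seed = as.integer(sy$seed %||% config$seed))
    }
    generateStudy(design)
  } else {
    f <- config$study$files
    MetaboliteStudy(readAbundance(f$abundance),
                    readPhenotypes(f$phenotypes),
                    readAnnotations(f$annotations))
  }
}

#' Run the full matrix-to-figures pipeline
#'
#' Executes, in order: study acquisition (synthetic generation or file
#' reading), preprocessing (impute, log, standardize), per-model
#' association fitting over the panel, top-k selection and row ordering,
#' and rendering of all four figure types (rain plot, faceted Manhattan,
#' paired heatmaps, bar-and-scatter). Writes `grid.csv` (the full
#' association grid), `grid_top.csv` (the displayed selection), the four
#' figures, and `manifest.json` recording package/R versions, the seed,
#' input hashes and output checksums. A stage failure halts with the stage
#' named and removes partial outputs.
#'
#' @param config a config path or list; see [validateRunConfig()].
#' @return named character vector of output paths, invisibly.
#' @export
runPipeline <- function(config) {
  config <- validateRunConfig(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(written)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  out <- function(f) file.path(config$out_dir, f)

  study <- stage("study", .studyFromConfig(config))
  panel <- if (!is.null(config$study$synth))
    metadata(study)$design@panel else .panelFromConfig(config$panel)

  study <- stage("preprocess", preprocessStudy(
    study, sdDenominator = config$preprocess$sd_denominator,
    maxMissingFrac = config$preprocess$max_missing_frac))

  grid <- stage("associate",
                suppressMessages(buildGrid(study, panel = panel,
                                           skipFailures = TRUE)))
  gridPath <- out("grid.csv")
  stage("write_grid", writeAssociationGrid(grid, gridPath))
  written <- c(written, gridPath)

  ospec <- OrderingSpec(
    method = config$ordering$method,
    pvalueSummary = if (is.null(config$ordering$anchor))
      "min_across_outcomes" else "anchor_outcome",
    anchor = config$ordering$anchor %||% NA_character_,
    linkage = config$ordering$linkage,
    distance = config$ordering$distance)
  shown <- stage("order", {
    g <- selectTopK(grid, k = config$ordering$top_k, spec = ospec)
    list(grid = g, order = orderMetabolites(g, ospec))
  })

  fmt <- config$plot$format
  figs <- c(rain = out(paste0("rain.", fmt)),
            manhattan = out(paste0("manhattan.", fmt)),
            heatmap_pair = out(paste0("heatmap_pair.", fmt)),
            barscatter = out(paste0("barscatter.", fmt)))
  stage("plot", suppressWarnings({
    renderPlot(buildRainPlotModel(
      shown$grid, rowOrder = shown$order,
      radiusRange = config$plot$radius_range,
      cap = config$plot$cap_sig,
      sizeMode = config$plot$size_mode), figs["rain"])
    renderPlot(buildManhattanModel(grid, alpha = config$plot$alpha),
               figs["manhattan"])
    renderPlot(buildPairedHeatmapModel(
      shown$grid, rowOrder = shown$order, cap = config$plot$cap_sig),
      figs["heatmap_pair"])
    bo <- config$plot$barscatter_outcome %||% outcomeNames(panel)[1]
    renderPlot(buildBarScatterModel(shown$grid, bo, rowOrder = shown$order),
               figs["barscatter"])
  }))
  written <- c(written, figs)

  topPath <- out("grid_top.csv")
  stage("write_top", writeAssociationGrid(shown$grid, topPath))
  written <- c(written, topPath)

  manifestPath <- out("manifest.json")
  stage("manifest", {
    inputs <- if (!is.null(config$study$files))
      lapply(config$study$files, function(p) unname(tools::md5sum(p)))
    else list(synthetic_seed = metadata(study)$design@seed)
    manifest <- list(
      package = "MetaboRain",
      package_version = as.character(packageVersion("MetaboRain")),
      r_version = paste(R.version$major, R.version$minor, sep = "."),
      seed = config$seed,
      inputs = inputs,
      outputs = as.list(vapply(written, function(p)
        unname(tools::md5sum(p)), character(1))))
    jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                         pretty = TRUE)
  })
  written <- c(written, manifest = manifestPath)
  invisible(c(grid = gridPath, figs, grid_top = topPath,
              manifest = manifestPath))
}
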