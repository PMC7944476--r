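# Pull a value out of a nested config list with a default.
cfgGet <- function(cfg, path, default = NULL) {
  for (k in path) {
    if (is.null(cfg) || is.null(cfg[[k]])) return(default)
    cfg <- cfg[[k]]
  }
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors the pipeline stages: a mandatory `seed`, exactly one
#' input source (`input$synthetic` with [cohortConfig()] fields, or
#' `input$directory` with a cohort written by [writeCohort()]), and optional
#' `preprocess`, `split`, `train` and `unmix` blocks.
#'
#' @param path YAML file path.
#' @return named list (validated by [runPipeline()]).
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path))
    nrStop(paste0("config file not found: ", path), "nrConfigError")
  cfg <- tryCatch(yaml::read_yaml(path),
                  error = function(e) nrStop(paste0("cannot parse YAML: ",
                                                    conditionMessage(e)),
                                             "nrParseError"))
  cfg
}

validatePipelineConfig <- function(cfg) {
  if (is.null(cfg$seed)) nrStop("config must state a seed", "nrConfigError")
  hasSynth <- !is.null(cfgGet(cfg, c("input", "synthetic")))
  hasDir <- !is.null(cfgGet(cfg, c("input", "directory")))
  if (hasSynth == hasDir)
    nrStop("config must name exactly one input source: input$synthetic or input$directory",
           "nrConfigError")
  invisible(cfg)
}

#' Default demonstration pipeline configuration
#'
#' A small synthetic two-class run (control vs sTBI, cardiolipin at 50% of
#' control) sized to execute in seconds.
#'
#' @param seed integer seed.
#' @return config list accepted by [runPipeline()].
#' @export
demoPipelineConfig <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    input = list(synthetic = list(
      nPerClass = 10L,
      classes = c("control", "sTBI"),
      nAccumulations = 5L,
      noiseSD = 0.01,
      spikeRate = 0.2,
      axis = list(from = 600, to = 1800, by = 2)
    )),
    train = list(gridWidth = 8L, gridHeight = 8L, nEpochs = 50L,
                 normalization = "vector"),
    split = list(trainFraction = 0.7)
  )
}

# Build a CohortConfig from the input$synthetic block.
synthConfigFromList <- function(sc) {
  classes <- cfgGet(sc, "classes",
                    rownames(defaultMeanCoefficients()))
  mc <- cfgGet(sc, "meanCoefficients")
  if (is.null(mc)) {
    full <- defaultMeanCoefficients()
    missing <- setdiff(classes, rownames(full))
    if (length(missing))
      nrStop(paste0("no default coefficients for class(es): ",
                    paste(missing, collapse = ", ")), "nrConfigError")
    mc <- full[classes, , drop = FALSE]
  } else if (is.list(mc)) {
    mc <- mc[classes]
  }
  cohortConfig(
    nPerClass = cfgGet(sc, "nPerClass", 20L),
    classNames = classes,
    meanCoefficients = mc,
    coefficientCV = cfgGet(sc, "coefficientCV", 0.15),
    baselineAmplitude = cfgGet(sc, "baselineAmplitude", 0.5),
    baselineDecay = cfgGet(sc, "baselineDecay", 700),
    baselineCurvature = cfgGet(sc, "baselineCurvature", 0.3),
    noiseSD = cfgGet(sc, "noiseSD", 0.01),
    noiseModel = cfgGet(sc, "noiseModel", "gaussian"),
    spikeRate = cfgGet(sc, "spikeRate", 0.2),
    nAccumulations = cfgGet(sc, "nAccumulations", 15L),
    seed = cfgGet(sc, "seed", 1L))
}

writeMatrixCSV <- function(axis, mat, path, firstCol = "wavenumber") {
  dat <- data.frame(axis, mat, check.names = FALSE)
  colnames(dat)[1] <- firstCol
  utils::write.csv(dat, path, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes generate/read, preprocessing, a stratified train/test split, SOM
#' training, held-out classification, SOMDI computation, NNLS unmixing of
#' every sample and group-level ANOVA, writing all artifacts plus a JSON
#' report and a manifest with per-file MD5 checksums. Identical config and
#' seed yield identical checksums.
#'
#' @param config config list or path to a YAML file
#'   (see [readPipelineConfig()]).
#' @param outDir output directory; overrides `config$output`.
#' @return invisibly, the manifest list (also written as `manifest.json`).
#' @export
runPipeline <- function(config, outDir = NULL) {
  if (is.character(config)) config <- readPipelineConfig(config)
  validatePipelineConfig(config)
  seed <- as.integer(config$seed)
  outDir <- outDir %||% cfgGet(config, "output")
  if (is.null(outDir)) nrStop("no output directory given", "nrConfigError")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  logLine <- function(stage, event, value = "") {
    message(sprintf("[%s] %s %s", stage, event, value))
  }

  # --- input -----------------------------------------------------------
  sc <- cfgGet(config, c("input", "synthetic"))
  if (!is.null(sc)) {
    if (is.null(sc$seed)) sc$seed <- seed
    axisSpec <- cfgGet(sc, "axis")
    axis <- if (is.null(axisSpec)) defaultAxis() else
      seq(axisSpec$from, axisSpec$to, by = axisSpec$by %||% 1)
    library <- defaultComponentLibrary(axis)
    cohort <- generateCohort(synthConfigFromList(sc), library)
    logLine("input", "generated synthetic cohort", ncol(cohort))
  } else {
    cohort <- readCohortDir(cfgGet(config, c("input", "directory")))
    library <- defaultComponentLibrary(wavenumbers(cohort))
    logLine("input", "read cohort", ncol(cohort))
  }

  # --- preprocess ------------------------------------------------------
  pp <- preprocessConfig(
    spikeThreshold = cfgGet(config, c("preprocess", "spikeThreshold"), 8),
    baselineNodes = cfgGet(config, c("preprocess", "baselineNodes"), 11L),
    baselineIterations = cfgGet(config, c("preprocess", "baselineIterations"), 20L),
    normalization = cfgGet(config, c("preprocess", "normalization"), "none"))
  processed <- preprocessCohort(cohort, pp)
  logLine("preprocess", "spikes replaced",
          sum(S4Vectors::metadata(processed)$spikeCounts))
  axis <- wavenumbers(processed)
  S <- spectraMatrix(processed)
  files <- c(files, writeMatrixCSV(axis, S,
                                   file.path(outDir, "processed_spectra.csv")))
  labels <- classLabels(processed)
  labPath <- file.path(outDir, "labels.csv")
  utils::write.csv(data.frame(sample_id = colnames(S), class = labels),
                   labPath, row.names = FALSE)
  files <- c(files, labPath)

  # --- split + train ---------------------------------------------------
  split <- stratifiedSplit(labels,
                           cfgGet(config, c("split", "trainFraction"), 0.7),
                           seed = seed)
  somNorm <- cfgGet(config, c("train", "normalization"), "vector")
  Sn <- normalizeColumns(S, axis, somNorm)
  tc <- somTrainConfig(
    gridWidth = cfgGet(config, c("train", "gridWidth"), 10L),
    gridHeight = cfgGet(config, c("train", "gridHeight"), 10L),
    nEpochs = cfgGet(config, c("train", "nEpochs"), 100L),
    init = cfgGet(config, c("train", "init"), "random-sample"),
    distance = cfgGet(config, c("train", "distance"), "euclidean"),
    seed = seed)
  model <- trainSOM(Sn[, split$train, drop = FALSE], labels[split$train],
                    config = tc, axis = axis)
  logLine("train", "trained SOM", sprintf("%dx%d", tc@gridWidth, tc@gridHeight))
  modelPath <- file.path(outDir, "model.json")
  saveSOMModel(model, modelPath)
  files <- c(files, modelPath)
  mapPath <- file.path(outDir, "map.csv")
  utils::write.csv(somGridSummary(model), mapPath, row.names = FALSE)
  files <- c(files, mapPath)

  # --- classify held-out samples --------------------------------------
  pred <- classifySpectra(model, Sn[, split$test, drop = FALSE])
  truth <- labels[split$test]
  acc <- mean(pred$class == truth)
  perClass <- vapply(model@classNames, function(cl) {
    idx <- truth == cl
    if (any(idx)) mean(pred$class[idx] == cl) else NA_real_
  }, numeric(1))
  confusion <- table(truth = truth, predicted = pred$class)
  logLine("classify", "held-out accuracy", sprintf("%.3f", acc))
  predPath <- file.path(outDir, "predictions.csv")
  utils::write.csv(data.frame(sample_id = colnames(S)[split$test],
                              truth = truth, predicted = pred$class,
                              confidence = pred$confidence),
                   predPath, row.names = FALSE)
  files <- c(files, predPath)

  # --- SOMDI -----------------------------------------------------------
  somdi <- computeSOMDI(model)
  somdiPath <- file.path(outDir, "somdi.csv")
  files <- c(files, writeMatrixCSV(somdi@axis, somdi@discriminants, somdiPath))
  topBands <- lapply(model@classNames, function(cl)
    somdiPeaks(somdi, cl, n = 5L))
  names(topBands) <- model@classNames

  # --- unmix + group statistics ---------------------------------------
  unmix <- unmixCohort(processed, library,
                       includeOffset = cfgGet(config, c("unmix", "includeOffset"), TRUE))
  coefPath <- file.path(outDir, "coefficients.csv")
  utils::write.csv(unmix, coefPath, row.names = FALSE)
  files <- c(files, coefPath)
  comparison <- tryCatch(
    groupCompare(unmix, cfgGet(config, c("unmix", "correction"), "none")),
    nrError = function(e) NULL)
  if (!is.null(comparison)) {
    gsPath <- file.path(outDir, "group_stats.csv")
    utils::write.csv(comparisonStats(comparison), gsPath, row.names = FALSE)
    files <- c(files, gsPath)
  }

  # --- report ----------------------------------------------------------
  coefSummary <- lapply(unique(unmix$component), function(cmp) {
    sub <- unmix[unmix$component == cmp, ]
    list(component = cmp,
         byClass = lapply(stats::setNames(nm = unique(labels)), function(cl) {
           v <- sub$coefficient[sub$class == cl]
           list(mean = mean(v), sd = stats::sd(v),
                median = stats::median(v),
                q25 = unname(stats::quantile(v, 0.25)),
                q75 = unname(stats::quantile(v, 0.75)))
         }))
  })
  report <- list(
    seed = seed,
    nSamples = ncol(S),
    classes = unique(labels),
    accuracy = acc,
    perClassAccuracy = as.list(perClass),
    confusion = as.data.frame(confusion),
    topSomdiBands = topBands,
    coefficients = coefSummary,
    anova = if (!is.null(comparison)) comparisonStats(comparison) else NULL)
  reportPath <- file.path(outDir, "report.json")
  jsonlite::write_json(report, reportPath, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  files <- c(files, reportPath)

  # --- manifest --------------------------------------------------------
  cfgTmp <- tempfile(fileext = ".json")
  jsonlite::write_json(config, cfgTmp, digits = NA, auto_unbox = TRUE)
  configHash <- unname(tools::md5sum(cfgTmp))
  unlink(cfgTmp)
  manifest <- list(
    package = "neuroraman",
    version = as.character(utils::packageVersion("neuroraman")),
    seed = seed,
    configHash = configHash,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    files = lapply(stats::setNames(nm = basename(files)), function(f)
      unname(tools::md5sum(file.path(outDir, f)))))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
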