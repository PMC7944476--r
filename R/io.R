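#' Read a spectrum from CSV or JCAMP-DX
#'
#' CSV: two numeric columns (wavenumber, intensity), comma-separated, dot
#' decimal; a header line is auto-detected. JCAMP-DX: `##XYDATA=(XY..XY)`
#' pairs or `(X++(Y..Y))` tables in plain (AFFN) form, honouring
#' `XFACTOR`/`YFACTOR`. A descending axis is re-sorted ascending (with its
#' intensities) with a warning.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"csv"` or `"jcamp"`.
#' @return a [RamanSpectrum-class].
#' @export
readSpectrum <- function(path, format = c("auto", "csv", "jcamp")) {
  format <- match.arg(format)
  if (!file.exists(path))
    nrStop(paste0("file not found: ", path), "nrParseError")
  if (format == "auto") {
    format <- if (grepl("\\.(jdx|dx|jcm|jcamp)$", tolower(path))) "jcamp" else "csv"
  }
  sp <- if (format == "csv") readSpectrumCSV(path) else readJCAMP(path)
  if (length(sp$axis) > 1 && all(diff(sp$axis) < 0)) {
    warning("descending wavenumber axis re-sorted ascending")
    ord <- order(sp$axis)
    sp$axis <- sp$axis[ord]
    sp$intensity <- sp$intensity[ord]
  }
  if (!isStrictlyIncreasing(sp$axis)) {
    ord <- order(sp$axis)
    sp$axis <- sp$axis[ord]
    sp$intensity <- sp$intensity[ord]
    if (!isStrictlyIncreasing(sp$axis))
      nrStop(paste0("axis is not strictly increasing in ", path), "nrParseError")
  }
  ramanSpectrum(sp$axis, sp$intensity)
}

readSpectrumCSV <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) nrStop(paste0("empty file: ", path), "nrParseError")
  start <- 1L
  first <- strsplit(lines[1], ",")[[1]]
  if (any(is.na(suppressWarnings(as.numeric(first))))) start <- 2L  # header
  if (start > length(lines))
    nrStop(paste0("no data rows in ", path), "nrParseError")
  ax <- numeric(0); y <- numeric(0)
  for (i in start:length(lines)) {
    parts <- strsplit(lines[i], ",")[[1]]
    if (length(parts) < 2L)
      nrStop(sprintf("line %d of %s: expected two comma-separated values", i, path),
             "nrParseError")
    vals <- suppressWarnings(as.numeric(parts[1:2]))
    if (anyNA(vals))
      nrStop(sprintf("line %d of %s: non-numeric value", i, path), "nrParseError")
    ax <- c(ax, vals[1]); y <- c(y, vals[2])
  }
  list(axis = ax, intensity = y)
}

#' Write a spectrum to CSV or JCAMP-DX
#'
#' @param spectrum a [RamanSpectrum-class].
#' @param path output file path.
#' @param format `"csv"` or `"jcamp"`.
#' @param title title string for JCAMP-DX headers.
#' @return invisibly, the path.
#' @export
writeSpectrum <- function(spectrum, path, format = c("csv", "jcamp"),
                          title = "neuroraman spectrum") {
  stopifnot(is(spectrum, "RamanSpectrum"))
  format <- match.arg(format)
  if (format == "csv") {
    writeLines(c("wavenumber,intensity",
                 sprintf("%.10g,%.10g", spectrum@axis, spectrum@intensity)),
               path)
  } else {
    writeJCAMP(spectrum, path, title)
  }
  invisible(path)
}

writeJCAMP <- function(spectrum, path, title) {
  ax <- spectrum@axis; y <- spectrum@intensity
  hdr <- c(
    paste0("##TITLE=", title),
    "##JCAMP-DX=4.24",
    "##DATA TYPE=RAMAN SPECTRUM",
    "##XUNITS=1/CM",
    "##YUNITS=ARBITRARY UNITS",
    sprintf("##FIRSTX=%.10g", ax[1]),
    sprintf("##LASTX=%.10g", ax[length(ax)]),
    sprintf("##NPOINTS=%d", length(ax)),
    "##XFACTOR=1",
    "##YFACTOR=1",
    "##XYDATA=(XY..XY)")
  body <- sprintf("%.10g, %.10g", ax, y)
  writeLines(c(hdr, body, "##END="), path)
}

readJCAMP <- function(path) {
  lines <- readLines(path, warn = FALSE)
  xf <- 1; yf <- 1
  grab <- function(key) {
    hit <- grep(paste0("^##\\s*", key, "\\s*="), lines, ignore.case = TRUE,
                value = TRUE)
    if (!length(hit)) return(NA_real_)
    suppressWarnings(as.numeric(sub("^##[^=]*=", "", hit[1])))
  }
  if (!is.na(v <- grab("XFACTOR"))) xf <- v
  if (!is.na(v <- grab("YFACTOR"))) yf <- v
  start <- grep("^##\\s*XYDATA", lines, ignore.case = TRUE)
  if (!length(start))
    nrStop(paste0("no ##XYDATA block in ", path), "nrParseError")
  form <- toupper(lines[start[1]])
  end <- grep("^##", lines)
  end <- end[end > start[1]]
  end <- if (length(end)) min(end) - 1L else length(lines)
  body <- lines[(start[1] + 1L):end]
  body <- body[nzchar(trimws(body))]
  if (grepl("XY\\.\\.XY", form)) {
    parts <- strsplit(trimws(body), "[,;[:space:]]+")
    ax <- numeric(0); y <- numeric(0)
    for (i in seq_along(parts)) {
      v <- suppressWarnings(as.numeric(parts[[i]]))
      if (anyNA(v) || length(v) %% 2L != 0L)
        nrStop(sprintf("line %d of %s: malformed XY pair", start[1] + i, path),
               "nrParseError")
      ax <- c(ax, v[seq(1, length(v), by = 2)])
      y <- c(y, v[seq(2, length(v), by = 2)])
    }
  } else {
    # (X++(Y..Y)): first number of each line is X, the rest are consecutive Y
    ax <- numeric(0); y <- numeric(0)
    dx <- NA_real_
    firstx <- grab("FIRSTX"); lastx <- grab("LASTX"); np <- grab("NPOINTS")
    if (!is.na(firstx) && !is.na(lastx) && !is.na(np) && np > 1)
      dx <- (lastx - firstx) / (np - 1)
    for (i in seq_along(body)) {
      v <- suppressWarnings(as.numeric(strsplit(trimws(body[i]), "[,;[:space:]]+")[[1]]))
      if (anyNA(v) || length(v) < 2L)
        nrStop(sprintf("line %d of %s: malformed X++(Y..Y) row", start[1] + i, path),
               "nrParseError")
      x0 <- v[1]; ys <- v[-1]
      step <- if (!is.na(dx)) dx else 1
      ax <- c(ax, x0 + step * (seq_along(ys) - 1L))
      y <- c(y, ys)
    }
  }
  list(axis = ax * xf, intensity = y * yf)
}

#' Write a cohort to disk as plain CSV
#'
#' One CSV per sample (first column wavenumber, then one column per
#' accumulation or the preprocessed spectrum), a `labels.csv`
#' (sample_id, class) and, for synthetic cohorts, a `truth.csv`
#' (sample_id, component, coefficient).
#'
#' @param cohort a [RamanCohort-class].
#' @param dir output directory (created if missing).
#' @return invisibly, the vector of files written.
#' @export
writeCohort <- function(cohort, dir) {
  stopifnot(is(cohort, "RamanCohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  axis <- wavenumbers(cohort)
  cd <- SummarizedExperiment::colData(cohort)
  ids <- cd$sample_id
  an <- SummarizedExperiment::assayNames(cohort)
  files <- character(0)
  for (s in seq_len(ncol(cohort))) {
    dat <- data.frame(wavenumber = axis)
    for (a in an) dat[[a]] <- SummarizedExperiment::assay(cohort, a)[, s]
    f <- file.path(dir, paste0(ids[s], ".csv"))
    utils::write.csv(dat, f, row.names = FALSE)
    files <- c(files, f)
  }
  f <- file.path(dir, "labels.csv")
  utils::write.csv(data.frame(sample_id = ids, class = cd$class), f,
                   row.names = FALSE)
  files <- c(files, f)
  tr <- truthCoefficients(cohort)
  if (!is.null(tr)) {
    long <- data.frame(
      sample_id = rep(rownames(tr), times = ncol(tr)),
      component = rep(colnames(tr), each = nrow(tr)),
      coefficient = as.numeric(tr))
    f <- file.path(dir, "truth.csv")
    utils::write.csv(long, f, row.names = FALSE)
    files <- c(files, f)
  }
  invisible(files)
}

#' Read a cohort from a directory of per-sample CSVs
#'
#' Expects the layout written by [writeCohort()]: per-sample CSVs whose
#' first column is the wavenumber axis, and a `labels.csv`.
#'
#' @param dir directory path.
#' @return a [RamanCohort-class].
#' @export
readCohortDir <- function(dir) {
  labPath <- file.path(dir, "labels.csv")
  if (!file.exists(labPath))
    nrStop(paste0("labels.csv not found in ", dir), "nrParseError")
  labels <- utils::read.csv(labPath, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "class") %in% colnames(labels)))
    nrStop("labels.csv must have sample_id and class columns", "nrParseError")
  axis <- NULL
  mats <- NULL
  for (s in seq_len(nrow(labels))) {
    f <- file.path(dir, paste0(labels$sample_id[s], ".csv"))
    if (!file.exists(f))
      nrStop(paste0("missing sample file: ", f), "nrParseError")
    dat <- utils::read.csv(f)
    if (is.null(axis)) {
      axis <- dat[[1]]
      nCols <- ncol(dat) - 1L
      mats <- lapply(seq_len(nCols), function(a)
        matrix(0, length(axis), nrow(labels)))
      names(mats) <- colnames(dat)[-1]
    }
    if (!isTRUE(all.equal(dat[[1]], axis)))
      nrStop(paste0("axis mismatch in ", f), "nrParseError")
    for (a in seq_along(mats)) mats[[a]][, s] <- dat[[a + 1L]]
  }
  for (a in seq_along(mats)) colnames(mats[[a]]) <- labels$sample_id
  cd <- S4Vectors::DataFrame(sample_id = labels$sample_id,
                             class = labels$class)
  trPath <- file.path(dir, "truth.csv")
  if (file.exists(trPath)) {
    tr <- utils::read.csv(trPath, stringsAsFactors = FALSE)
    for (cmp in unique(tr$component)) {
      sub <- tr[tr$component == cmp, ]
      cd[[paste0("truth_", cmp)]] <-
        sub$coefficient[match(labels$sample_id, sub$sample_id)]
    }
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = mats,
    rowData = S4Vectors::DataFrame(wavenumber = axis),
    colData = cd)
  new("RamanCohort", se)
}

#' Persist a trained SOM model as JSON
#'
#' A single self-describing JSON archive holding the axis, neuron weights,
#' label weights, class names, grid geometry, training configuration and
#' seed; round-trips through [readSOMModel()].
#'
#' @param model a [SOMModel-class].
#' @param path output path.
#' @return invisibly, the path.
#' @export
saveSOMModel <- function(model, path) {
  stopifnot(is(model, "SOMModel"))
  obj <- list(
    format = "neuroraman-som", version = 1L,
    gridWidth = model@gridWidth, gridHeight = model@gridHeight,
    classNames = model@classNames, axis = model@axis,
    weights = model@weights, labelWeights = unname(model@labelWeights),
    trainedIterations = model@trainedIterations,
    config = model@config, seed = model@seed)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Read a SOM model written by [saveSOMModel()]
#' @param path JSON path.
#' @return a [SOMModel-class].
#' @export
readSOMModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "neuroraman-som"))
    nrStop(paste0("not a neuroraman SOM archive: ", path), "nrParseError")
  m <- obj$gridWidth * obj$gridHeight
  asMat <- function(x) if (is.matrix(x)) x else matrix(unlist(x), nrow = m, byrow = TRUE)
  W <- asMat(obj$weights)
  L <- asMat(obj$labelWeights)
  colnames(L) <- obj$classNames
  new("SOMModel",
      gridWidth = as.integer(obj$gridWidth),
      gridHeight = as.integer(obj$gridHeight),
      coords = hexGridCoords(obj$gridWidth, obj$gridHeight),
      weights = W, labelWeights = L, classNames = obj$classNames,
      axis = as.numeric(obj$axis),
      trainedIterations = as.integer(obj$trainedIterations),
      config = as.list(obj$config), seed = as.integer(obj$seed))
}
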