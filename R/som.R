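#' SOM training configuration
#'
#' @param gridWidth,gridHeight hexagonal grid dimensions (neurons).
#' @param nEpochs passes over the training set; each pass presents every
#'   training spectrum once in a fresh seeded random order.
#' @param learningRate length-2 numeric: initial and final learning rate of
#'   the exponential decay schedule.
#' @param radius length-2 numeric: initial and final neighbourhood radius in
#'   hex distance units; defaults to half the larger grid dimension decaying
#'   to 1.
#' @param init `"random-sample"` (seeded sample of training spectra) or
#'   `"pca-span"` (grid spanning the first two principal components).
#' @param distance `"euclidean"` (default) or `"cosine"`.
#' @param seed integer random seed.
#' @return a [SOMTrainConfig-class].
#' @export
somTrainConfig <- function(gridWidth = 10L, gridHeight = 10L, nEpochs = 100L,
                           learningRate = c(0.5, 0.01), radius = NULL,
                           init = "random-sample", distance = "euclidean",
                           seed = 1L) {
  if (is.null(radius))
    radius <- c(max(gridWidth, gridHeight) / 2, 1)
  new("SOMTrainConfig",
      gridWidth = as.integer(gridWidth), gridHeight = as.integer(gridHeight),
      nEpochs = as.integer(nEpochs), learningRate = as.numeric(learningRate),
      radius = as.numeric(radius), init = init, distance = distance,
      seed = as.integer(seed))
}

# Axial (q, r) coordinates of a pointy-top hex grid laid out row-major from
# rectangular (col, row) offset coordinates (odd-r shifted).
hexGridCoords <- function(width, height) {
  r <- rep(seq_len(height) - 1L, each = width)
  c0 <- rep(seq_len(width) - 1L, times = height)
  cbind(q = c0 - r %/% 2L, r = r)
}

#' Hexagonal grid distance
#'
#' Length of the shortest path between two hexes in axial (q, r)
#' coordinates on a pointy-top hexagonal grid.
#'
#' @param coordA,coordB length-2 integer vectors of axial (q, r) coordinates.
#' @return integer grid distance.
#' @examples
#' hexDistance(c(0, 0), c(2, -1))
#' @export
hexDistance <- function(coordA, coordB) {
  if (length(coordA) != 2L || length(coordB) != 2L ||
      anyNA(coordA) || anyNA(coordB) ||
      any(coordA != round(coordA)) || any(coordB != round(coordB)))
    nrStop("coordinates must be length-2 integer axial (q, r) pairs")
  dq <- coordA[1] - coordB[1]
  dr <- coordA[2] - coordB[2]
  as.integer((abs(dq) + abs(dr) + abs(dq + dr)) / 2)
}

# All pairwise hex distances between the rows of a coordinate matrix.
hexDistanceMatrix <- function(coords) {
  dq <- outer(coords[, 1], coords[, 1], "-")
  dr <- outer(coords[, 2], coords[, 2], "-")
  (abs(dq) + abs(dr) + abs(dq + dr)) / 2
}

# Extract a (samples x channels) matrix plus axis and labels from the
# accepted spectra inputs.
somInputs <- function(x, labels = NULL) {
  if (is(x, "RamanCohort")) {
    mat <- t(spectraMatrix(x))
    axis <- wavenumbers(x)
    if (is.null(labels)) labels <- classLabels(x)
  } else if (is(x, "RamanSpectrum")) {
    mat <- matrix(x@intensity, nrow = 1)
    axis <- x@axis
  } else if (is.matrix(x)) {
    # columns are samples (as in SummarizedExperiment assays)
    mat <- t(x)
    axis <- numeric(0)
  } else nrStop("spectra must be a RamanCohort, RamanSpectrum or matrix")
  if (anyNA(mat)) nrStop("spectra must not contain NA")
  list(mat = mat, axis = axis, labels = labels)
}

#' Train a hexagonal self-organizing map with class labels
#'
#' Online Kohonen training: per step one training spectrum is presented, its
#' best-matching unit (BMU) found by Euclidean (or cosine) distance, and the
#' weights of the BMU and its hex neighbourhood are moved toward the
#' spectrum under a Gaussian neighbourhood kernel with exponentially
#' decaying learning rate and radius. Per-neuron class-label vectors are
#' co-trained with the same kernel toward the sample's one-hot class vector,
#' providing the supervised labelling used for classification and for the
#' SOM discriminant index. Deterministic given the config seed.
#'
#' @param x spectra: a preprocessed [RamanCohort-class], or a numeric matrix
#'   with one column per sample (rows are wavenumber channels). Spectra
#'   should be normalized (see [normalizeSpectrum()]) so distances compare
#'   shape, not intensity.
#' @param labels class label per sample; taken from the cohort when omitted.
#' @param config a [SOMTrainConfig-class].
#' @param axis optional wavenumber axis for matrix input.
#' @return a trained [SOMModel-class].
#' @export
trainSOM <- function(x, labels = NULL, config = somTrainConfig(), axis = NULL) {
  stopifnot(is(config, "SOMTrainConfig"))
  inp <- somInputs(x, labels)
  X <- inp$mat
  labels <- as.character(inp$labels)
  if (is.null(inp$labels) || !length(labels))
    nrStop("class labels are required for training")
  if (length(labels) != nrow(X))
    nrStop("labels length must equal the number of spectra")
  if (!is.null(axis)) inp$axis <- as.numeric(axis)
  if (length(inp$axis) && length(inp$axis) != ncol(X))
    nrStop("axis length must match the number of channels")
  classNames <- unique(labels)
  if (any(table(labels) < 1L)) nrStop("every class needs at least one spectrum")

  m <- config@gridWidth * config@gridHeight
  n <- nrow(X)
  coords <- hexGridCoords(config@gridWidth, config@gridHeight)
  hexd <- hexDistanceMatrix(coords)

  set.seed(config@seed)
  W0 <- if (config@init == "random-sample") {
    X[sample.int(n, m, replace = n < m), , drop = FALSE]
  } else {
    pc <- stats::prcomp(X, center = TRUE, rank. = 2L)
    nPC <- ncol(pc$rotation)
    u <- scale(coords, center = TRUE, scale = FALSE)
    u <- sweep(u, 2, pmax(apply(abs(u), 2, max), 1), "/")
    span <- matrix(0, m, ncol(X))
    for (d in seq_len(min(2L, nPC)))
      span <- span + (u[, d] * pc$sdev[d]) %*% t(pc$rotation[, d])
    sweep(span, 2, colMeans(X), "+")
  }
  onehot <- outer(labels, classNames, "==") * 1.0
  order0 <- unlist(lapply(seq_len(config@nEpochs), function(e) sample.int(n)))

  res <- som_train_cpp(t(X), onehot, as.integer(order0 - 1L),
                       t(W0), matrix(0, m, length(classNames)), hexd,
                       config@learningRate[1], config@learningRate[2],
                       config@radius[1], config@radius[2],
                       config@distance == "cosine")
  res$weights <- t(res$weights)
  lw <- res$labelWeights
  lw[lw < 0] <- 0
  colnames(lw) <- classNames
  new("SOMModel",
      gridWidth = config@gridWidth, gridHeight = config@gridHeight,
      coords = coords, weights = res$weights, labelWeights = lw,
      classNames = classNames, axis = as.numeric(inp$axis),
      trainedIterations = length(order0),
      config = list(nEpochs = config@nEpochs,
                    learningRate = config@learningRate,
                    radius = config@radius, init = config@init,
                    distance = config@distance),
      seed = config@seed)
}

# Squared Euclidean (or cosine) distances from each spectrum (rows of S) to
# each neuron weight vector; returns samples x neurons.
neuronDistances <- function(model, S) {
  W <- model@weights
  if (identical(model@config$distance, "cosine")) {
    nw <- sqrt(rowSums(W^2))
    ns <- sqrt(rowSums(S^2))
    d <- 1 - (S %*% t(W)) / (outer(ns, nw))
    d[!is.finite(d)] <- 1
    d
  } else {
    outer(rowSums(S^2), rep(1, nrow(W))) - 2 * S %*% t(W) +
      outer(rep(1, nrow(S)), rowSums(W^2))
  }
}

#' Best-matching-unit coordinates of spectra
#'
#' Maps each spectrum to the neuron minimizing the model's distance; ties
#' are broken deterministically toward the lowest linear neuron index.
#'
#' @param model a trained [SOMModel-class].
#' @param x spectra (cohort, matrix with samples in columns, or single
#'   [RamanSpectrum-class]).
#' @return data.frame with columns `neuron` (1-based linear index), `q`, `r`
#'   (axial coordinates), one row per spectrum.
#' @export
mapPositions <- function(model, x) {
  stopifnot(is(model, "SOMModel"))
  inp <- somInputs(x)
  if (ncol(inp$mat) != ncol(model@weights))
    nrStop("spectra are not on the model's axis (channel count differs)")
  if (length(model@axis) && length(inp$axis) &&
      !isTRUE(all.equal(model@axis, inp$axis)))
    nrStop("spectra are not on the model's axis")
  D <- neuronDistances(model, inp$mat)
  bmu <- apply(D, 1, which.min)  # which.min takes the first (lowest index) min
  data.frame(neuron = bmu,
             q = model@coords[bmu, 1], r = model@coords[bmu, 2])
}

#' Classify spectra with a trained SOM
#'
#' Each spectrum is assigned the arg-max class of its best-matching unit's
#' label vector; the confidence is that class's normalized label weight.
#' Arg-max ties break toward the first-listed class.
#'
#' @param model a trained [SOMModel-class].
#' @param x spectra (cohort, matrix with samples in columns, or single
#'   [RamanSpectrum-class]).
#' @return data.frame with columns `class` and `confidence` (in \[0, 1\]).
#' @export
classifySpectra <- function(model, x) {
  stopifnot(is(model, "SOMModel"))
  if (model@trainedIterations < 1L)
    nrStop("model has not been trained", "nrStateError")
  pos <- mapPositions(model, x)
  lw <- model@labelWeights[pos$neuron, , drop = FALSE]
  idx <- apply(lw, 1, which.max)  # first max on ties
  tot <- rowSums(lw)
  conf <- ifelse(tot > 0,
                 lw[cbind(seq_len(nrow(lw)), idx)] / tot,
                 1 / length(model@classNames))
  data.frame(class = model@classNames[idx], confidence = conf)
}

#' Grid summary of a trained map
#'
#' Per-neuron axial coordinates, majority class and label weights, in the
#' shape used to draw cluster maps (each hexagon coloured by the class it
#' activates on).
#'
#' @param model a trained [SOMModel-class].
#' @return data.frame with columns `neuron`, `q`, `r`, `majorityClass` and
#'   one `weight_<class>` column per class.
#' @export
somGridSummary <- function(model) {
  stopifnot(is(model, "SOMModel"))
  lw <- model@labelWeights
  idx <- apply(lw, 1, which.max)
  maj <- ifelse(rowSums(lw) > 0, model@classNames[idx], NA_character_)
  out <- data.frame(neuron = seq_len(nrow(lw)),
                    q = model@coords[, 1], r = model@coords[, 2],
                    majorityClass = maj)
  for (k in seq_along(model@classNames))
    out[[paste0("weight_", model@classNames[k])]] <- lw[, k]
  out
}

setMethod("show", "SOMModel", function(object) {
  cat(sprintf("SOMModel: %dx%d hexagonal grid, %d-channel weights\n",
              object@gridWidth, object@gridHeight, ncol(object@weights)))
  cat(sprintf("  classes: %s | trained iterations: %d | seed: %d\n",
              paste(object@classNames, collapse = ", "),
              object@trainedIterations, object@seed))
  invisible(object)
})

#' @rdname neuroraman-generics
#' @export
setMethod("classLabels", "SOMModel", function(x) x@classNames)

#' @rdname neuroraman-generics
#' @export
setMethod("wavenumbers", "SOMModel", function(x) x@axis)
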