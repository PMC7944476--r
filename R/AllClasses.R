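#' A single Raman spectrum
#'
#' Holds one measurement: a strictly increasing wavenumber axis (cm^-1) and
#' intensity values (counts) of equal length.
#'
#' @slot axis numeric, strictly increasing wavenumbers in cm^-1.
#' @slot intensity numeric, same length as `axis`.
#' @exportClass RamanSpectrum
setClass("RamanSpectrum",
  slots = c(axis = "numeric", intensity = "numeric"),
  validity = function(object) {
    if (length(object@axis) != length(object@intensity))
      return("axis and intensity must have equal length")
    if (anyNA(object@axis) || anyNA(object@intensity))
      return("axis and intensity must not contain missing values")
    if (!isStrictlyIncreasing(object@axis))
      return("axis must be strictly increasing")
    TRUE
  }
)

#' Reference component spectra on a shared axis
#'
#' The unmixing basis: named, non-negative reference spectra (lipids,
#' protein, ...) evaluated on a common wavenumber grid. Components are stored
#' as the columns of a matrix.
#'
#' @slot axis numeric, strictly increasing wavenumbers in cm^-1.
#' @slot components numeric matrix, one column per named component, rows
#'   matching `axis`; all intensities >= 0.
#' @exportClass ComponentLibrary
setClass("ComponentLibrary",
  slots = c(axis = "numeric", components = "matrix"),
  validity = function(object) {
    if (!isStrictlyIncreasing(object@axis))
      return("axis must be strictly increasing")
    if (nrow(object@components) != length(object@axis))
      return("component vectors must match axis length")
    if (ncol(object@components) < 1L)
      return("library must contain at least one component")
    nm <- colnames(object@components)
    if (is.null(nm) || anyDuplicated(nm) || any(!nzchar(nm)))
      return("components must have unique non-empty names")
    if (any(object@components < 0))
      return("component intensities must be non-negative")
    TRUE
  }
)

#' Configuration for the synthetic cohort generator
#'
#' Describes the acquisition and biology the generator emulates: per-class
#' sample counts, per-class mean mixing coefficients of the library
#' components, between-sample coefficient variation, the smooth fluorescence
#' baseline, detector noise, cosmic-ray spike rate, and the number of raw
#' accumulations recorded per sample.
#'
#' @slot nPerClass integer, samples per class (>= 1).
#' @slot classNames character, unique class labels.
#' @slot meanCoefficients numeric matrix (classes x components) of
#'   non-negative mean mixing coefficients; dimnames give class and
#'   component names.
#' @slot coefficientCV numeric, between-sample coefficient of variation of
#'   the mixing coefficients.
#' @slot baselineAmplitude,baselineDecay,baselineCurvature numeric, amplitude
#'   (counts), exponential decay constant (cm^-1) and relative low-order
#'   curvature of the fluorescence background.
#' @slot noiseSD numeric >= 0, additive Gaussian noise standard deviation.
#' @slot noiseModel character, `"gaussian"` (default) or `"poisson"`.
#' @slot spikeRate numeric >= 0, expected cosmic-ray spikes per accumulation.
#' @slot nAccumulations integer >= 1, accumulations per sample.
#' @slot seed integer random seed.
#' @exportClass CohortConfig
setClass("CohortConfig",
  slots = c(
    nPerClass = "integer", classNames = "character",
    meanCoefficients = "matrix", coefficientCV = "numeric",
    baselineAmplitude = "numeric", baselineDecay = "numeric",
    baselineCurvature = "numeric", noiseSD = "numeric",
    noiseModel = "character", spikeRate = "numeric",
    nAccumulations = "integer", seed = "integer"
  ),
  validity = function(object) {
    if (object@nPerClass < 1L) return("nPerClass must be >= 1")
    if (anyDuplicated(object@classNames)) return("class names must be unique")
    if (nrow(object@meanCoefficients) != length(object@classNames))
      return("meanCoefficients must have one row per class")
    if (any(object@meanCoefficients < 0))
      return("mean coefficients must be non-negative")
    if (object@noiseSD < 0) return("noiseSD must be >= 0")
    if (object@spikeRate < 0) return("spikeRate must be >= 0")
    if (object@nAccumulations < 1L) return("nAccumulations must be >= 1")
    if (!object@noiseModel %in% c("gaussian", "poisson"))
      return("noiseModel must be 'gaussian' or 'poisson'")
    TRUE
  }
)

#' A labelled cohort of Raman measurements
#'
#' A [SummarizedExperiment::SummarizedExperiment] with wavenumbers in
#' `rowData(x)$wavenumber`, one column per sample, class labels in
#' `colData(x)$class`, and either raw accumulation stacks (assays
#' `acc01`, `acc02`, ...) or preprocessed spectra (assay `spectra`).
#' Synthetic cohorts additionally carry per-sample ground-truth mixing
#' coefficients in `colData` columns `truth_<component>` and the noiseless
#' clean spectra in `metadata(x)$clean`.
#'
#' @exportClass RamanCohort
setClass("RamanCohort",
  contains = "SummarizedExperiment",
  validity = function(object) {
    wn <- SummarizedExperiment::rowData(object)$wavenumber
    if (is.null(wn)) return("rowData must contain a 'wavenumber' column")
    if (!isStrictlyIncreasing(wn)) return("wavenumber must be strictly increasing")
    cl <- SummarizedExperiment::colData(object)$class
    if (is.null(cl)) return("colData must contain a 'class' column")
    TRUE
  }
)

#' Preprocessing configuration
#'
#' @slot spikeThreshold numeric > 0, robust z cutoff for cosmic-ray detection.
#' @slot baselineNodes integer >= 4, spline node count (default 11).
#' @slot baselineIterations integer, maximum re-weighting iterations.
#' @slot targetAxis numeric, resampling grid (strictly increasing), or
#'   length 0 to keep the native axis.
#' @slot normalization character, one of `"none"`, `"vector"`, `"area"`.
#' @exportClass PreprocessConfig
setClass("PreprocessConfig",
  slots = c(
    spikeThreshold = "numeric", baselineNodes = "integer",
    baselineIterations = "integer", targetAxis = "numeric",
    normalization = "character"
  ),
  validity = function(object) {
    if (object@spikeThreshold <= 0) return("spikeThreshold must be > 0")
    if (object@baselineNodes < 4L) return("baselineNodes must be >= 4")
    if (length(object@targetAxis) && !isStrictlyIncreasing(object@targetAxis))
      return("targetAxis must be strictly increasing")
    if (!object@normalization %in% c("none", "vector", "area"))
      return("normalization must be one of none/vector/area")
    TRUE
  }
)

#' SOM training configuration
#'
#' @slot gridWidth,gridHeight integer neuron counts of the hexagonal grid.
#' @slot nEpochs integer, passes over the training set.
#' @slot learningRate numeric length 2, initial and final learning rate of
#'   the exponential decay schedule.
#' @slot radius numeric length 2, initial and final neighbourhood radius in
#'   hex-grid distance units.
#' @slot init character, `"random-sample"` or `"pca-span"`.
#' @slot distance character, `"euclidean"` or `"cosine"`.
#' @slot seed integer random seed.
#' @exportClass SOMTrainConfig
setClass("SOMTrainConfig",
  slots = c(
    gridWidth = "integer", gridHeight = "integer", nEpochs = "integer",
    learningRate = "numeric", radius = "numeric", init = "character",
    distance = "character", seed = "integer"
  ),
  validity = function(object) {
    if (object@gridWidth < 1L || object@gridHeight < 1L)
      return("grid dimensions must be positive")
    if (object@nEpochs < 1L) return("nEpochs must be >= 1")
    if (length(object@learningRate) != 2L || any(object@learningRate <= 0))
      return("learningRate must be two positive values (initial, final)")
    if (length(object@radius) != 2L || any(object@radius <= 0))
      return("radius must be two positive values (initial, final)")
    if (object@radius[1] > max(object@gridWidth, object@gridHeight))
      return("initial radius must not exceed the larger grid dimension")
    if (!object@init %in% c("random-sample", "pca-span"))
      return("init must be 'random-sample' or 'pca-span'")
    if (!object@distance %in% c("euclidean", "cosine"))
      return("distance must be 'euclidean' or 'cosine'")
    TRUE
  }
)

#' A trained hexagonal self-organizing map with class-label vectors
#'
#' Neurons live on a pointy-top hexagonal grid addressed by axial
#' coordinates. Each neuron carries a spectral weight vector (one value per
#' wavenumber) and a non-negative class-label vector co-trained with the
#' weights; the label vectors drive classification and the SOM discriminant
#' index.
#'
#' @slot gridWidth,gridHeight integer grid dimensions.
#' @slot coords integer matrix (neurons x 2) of axial (q, r) coordinates,
#'   row-major neuron order.
#' @slot weights numeric matrix (neurons x wavenumbers).
#' @slot labelWeights numeric matrix (neurons x classes), entries between 0 and 1,
#'   row sums <= 1.
#' @slot classNames character, ordered class labels.
#' @slot axis numeric wavenumber axis (may be empty when trained on
#'   unannotated matrices).
#' @slot trainedIterations integer, total online updates performed.
#' @slot config list, the training configuration used.
#' @slot seed integer seed the training was run with.
#' @exportClass SOMModel
setClass("SOMModel",
  slots = c(
    gridWidth = "integer", gridHeight = "integer", coords = "matrix",
    weights = "matrix", labelWeights = "matrix", classNames = "character",
    axis = "numeric", trainedIterations = "integer", config = "list",
    seed = "integer"
  ),
  validity = function(object) {
    m <- object@gridWidth * object@gridHeight
    if (nrow(object@weights) != m)
      return("weights must have gridWidth * gridHeight rows")
    if (nrow(object@coords) != m || ncol(object@coords) != 2L)
      return("coords must be a (neurons x 2) matrix")
    if (nrow(object@labelWeights) != m)
      return("labelWeights must have one row per neuron")
    if (ncol(object@labelWeights) != length(object@classNames))
      return("labelWeights must have one column per class")
    if (any(object@labelWeights < 0))
      return("label weights must be non-negative")
    if (any(rowSums(object@labelWeights) > 1 + 1e-8))
      return("label weights of a neuron must sum to <= 1")
    if (anyDuplicated(object@classNames))
      return("class names must be unique")
    if (length(object@axis) && length(object@axis) != ncol(object@weights))
      return("axis length must match weight vector length")
    TRUE
  }
)

#' SOM discriminant index (SOMDI) vectors
#'
#' One signed spectrum-length vector per class; positive entries mark
#' wavenumbers that drive neuron activation toward that class.
#'
#' @slot axis numeric wavenumber axis.
#' @slot discriminants numeric matrix (wavenumbers x classes).
#' @slot classNames character class labels (column order).
#' @exportClass SOMDIResult
setClass("SOMDIResult",
  slots = c(axis = "numeric", discriminants = "matrix", classNames = "character"),
  validity = function(object) {
    if (nrow(object@discriminants) != length(object@axis))
      return("discriminant vectors must match axis length")
    if (ncol(object@discriminants) != length(object@classNames))
      return("one discriminant vector per class required")
    TRUE
  }
)

#' Result of one non-negative least-squares fit
#'
#' @slot coefficients named numeric, non-negative coefficient per component.
#' @slot residualNorm numeric, Euclidean norm of the fit residual.
#' @slot includeOffset logical, whether a constant offset term was fitted.
#' @slot offset numeric, the fitted offset (0 when not fitted).
#' @exportClass UnmixResult
setClass("UnmixResult",
  slots = c(
    coefficients = "numeric", residualNorm = "numeric",
    includeOffset = "logical", offset = "numeric"
  ),
  validity = function(object) {
    if (any(object@coefficients < 0)) return("coefficients must be >= 0")
    if (object@residualNorm < 0) return("residualNorm must be >= 0")
    TRUE
  }
)

#' Group-level comparison of unmixing coefficients
#'
#' Per-component one-way ANOVA across classes.
#'
#' @slot groups character, class names.
#' @slot means numeric matrix (components x groups) of coefficient means.
#' @slot variances numeric matrix (components x groups).
#' @slot statistics data.frame with columns `component`, `F`, `p`.
#' @exportClass GroupComparison
setClass("GroupComparison",
  slots = c(
    groups = "character", means = "matrix", variances = "matrix",
    statistics = "data.frame"
  ),
  validity = function(object) {
    if (length(object@groups) < 2L) return("at least two groups required")
    p <- object@statistics$p
    if (!is.null(p) && any(p < 0 | p > 1, na.rm = TRUE))
      return("p-values must lie in [0, 1]")
    TRUE
  }
)
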