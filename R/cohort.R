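#' Configure a synthetic cohort
#'
#' Builds a [CohortConfig-class]. The defaults emulate a probe acquisition of
#' murine brain tissue: 15 accumulations per sample, a broad fluorescence
#' baseline, additive detector noise, occasional cosmic-ray spikes, and three
#' classes (control, mTBI, sTBI) whose lipid composition differs chiefly by a
#' cardiolipin depletion that deepens with injury severity (70% of control in
#' mTBI, 50% in sTBI), with a milder ganglioside/hemoglobin increase.
#'
#' @param nPerClass samples per class.
#' @param classNames class labels; defaults to the rownames of
#'   `meanCoefficients`.
#' @param meanCoefficients matrix (classes x components) or named list of
#'   named numeric vectors of non-negative mean mixing coefficients.
#' @param coefficientCV between-sample coefficient of variation of the
#'   mixing coefficients (truncated-at-zero normal sampling).
#' @param baselineAmplitude,baselineDecay,baselineCurvature fluorescence
#'   background: amplitude (counts, in units of the unit-maximum component
#'   spectra), exponential decay constant (cm^-1) and relative curvature of
#'   the added low-order term.
#' @param noiseSD additive Gaussian noise standard deviation per channel.
#' @param noiseModel `"gaussian"` (default) or `"poisson"` shot noise.
#' @param spikeRate expected cosmic-ray spikes per accumulation.
#' @param nAccumulations raw accumulations recorded per sample.
#' @param seed integer random seed (mandatory for reproducibility).
#' @return a [CohortConfig-class].
#' @export
cohortConfig <- function(nPerClass = 20L,
                         classNames = NULL,
                         meanCoefficients = defaultMeanCoefficients(),
                         coefficientCV = 0.15,
                         baselineAmplitude = 0.5,
                         baselineDecay = 700,
                         baselineCurvature = 0.3,
                         noiseSD = 0.01,
                         noiseModel = "gaussian",
                         spikeRate = 0.2,
                         nAccumulations = 15L,
                         seed = 1L) {
  if (is.list(meanCoefficients)) {
    comps <- unique(unlist(lapply(meanCoefficients, names)))
    mc <- t(vapply(meanCoefficients,
                   function(v) { out <- setNames(numeric(length(comps)), comps)
                                 out[names(v)] <- v; out },
                   numeric(length(comps))))
    colnames(mc) <- comps
    meanCoefficients <- mc
  }
  if (is.null(classNames)) classNames <- rownames(meanCoefficients)
  if (is.null(classNames))
    nrStop("classNames missing and meanCoefficients has no rownames",
           "nrConfigError")
  rownames(meanCoefficients) <- classNames
  new("CohortConfig",
      nPerClass = as.integer(nPerClass), classNames = classNames,
      meanCoefficients = meanCoefficients,
      coefficientCV = coefficientCV,
      baselineAmplitude = baselineAmplitude, baselineDecay = baselineDecay,
      baselineCurvature = baselineCurvature,
      noiseSD = noiseSD, noiseModel = noiseModel, spikeRate = spikeRate,
      nAccumulations = as.integer(nAccumulations), seed = as.integer(seed))
}

#' Default per-class mean mixing coefficients
#'
#' Cardiolipin at 100%/70%/50% of the control level for control/mTBI/sTBI,
#' a modest ganglioside and hemoglobin increase with injury, and a slight
#' cholesterol decrease; protein held constant.
#' @return numeric matrix (classes x components).
#' @export
defaultMeanCoefficients <- function() {
  rbind(
    control = c(cardiolipin = 1.00, ganglioside = 0.60, hemoglobin = 0.10,
                cholesterol = 0.70, protein = 0.90),
    mTBI    = c(cardiolipin = 0.70, ganglioside = 0.75, hemoglobin = 0.20,
                cholesterol = 0.60, protein = 0.90),
    sTBI    = c(cardiolipin = 0.50, ganglioside = 0.80, hemoglobin = 0.25,
                cholesterol = 0.55, protein = 0.90)
  )
}

#' Smooth fluorescence baseline model
#'
#' Exponentially decaying curve plus a gently sloping low-order term,
#' mimicking the broad fluorescence background under tissue Raman spectra.
#'
#' @param axis wavenumber grid.
#' @param amplitude baseline amplitude (counts).
#' @param decay exponential decay constant (cm^-1).
#' @param curvature relative weight of the low-order term.
#' @return numeric vector on `axis`.
#' @export
fluorescenceBaseline <- function(axis, amplitude = 0.5, decay = 700,
                                 curvature = 0.3) {
  t <- axis - axis[1]
  rel <- if (max(t) > 0) t / max(t) else t
  amplitude * (exp(-t / decay) + curvature * (1 - 0.5 * rel + 0.2 * rel^2))
}

#' Add cosmic-ray spikes to a spectrum
#'
#' Draws a Poisson number of narrow, high-amplitude spikes (1-3 channels
#' wide, amplitude at least 10x the spectrum's robust intensity scale) and
#' adds them at random positions. Spikes are purely additive: the output is
#' never below the input.
#'
#' @param intensity numeric intensity vector.
#' @param rate expected number of spikes (Poisson mean), >= 0.
#' @param seed optional integer; when given, the draw is made from a local
#'   seeded generator and the caller's RNG state is left untouched.
#' @return numeric vector with spikes added; attribute `"nSpikes"` gives the
#'   number of spikes drawn.
#' @export
injectCosmicRays <- function(intensity, rate, seed = NULL) {
  if (rate < 0) nrStop("spike rate must be >= 0")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(as.integer(seed))
  }
  out <- intensity
  n <- stats::rpois(1, rate)
  if (n > 0) {
    sc <- robustScale(intensity)
    len <- length(intensity)
    for (i in seq_len(n)) {
      pos <- sample.int(len, 1L)
      width <- sample.int(3L, 1L)
      amp <- stats::runif(1, 10, 30) * sc
      # triangular spike profile over `width` channels
      offs <- seq_len(width) - 1L
      rel <- c(1, 0.6, 0.3)[seq_len(width)]
      idx <- pos + offs
      keep <- idx <= len
      out[idx[keep]] <- out[idx[keep]] + amp * rel[keep]
    }
  }
  attr(out, "nSpikes") <- n
  out
}

#' Generate a labelled synthetic cohort
#'
#' For each sample: mixing coefficients are drawn from a truncated-at-zero
#' normal around the class means, the clean spectrum is the linear
#' combination of the library components plus the fluorescence baseline, and
#' `nAccumulations` raw replicates are emitted with independent per-channel
#' noise and Poisson cosmic-ray spikes. Fully reproducible from the config
#' seed.
#'
#' @param config a [CohortConfig-class].
#' @param library a [ComponentLibrary-class]; component names referenced by
#'   the config must exist in the library.
#' @return a [RamanCohort-class] with accumulation assays `acc01`, ...,
#'   ground-truth coefficients in `colData` and the clean spectra in
#'   `metadata(x)$clean`.
#' @export
generateCohort <- function(config, library = defaultComponentLibrary()) {
  stopifnot(is(config, "CohortConfig"), is(library, "ComponentLibrary"))
  comps <- colnames(config@meanCoefficients)
  unknown <- setdiff(comps, componentNames(library))
  if (length(unknown))
    nrStop(paste0("unknown component(s) in config: ",
                  paste(unknown, collapse = ", ")), "nrConfigError")
  axis <- library@axis
  A <- library@components[, comps, drop = FALSE]
  nC <- length(config@classNames)
  nS <- nC * config@nPerClass
  nW <- length(axis)
  nA <- config@nAccumulations

  set.seed(config@seed)
  base <- fluorescenceBaseline(axis, config@baselineAmplitude,
                               config@baselineDecay, config@baselineCurvature)

  labels <- rep(config@classNames, each = config@nPerClass)
  truth <- matrix(0, nS, length(comps), dimnames = list(NULL, comps))
  clean <- matrix(0, nW, nS)
  accs <- lapply(seq_len(nA), function(a) matrix(0, nW, nS))

  for (s in seq_len(nS)) {
    mu <- config@meanCoefficients[labels[s], ]
    cf <- pmax(0, stats::rnorm(length(mu), mu, config@coefficientCV * mu))
    truth[s, ] <- cf
    cs <- as.numeric(A %*% cf) + base
    clean[, s] <- cs
    for (a in seq_len(nA)) {
      acc <- if (config@noiseModel == "poisson" && config@noiseSD > 0) {
        # shot-noise approximation: scale so that noiseSD sets the scale at
        # the clean maximum
        sc <- max(cs) / max(config@noiseSD^2, .Machine$double.eps)
        stats::rpois(nW, pmax(cs, 0) * sc) / sc
      } else {
        cs + stats::rnorm(nW, 0, config@noiseSD)
      }
      if (config@spikeRate > 0)
        acc <- as.numeric(injectCosmicRays(acc, config@spikeRate))
      accs[[a]][, s] <- acc
    }
  }

  sampleIds <- sprintf("s%03d", seq_len(nS))
  for (a in seq_len(nA)) colnames(accs[[a]]) <- sampleIds
  names(accs) <- sprintf("acc%02d", seq_len(nA))
  cd <- S4Vectors::DataFrame(sample_id = sampleIds, class = labels)
  for (cmp in comps) cd[[paste0("truth_", cmp)]] <- truth[, cmp]
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = accs,
    rowData = S4Vectors::DataFrame(wavenumber = axis),
    colData = cd,
    metadata = list(config = config, clean = clean, baseline = base))
  new("RamanCohort", se)
}

#' @rdname neuroraman-generics
#' @export
setMethod("wavenumbers", "RamanCohort",
          function(x) SummarizedExperiment::rowData(x)$wavenumber)

#' @rdname neuroraman-generics
#' @export
setMethod("classLabels", "RamanCohort",
          function(x) as.character(SummarizedExperiment::colData(x)$class))

#' Ground-truth mixing coefficients of a synthetic cohort
#' @param x a [RamanCohort-class].
#' @return numeric matrix (samples x components), or NULL when the cohort
#'   carries no truth columns.
#' @export
truthCoefficients <- function(x) {
  stopifnot(is(x, "RamanCohort"))
  cd <- SummarizedExperiment::colData(x)
  cols <- grep("^truth_", colnames(cd), value = TRUE)
  if (!length(cols)) return(NULL)
  m <- as.matrix(as.data.frame(cd[, cols, drop = FALSE]))
  colnames(m) <- sub("^truth_", "", cols)
  rownames(m) <- cd$sample_id
  m
}

#' Raw accumulation stack of one sample
#' @param x a [RamanCohort-class] with accumulation assays.
#' @param sample sample index or id.
#' @return numeric matrix (accumulations x wavenumbers).
#' @export
accumulationStack <- function(x, sample) {
  stopifnot(is(x, "RamanCohort"))
  an <- grep("^acc", SummarizedExperiment::assayNames(x), value = TRUE)
  if (!length(an)) nrStop("cohort has no accumulation assays")
  if (is.character(sample))
    sample <- match(sample, SummarizedExperiment::colData(x)$sample_id)
  t(vapply(an, function(a) SummarizedExperiment::assay(x, a)[, sample],
           numeric(nrow(x))))
}

#' Spectrum matrix of a cohort
#'
#' Returns the preprocessed `spectra` assay if present, otherwise the plain
#' mean over accumulation assays.
#' @param x a [RamanCohort-class].
#' @return numeric matrix (wavenumbers x samples).
#' @export
spectraMatrix <- function(x) {
  stopifnot(is(x, "RamanCohort"))
  an <- SummarizedExperiment::assayNames(x)
  if ("spectra" %in% an) return(SummarizedExperiment::assay(x, "spectra"))
  accs <- grep("^acc", an, value = TRUE)
  if (!length(accs)) nrStop("cohort has neither 'spectra' nor accumulation assays")
  out <- SummarizedExperiment::assay(x, accs[1])
  if (length(accs) > 1)
    for (a in accs[-1]) out <- out + SummarizedExperiment::assay(x, a)
  out / length(accs)
}

setMethod("show", "RamanCohort", function(object) {
  cl <- table(classLabels(object))
  cat(sprintf("RamanCohort: %d samples x %d channels (%.0f-%.0f cm-1)\n",
              ncol(object), nrow(object),
              min(wavenumbers(object)), max(wavenumbers(object))))
  cat("  assays:", paste(SummarizedExperiment::assayNames(object), collapse = ", "), "\n")
  cat("  classes:", paste(sprintf("%s (%d)", names(cl), cl), collapse = ", "), "\n")
  invisible(object)
})
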