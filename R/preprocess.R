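#' Preprocessing configuration
#'
#' @param spikeThreshold robust z-score cutoff for cosmic-ray detection.
#' @param baselineNodes spline node count for baseline fitting (>= 4).
#' @param baselineIterations maximum asymmetric re-weighting iterations.
#' @param targetAxis resampling grid, or NULL to keep the native axis.
#' @param normalization `"none"`, `"vector"` or `"area"`.
#' @return a [PreprocessConfig-class].
#' @export
preprocessConfig <- function(spikeThreshold = 8, baselineNodes = 11L,
                             baselineIterations = 20L, targetAxis = NULL,
                             normalization = "none") {
  new("PreprocessConfig",
      spikeThreshold = spikeThreshold,
      baselineNodes = as.integer(baselineNodes),
      baselineIterations = as.integer(baselineIterations),
      targetAxis = if (is.null(targetAxis)) numeric(0) else as.numeric(targetAxis),
      normalization = normalization)
}

#' Remove cosmic-ray spikes by cross-accumulation comparison
#'
#' Cosmic rays hit a single readout, so a spiked value disagrees with the
#' other accumulations at the same channel. For each channel of each
#' accumulation, a value whose deviation from the cross-accumulation median
#' exceeds `spikeThreshold` robust scales is replaced by the median of the
#' remaining accumulations at that channel; the cleaned stack is then
#' averaged.
#'
#' @param accumulations numeric matrix, one row per accumulation (columns are
#'   channels), or a single numeric vector (see Details).
#' @param spikeThreshold robust z cutoff (default 8).
#' @param axis optional wavenumber axis; when supplied the result is a
#'   [RamanSpectrum-class], otherwise a plain numeric vector.
#' @param collapse if FALSE, return the cleaned stack instead of its mean.
#' @details With a single accumulation no cross-replicate comparison is
#'   possible; the function falls back to within-spectrum detection against a
#'   running median and linear neighbour interpolation, with a warning.
#' @return cleaned mean spectrum (vector or [RamanSpectrum-class]) with
#'   attribute `"nSpikes"` (number of replaced values), or the cleaned stack
#'   when `collapse = FALSE`.
#' @export
removeCosmicRays <- function(accumulations, spikeThreshold = 8, axis = NULL,
                             collapse = TRUE) {
  if (spikeThreshold <= 0) nrStop("spikeThreshold must be > 0")
  if (is.list(accumulations)) {
    if (length(unique(lengths(accumulations))) != 1L)
      nrStop("accumulations have mismatched lengths")
    accumulations <- do.call(rbind, accumulations)
  }
  if (is.numeric(accumulations) && is.null(dim(accumulations)))
    accumulations <- matrix(accumulations, nrow = 1)
  if (!is.matrix(accumulations)) nrStop("accumulations must be a matrix")
  if (anyNA(accumulations)) nrStop("accumulations must not contain NA")
  nAcc <- nrow(accumulations)

  if (nAcc < 2L) {
    warning("single accumulation: falling back to within-spectrum neighbour interpolation")
    x <- accumulations[1, ]
    n <- length(x)
    k <- min(7L, if (n %% 2L == 1L) n else n - 1L)
    med <- stats::runmed(x, k = k)
    dev <- x - med
    s <- robustScale(dev)
    flag <- dev > spikeThreshold * s
    nSpikes <- sum(flag)
    if (nSpikes > 0 && any(!flag)) {
      x[flag] <- stats::approx(which(!flag), x[!flag], xout = which(flag),
                               rule = 2)$y
    }
    out <- if (collapse) x else matrix(x, nrow = 1)
  } else {
    med <- apply(accumulations, 2, stats::median)
    madj <- apply(accumulations, 2, stats::mad)
    # per-channel MADs over a handful of accumulations are unstable; floor
    # them by the typical (median positive) channel scale so ordinary noise
    # at an unlucky channel is not flagged
    pos <- madj[madj > 0]
    floorScale <- if (length(pos)) stats::median(pos) else
      max(1e-12, 1e-9 * max(abs(accumulations)))
    s <- pmax(madj, floorScale)
    dev <- abs(sweep(accumulations, 2, med))
    flag <- sweep(dev, 2, spikeThreshold * s) > 0
    nSpikes <- sum(flag)
    cleaned <- accumulations
    if (nSpikes > 0) {
      for (j in which(colSums(flag) > 0)) {
        keep <- !flag[, j]
        repl <- if (any(keep)) stats::median(accumulations[keep, j]) else med[j]
        cleaned[flag[, j], j] <- repl
      }
    }
    out <- if (collapse) colMeans(cleaned) else cleaned
  }
  if (!is.null(axis) && collapse) out <- ramanSpectrum(axis, out)
  attr(out, "nSpikes") <- nSpikes
  out
}

# Fit the fluorescence baseline in two stages.
#
# Stage 1: iterative asymmetric re-weighted B-spline regression — channels
# above the running fit (Raman bands) are smoothly down-weighted via a
# logistic on the residual scale of the below-fit channels, so the spline
# settles on the lower envelope.
#
# Stage 2: the stage-1 residuals identify band regions (cores above 3 sigma,
# expanded outward while residuals stay above 0.5 sigma). Equally spaced
# node windows whose channels are mostly baseline-like contribute one anchor
# point (median position / median intensity of their unmasked channels);
# windows dominated by bands are dropped so elevated inter-band valleys
# cannot masquerade as baseline. A natural cubic spline through the
# surviving node anchors is the baseline; the mask/anchor pass is applied
# twice so the second pass works from an unbiased fit.
fitBaseline <- function(axis, intensity, nodes = 11L, iterations = 20L) {
  n <- length(intensity)
  if (n <= nodes) nrStop("spectrum must be longer than the node count")
  knots <- seq(min(axis), max(axis), length.out = nodes + 2L)
  knots <- knots[-c(1L, length(knots))]
  B <- splines::bs(axis, knots = knots, degree = 3L, intercept = TRUE)
  w <- rep(1, n)
  fitted <- numeric(n)
  # fit-independent channel noise estimate from first differences (bands and
  # baseline are smooth, so differences are noise-dominated); keeps the band
  # detection threshold honest when the envelope fit hugs the data
  noiseScale <- stats::mad(diff(intensity)) / sqrt(2)
  sigma <- 0
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max(1L, iterations))) {
    fit <- stats::lm.wfit(B, intensity, w)
    cf <- fit$coefficients
    cf[is.na(cf)] <- 0
    fitted <- as.numeric(B %*% cf)
    r <- intensity - fitted
    neg <- r[r < 0]
    sigma <- if (length(neg) > 1L) stats::sd(neg) else 0
    sigma <- max(sigma, noiseScale, 1e-9 * max(abs(intensity), 1))
    z <- pmin((r - 2 * sigma) / sigma, 50)
    wNew <- 1 / (1 + exp(2 * z))
    delta <- sum(abs(wNew - w)) / max(sum(w), 1)
    w <- wNew
    if (delta < 1e-2) { converged <- TRUE; break }
  }
  if (!converged && iterations > 1L)
    warning("baseline re-weighting did not converge; continuing from last iterate")

  bandMask <- function(f) {
    r <- intensity - f
    core <- r > 3 * sigma
    mask <- core
    runs <- rle(core)
    idx <- 1L
    for (k in seq_along(runs$lengths)) {
      if (runs$values[k]) {
        lo <- idx
        hi <- idx + runs$lengths[k] - 1L
        # expand over the band's flanks; the floor at 1% of the band height
        # keeps far Lorentzian tails from swallowing the whole axis when the
        # noise scale is tiny
        thr <- max(0.5 * sigma, 0.01 * max(r[lo:hi]))
        while (lo > 1L && r[lo - 1L] > thr) lo <- lo - 1L
        while (hi < n && r[hi + 1L] > thr) hi <- hi + 1L
        mask[lo:hi] <- TRUE
      }
      idx <- idx + runs$lengths[k]
    }
    mask
  }
  anchorSpline <- function(mask) {
    nodeX <- seq(min(axis), max(axis), length.out = nodes)
    half <- diff(nodeX[1:2]) / 2
    px <- numeric(0); py <- numeric(0)
    for (xk in nodeX) {
      inWin <- abs(axis - xk) <= half
      ok <- which(inWin & !mask)
      # distrust windows dominated by band channels
      if (length(ok) >= max(5, 0.25 * sum(inWin))) {
        px <- c(px, stats::median(axis[ok]))
        py <- c(py, stats::median(intensity[ok]))
      }
    }
    # leave-one-out consistency: an interior anchor sitting well above the
    # spline through the remaining anchors is an elevated inter-band valley,
    # not baseline; drop the worst offender until all agree
    while (length(px) > 4L) {
      excess <- vapply(2:(length(px) - 1L), function(i) {
        pred <- stats::spline(px[-i], py[-i], xout = px[i],
                              method = "natural")$y
        py[i] - pred
      }, numeric(1))
      worst <- which.max(excess)
      if (excess[worst] <= 2 * sigma) break
      px <- px[-(worst + 1L)]
      py <- py[-(worst + 1L)]
    }
    if (length(px) < 4L) return(NULL)
    stats::spline(px, py, xout = axis, method = "natural")$y
  }
  f2 <- anchorSpline(bandMask(fitted))
  if (!is.null(f2)) {
    f3 <- anchorSpline(bandMask(f2))
    fitted <- if (is.null(f3)) f2 else f3
  }
  list(baseline = fitted, iterations = it, converged = converged)
}

#' Subtract the fluorescence baseline
#'
#' Fits a smooth spline through the lower envelope of the spectrum by
#' iterative asymmetric re-weighting (channels above the running fit are
#' down-weighted, so Raman bands do not pull the baseline up) and subtracts
#' it. Small negative residual intensities are retained, not clipped, to
#' avoid biasing downstream least-squares fits.
#'
#' @param spectrum a [RamanSpectrum-class].
#' @param baselineNodes spline node count (default 11).
#' @param baselineIterations maximum re-weighting iterations.
#' @param returnBaseline if TRUE, attach the fitted baseline as attribute
#'   `"baseline"`.
#' @return baseline-corrected [RamanSpectrum-class]; attribute
#'   `"iterations"` records the re-weighting iterations used.
#' @export
subtractBaseline <- function(spectrum, baselineNodes = 11L,
                             baselineIterations = 20L,
                             returnBaseline = FALSE) {
  stopifnot(is(spectrum, "RamanSpectrum"))
  fit <- fitBaseline(spectrum@axis, spectrum@intensity,
                     nodes = baselineNodes, iterations = baselineIterations)
  out <- ramanSpectrum(spectrum@axis, spectrum@intensity - fit$baseline)
  attr(out, "iterations") <- fit$iterations
  if (returnBaseline) attr(out, "baseline") <- fit$baseline
  out
}

#' Resample and truncate a spectrum
#'
#' Linear interpolation onto a target grid lying inside the source axis;
#' values are never extrapolated. Cubic interpolation is available but
#' linear is the default to avoid ringing near sharp bands.
#'
#' @param spectrum a [RamanSpectrum-class].
#' @param targetAxis strictly increasing grid within the source axis range.
#' @param method `"linear"` (default) or `"cubic"`.
#' @return resampled [RamanSpectrum-class].
#' @export
resampleTruncate <- function(spectrum, targetAxis, method = c("linear", "cubic")) {
  stopifnot(is(spectrum, "RamanSpectrum"))
  method <- match.arg(method)
  if (!isStrictlyIncreasing(targetAxis))
    nrStop("targetAxis must be strictly increasing", "nrInvalidAxis")
  src <- spectrum@axis
  if (min(targetAxis) < min(src) || max(targetAxis) > max(src))
    nrStop("target axis extends beyond the source range; extrapolation is not performed",
           "nrRangeError")
  y <- if (method == "linear") {
    stats::approx(src, spectrum@intensity, xout = targetAxis)$y
  } else {
    stats::spline(src, spectrum@intensity, xout = targetAxis, method = "natural")$y
  }
  ramanSpectrum(targetAxis, y)
}

#' Normalize a spectrum
#'
#' @param spectrum a [RamanSpectrum-class].
#' @param mode `"none"`, `"vector"` (unit Euclidean norm) or `"area"`
#'   (unit trapezoidal integral).
#' @return normalized [RamanSpectrum-class].
#' @export
normalizeSpectrum <- function(spectrum, mode = c("none", "vector", "area")) {
  stopifnot(is(spectrum, "RamanSpectrum"))
  mode <- match.arg(mode)
  if (mode == "none") return(spectrum)
  y <- spectrum@intensity
  denom <- switch(mode,
                  vector = sqrt(sum(y^2)),
                  area = trapezoid(spectrum@axis, y))
  if (!is.finite(denom) || abs(denom) < .Machine$double.eps)
    nrStop("cannot normalize an all-zero spectrum", "nrDegenerateInput")
  ramanSpectrum(spectrum@axis, y / denom)
}

# Column-wise normalization of a spectrum matrix (channels x samples).
normalizeColumns <- function(mat, axis, mode) {
  if (mode == "none") return(mat)
  apply(mat, 2, function(y)
    intensities(normalizeSpectrum(ramanSpectrum(axis, y), mode)))
}

#' Peak height within a wavenumber window
#'
#' Maximum intensity within `[center - halfWindow, center + halfWindow]`;
#' intended for baseline-corrected spectra.
#'
#' @param spectrum a [RamanSpectrum-class].
#' @param center window centre (cm^-1).
#' @param halfWindow half width of the search window (cm^-1).
#' @return numeric peak height.
#' @export
peakHeight <- function(spectrum, center, halfWindow = 10) {
  stopifnot(is(spectrum, "RamanSpectrum"))
  ax <- spectrum@axis
  if (center - halfWindow < min(ax) || center + halfWindow > max(ax))
    nrStop("peak window lies outside the spectrum axis", "nrRangeError")
  inWin <- ax >= center - halfWindow & ax <= center + halfWindow
  max(spectrum@intensity[inWin])
}

#' Ratio of two peak heights
#'
#' For example the 1447/1660 cm^-1 peak-height ratio, which increases when
#' cardiolipin (dominating 1660 cm^-1) is depleted.
#'
#' @param spectrum a [RamanSpectrum-class].
#' @param numCenter,denCenter numerator and denominator band centres (cm^-1).
#' @param halfWindow half width of both search windows (cm^-1).
#' @return dimensionless ratio.
#' @export
bandRatio <- function(spectrum, numCenter, denCenter, halfWindow = 10) {
  num <- peakHeight(spectrum, numCenter, halfWindow)
  den <- peakHeight(spectrum, denCenter, halfWindow)
  if (den <= 0)
    nrStop("denominator peak height is not positive", "nrDegenerateInput")
  num / den
}

#' Preprocess a whole cohort
#'
#' Runs the full cleaning chain per sample — cosmic-ray removal across
#' accumulations, spline baseline subtraction, optional resampling and
#' normalization — and returns a cohort with a single `spectra` assay.
#'
#' @param cohort a [RamanCohort-class] with accumulation assays.
#' @param config a [PreprocessConfig-class].
#' @return a [RamanCohort-class] on the (possibly resampled) axis with assay
#'   `spectra`; per-sample replaced spike counts are recorded in
#'   `metadata(x)$spikeCounts`.
#' @export
preprocessCohort <- function(cohort, config = preprocessConfig()) {
  stopifnot(is(cohort, "RamanCohort"), is(config, "PreprocessConfig"))
  axis <- wavenumbers(cohort)
  target <- if (length(config@targetAxis)) config@targetAxis else axis
  n <- ncol(cohort)
  out <- matrix(0, length(target), n)
  spikes <- integer(n)
  for (s in seq_len(n)) {
    stack <- accumulationStack(cohort, s)
    cleaned <- removeCosmicRays(stack, config@spikeThreshold, axis = axis)
    spikes[s] <- attr(cleaned, "nSpikes")
    corr <- subtractBaseline(cleaned, config@baselineNodes,
                             config@baselineIterations)
    rs <- resampleTruncate(corr, target)
    if (config@normalization != "none")
      rs <- normalizeSpectrum(rs, config@normalization)
    out[, s] <- rs@intensity
  }
  cd <- SummarizedExperiment::colData(cohort)
  colnames(out) <- cd$sample_id
  md <- S4Vectors::metadata(cohort)
  md$spikeCounts <- spikes
  md$preprocess <- config
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(spectra = out),
    rowData = S4Vectors::DataFrame(wavenumber = target),
    colData = cd, metadata = md)
  new("RamanCohort", se)
}
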