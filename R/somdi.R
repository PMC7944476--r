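#' SOM discriminant index (SOMDI)
#'
#' For each class, the discriminant vector is the mean over neurons of the
#' neuron's weight vector scaled by its label contrast — the neuron's label
#' weight for the class minus its mean label weight over the other classes.
#' Positive entries mark wavenumbers whose intensity drives neuron
#' activation toward that class. The mean (rather than unit-norm) scaling
#' preserves magnitude, so a map with no class structure yields vectors near
#' zero, comparable against a label-permutation noise floor.
#'
#' @param model a trained [SOMModel-class] with at least two classes.
#' @return a [SOMDIResult-class].
#' @export
computeSOMDI <- function(model) {
  stopifnot(is(model, "SOMModel"))
  if (model@trainedIterations < 1L)
    nrStop("model has not been trained", "nrStateError")
  k <- length(model@classNames)
  if (k < 2L)
    nrStop("SOMDI needs at least two classes to contrast",
           "nrDegenerateContrast")
  L <- model@labelWeights
  W <- model@weights
  m <- nrow(W)
  D <- vapply(seq_len(k), function(c) {
    contrast <- L[, c] - rowMeans(L[, -c, drop = FALSE])
    as.numeric(crossprod(W, contrast)) / m
  }, numeric(ncol(W)))
  colnames(D) <- model@classNames
  axis <- if (length(model@axis)) model@axis else as.numeric(seq_len(ncol(W)))
  new("SOMDIResult", axis = axis, discriminants = D,
      classNames = model@classNames)
}

#' Extract one class's discriminant vector as a spectrum
#' @param somdi a [SOMDIResult-class].
#' @param class class name.
#' @return a [RamanSpectrum-class] (signed intensities).
#' @export
somdiSpectrum <- function(somdi, class) {
  stopifnot(is(somdi, "SOMDIResult"))
  if (!class %in% somdi@classNames)
    nrStop(paste0("unknown class: ", class))
  ramanSpectrum(somdi@axis, somdi@discriminants[, class])
}

#' Top positive SOMDI peak positions for a class
#'
#' Local maxima of the positive part of the class's discriminant vector,
#' ranked by height, with a minimum mutual separation so one broad band is
#' not reported several times.
#'
#' @param somdi a [SOMDIResult-class].
#' @param class class name.
#' @param n number of peaks to report.
#' @param minSeparation minimum spacing between reported peaks (cm^-1).
#' @return numeric vector of peak wavenumbers (length <= n), ordered by
#'   decreasing height.
#' @export
somdiPeaks <- function(somdi, class, n = 5L, minSeparation = 30) {
  d <- pmax(somdiSpectrum(somdi, class)@intensity, 0)
  axis <- somdi@axis
  len <- length(d)
  isMax <- d > 0 &
    d >= c(-Inf, d[-len]) &
    d >= c(d[-1], -Inf)
  cand <- which(isMax)
  cand <- cand[order(d[cand], decreasing = TRUE)]
  picked <- numeric(0)
  for (i in cand) {
    if (!length(picked) || all(abs(axis[i] - picked) >= minSeparation))
      picked <- c(picked, axis[i])
    if (length(picked) >= n) break
  }
  picked
}

setMethod("show", "SOMDIResult", function(object) {
  cat(sprintf("SOMDIResult: %d classes on %d channels\n",
              ncol(object@discriminants), length(object@axis)))
  for (cl in object@classNames) {
    pk <- somdiPeaks(object, cl, n = 3L)
    cat(sprintf("  %s: top bands %s cm-1\n", cl,
                paste(round(pk), collapse = ", ")))
  }
  invisible(object)
})

#' @rdname neuroraman-generics
#' @export
setMethod("classLabels", "SOMDIResult", function(x) x@classNames)

#' @rdname neuroraman-generics
#' @export
setMethod("wavenumbers", "SOMDIResult", function(x) x@axis)
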