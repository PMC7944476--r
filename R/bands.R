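#' Pseudo-Voigt band profile
#'
#' Weighted sum of a Lorentzian and a Gaussian of common centre and
#' full-width-half-maximum, the standard line shape for condensed-phase
#' Raman bands. The profile peaks at `amplitude` at `center`.
#'
#' @param x numeric wavenumbers at which to evaluate.
#' @param center band centre (cm^-1).
#' @param fwhm full width at half maximum (cm^-1), > 0.
#' @param amplitude peak height, >= 0.
#' @param shapeMix Lorentzian fraction in \[0, 1\]; 0 is pure Gaussian.
#' @return numeric vector of intensities, same length as `x`.
#' @export
pseudoVoigt <- function(x, center, fwhm, amplitude = 1, shapeMix = 0.5) {
  if (fwhm <= 0) nrStop("fwhm must be > 0")
  if (amplitude < 0) nrStop("amplitude must be >= 0")
  if (shapeMix < 0 || shapeMix > 1) nrStop("shapeMix must lie in [0, 1]")
  u <- (x - center) / (fwhm / 2)
  lor <- 1 / (1 + u^2)
  gau <- exp(-log(2) * u^2)
  amplitude * (shapeMix * lor + (1 - shapeMix) * gau)
}

#' Describe one spectral band
#'
#' @param center band centre (cm^-1).
#' @param fwhm full width at half maximum (cm^-1), > 0.
#' @param amplitude relative peak height, >= 0.
#' @param shapeMix Lorentzian fraction of the pseudo-Voigt profile.
#' @return one-row data.frame usable in a band table.
#' @seealso [generateComponentLibrary()]
#' @export
bandSpec <- function(center, fwhm, amplitude = 1, shapeMix = 0.5) {
  if (fwhm <= 0) nrStop("fwhm must be > 0")
  if (amplitude < 0) nrStop("amplitude must be >= 0")
  if (shapeMix < 0 || shapeMix > 1) nrStop("shapeMix must lie in [0, 1]")
  data.frame(center = center, fwhm = fwhm, amplitude = amplitude,
             shapeMix = shapeMix)
}

#' Default fingerprint-region wavenumber axis
#'
#' 600-1800 cm^-1 at 1 cm^-1 spacing: the band-rich fingerprint region that
#' contains every band this package interprets (1003, 1266, 1337, 1447,
#' 1660 cm^-1).
#' @return numeric vector.
#' @export
defaultAxis <- function() seq(600, 1800, by = 1)

#' Full probe spectral domain
#'
#' The full acquisition domain of the fibre probe, -200 to 3723 cm^-1.
#' @param by grid spacing in cm^-1.
#' @return numeric vector.
#' @export
probeAxis <- function(by = 1) seq(-200, 3723, by = by)

#' Build a component library from band tables
#'
#' Evaluates, for each named component, the sum of its pseudo-Voigt band
#' profiles on a common wavenumber grid.
#'
#' @param bandTable named list; each element a data.frame of bands as
#'   returned by [bandSpec()] (rows may be concatenated with `rbind`).
#' @param axis strictly increasing wavenumber grid.
#' @return a [ComponentLibrary-class].
#' @examples
#' lib <- generateComponentLibrary(
#'   list(protein = bandSpec(1003, 12)), axis = defaultAxis())
#' componentNames(lib)
#' @export
generateComponentLibrary <- function(bandTable, axis) {
  if (!isStrictlyIncreasing(axis))
    nrStop("axis must be strictly increasing", "nrInvalidAxis")
  if (!length(bandTable) || is.null(names(bandTable)))
    nrStop("bandTable must be a non-empty named list")
  if (anyDuplicated(names(bandTable)))
    nrStop("component names must be unique")
  comps <- vapply(bandTable, function(bands) {
    if (is.null(bands) || nrow(bands) < 1L)
      nrStop("every component needs at least one band")
    v <- numeric(length(axis))
    for (i in seq_len(nrow(bands))) {
      v <- v + pseudoVoigt(axis, bands$center[i], bands$fwhm[i],
                           bands$amplitude[i], bands$shapeMix[i])
    }
    v
  }, numeric(length(axis)))
  comps <- matrix(comps, nrow = length(axis),
                  dimnames = list(NULL, names(bandTable)))
  new("ComponentLibrary", axis = as.numeric(axis), components = comps)
}

# Band tables of the default five-component brain basis. Positions and
# relative heights follow standard assignments: cardiolipin dominates
# 1266 (=C-H in-plane) and 1660 cm^-1 (C=C stretch); CH2/CH3 bending of
# mixed proteins and lipids dominates 1447 cm^-1; phenylalanine ring
# breathing marks protein at 1003 cm^-1.
defaultBandTables <- function() {
  list(
    cardiolipin = rbind(
      bandSpec(1266, 22, 0.85, 0.6), bandSpec(1301, 18, 0.35, 0.6),
      bandSpec(1440, 20, 0.45, 0.6), bandSpec(1660, 24, 1.00, 0.6),
      bandSpec(1745, 16, 0.20, 0.6)),
    ganglioside = rbind(
      bandSpec(1063, 18, 0.50, 0.5), bandSpec(1130, 18, 0.45, 0.5),
      bandSpec(1447, 22, 1.00, 0.5), bandSpec(1660, 26, 0.35, 0.5)),
    hemoglobin = rbind(
      bandSpec(754, 12, 0.90, 0.7), bandSpec(1127, 14, 0.40, 0.7),
      bandSpec(1549, 16, 1.00, 0.7), bandSpec(1620, 14, 0.60, 0.7)),
    cholesterol = rbind(
      bandSpec(700, 12, 0.80, 0.5), bandSpec(1440, 20, 1.00, 0.5),
      bandSpec(1672, 18, 0.35, 0.5)),
    protein = rbind(
      bandSpec(1003, 10, 1.00, 0.4), bandSpec(1337, 24, 0.55, 0.5),
      bandSpec(1447, 22, 0.80, 0.5), bandSpec(1660, 28, 0.90, 0.5))
  )
}

#' Default five-component brain lipid/protein library
#'
#' Cardiolipin, ganglioside, hemoglobin, cholesterol and a generic protein
#' component, each scaled to unit maximum so that unmixing coefficients are
#' comparable across components. This is a synthetic stand-in basis, not a
#' measured lipid reference set.
#'
#' @param axis wavenumber grid (default the fingerprint region).
#' @return a [ComponentLibrary-class].
#' @export
defaultComponentLibrary <- function(axis = defaultAxis()) {
  lib <- generateComponentLibrary(defaultBandTables(), axis)
  m <- apply(lib@components, 2, max)
  m[m == 0] <- 1
  lib@components <- sweep(lib@components, 2, m, "/")
  lib
}

#' @rdname neuroraman-generics
#' @export
setMethod("componentNames", "ComponentLibrary",
          function(x) colnames(x@components))

#' @rdname neuroraman-generics
#' @export
setMethod("wavenumbers", "ComponentLibrary", function(x) x@axis)

#' Extract the component matrix of a library
#' @param x a [ComponentLibrary-class].
#' @return numeric matrix (wavenumbers x components).
#' @export
componentMatrix <- function(x) {
  stopifnot(is(x, "ComponentLibrary"))
  x@components
}

setMethod("show", "ComponentLibrary", function(object) {
  cat(sprintf("ComponentLibrary: %d components on %d channels (%.0f-%.0f cm-1)\n",
              ncol(object@components), length(object@axis),
              min(object@axis), max(object@axis)))
  cat("  components:", paste(colnames(object@components), collapse = ", "), "\n")
  invisible(object)
})
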