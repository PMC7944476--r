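#' Create a Raman spectrum
#'
#' @param axis numeric wavenumber axis in cm^-1, strictly increasing.
#' @param intensity numeric intensity values (counts), same length as `axis`.
#' @return a [RamanSpectrum-class] object.
#' @examples
#' s <- ramanSpectrum(600:610, rnorm(11))
#' wavenumbers(s)
#' @export
ramanSpectrum <- function(axis, intensity) {
  obj <- new("RamanSpectrum", axis = as.numeric(axis),
             intensity = as.numeric(intensity))
  obj
}

#' @rdname neuroraman-generics
#' @export
setMethod("wavenumbers", "RamanSpectrum", function(x) x@axis)

#' @rdname neuroraman-generics
#' @export
setMethod("intensities", "RamanSpectrum", function(x) x@intensity)

setMethod("show", "RamanSpectrum", function(object) {
  cat(sprintf("RamanSpectrum: %d channels, %.1f-%.1f cm-1\n",
              length(object@axis), min(object@axis), max(object@axis)))
  invisible(object)
})

setMethod("length", "RamanSpectrum", function(x) length(x@axis))

# Coerce a spectrum-like input (RamanSpectrum or 2-column thing) to a
# RamanSpectrum; internal convenience.
asSpectrum <- function(x, axis = NULL) {
  if (is(x, "RamanSpectrum")) return(x)
  if (is.numeric(x) && !is.null(axis)) return(ramanSpectrum(axis, x))
  nrStop("expected a RamanSpectrum (or a numeric vector with an axis)")
}
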