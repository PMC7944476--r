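#' @name neuroraman-generics
#' @title Accessor generics
#' @description Small accessor generics shared by the package's classes.
#' @param x an object.
#' @return `wavenumbers` and `intensities` return numeric vectors;
#'   `componentNames` and `classLabels` return character vectors.
NULL

#' @rdname neuroraman-generics
#' @export
setGeneric("wavenumbers", function(x) standardGeneric("wavenumbers"))

#' @rdname neuroraman-generics
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @rdname neuroraman-generics
#' @export
setGeneric("componentNames", function(x) standardGeneric("componentNames"))

#' @rdname neuroraman-generics
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))
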