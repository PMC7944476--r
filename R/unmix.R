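#' Non-negative least-squares fit of component spectra
#'
#' Finds non-negative coefficients minimizing the Euclidean norm of
#' `spectrum - sum(c_i * component_i) (- offset)` via the Lawson-Hanson
#' active-set algorithm. Components are scaled to unit maximum before
#' fitting by default so coefficients are comparable across components. The
#' optional offset absorbs residual baseline and is free in sign (the
#' component coefficients remain non-negative).
#'
#' @param spectrum a [RamanSpectrum-class] on the library axis.
#' @param library a [ComponentLibrary-class].
#' @param includeOffset fit a constant offset term (default TRUE).
#' @param normalizeComponents scale each component to unit maximum before
#'   fitting (default TRUE).
#' @return an [UnmixResult-class].
#' @export
nnlsFit <- function(spectrum, library, includeOffset = TRUE,
                    normalizeComponents = TRUE) {
  stopifnot(is(spectrum, "RamanSpectrum"), is(library, "ComponentLibrary"))
  if (length(spectrum@axis) != length(library@axis) ||
      !isTRUE(all.equal(spectrum@axis, library@axis)))
    nrStop("spectrum and library must share an identical axis")
  A <- library@components
  mx <- apply(A, 2, max)
  if (any(mx == 0))
    nrStop(paste0("all-zero library component(s): ",
                  paste(colnames(A)[mx == 0], collapse = ", ")),
           "nrDegenerateBasis")
  if (normalizeComponents) A <- sweep(A, 2, mx, "/")
  k <- ncol(A)
  Afit <- if (includeOffset) cbind(A, 1, -1) else A
  sol <- pracma::lsqnonneg(Afit, spectrum@intensity)
  x <- sol$x
  coeff <- setNames(x[seq_len(k)], colnames(A))
  offset <- if (includeOffset) x[k + 1] - x[k + 2] else 0
  resid <- spectrum@intensity - as.numeric(Afit %*% x)
  new("UnmixResult", coefficients = coeff,
      residualNorm = sqrt(sum(resid^2)),
      includeOffset = includeOffset, offset = offset)
}

#' @describeIn nnlsFit fitted coefficients of an [UnmixResult-class].
#' @param object an [UnmixResult-class].
#' @param ... ignored.
#' @export
setMethod("coef", "UnmixResult", function(object, ...) object@coefficients)

setMethod("show", "UnmixResult", function(object) {
  cat("UnmixResult:\n")
  print(round(object@coefficients, 4))
  cat(sprintf("  residual norm %.4g%s\n", object@residualNorm,
              if (object@includeOffset)
                sprintf(" | offset %.4g", object@offset) else ""))
  invisible(object)
})

#' Unmix every sample of a cohort
#'
#' Fits the component library to each sample's average spectrum (the
#' `spectra` assay of a preprocessed cohort, or the plain accumulation mean)
#' and tabulates the coefficients with class labels for group statistics.
#'
#' @param cohort a [RamanCohort-class] on the library's axis.
#' @param library a [ComponentLibrary-class].
#' @param includeOffset,normalizeComponents passed to [nnlsFit()].
#' @return data.frame in long format with columns `sample_id`, `class`,
#'   `component`, `coefficient`, `residual_norm`.
#' @export
unmixCohort <- function(cohort, library, includeOffset = TRUE,
                        normalizeComponents = TRUE) {
  stopifnot(is(cohort, "RamanCohort"), is(library, "ComponentLibrary"))
  if (ncol(cohort) < 1L) nrStop("cohort is empty")
  axis <- wavenumbers(cohort)
  if (length(axis) != length(library@axis) ||
      !isTRUE(all.equal(as.numeric(axis), library@axis)))
    nrStop("cohort and library must share an identical axis")
  S <- spectraMatrix(cohort)
  labels <- classLabels(cohort)
  ids <- SummarizedExperiment::colData(cohort)$sample_id
  if (is.null(ids)) ids <- sprintf("s%03d", seq_len(ncol(S)))
  rows <- lapply(seq_len(ncol(S)), function(s) {
    fit <- nnlsFit(ramanSpectrum(axis, S[, s]), library,
                   includeOffset = includeOffset,
                   normalizeComponents = normalizeComponents)
    data.frame(sample_id = ids[s], class = labels[s],
               component = names(fit@coefficients),
               coefficient = unname(fit@coefficients),
               residual_norm = fit@residualNorm)
  })
  do.call(rbind, rows)
}

#' Fit component spectra to a class's SOMDI vector
#'
#' NNLS of the library onto the positive part of the class's discriminant
#' vector — a physically realistic decomposition, since measured tissue
#' spectra are mixtures of positive component contributions. Large
#' coefficients indicate the components driving that class's activation.
#'
#' @param somdi a [SOMDIResult-class] on the library axis.
#' @param library a [ComponentLibrary-class].
#' @param class class name.
#' @param normalizeComponents passed to [nnlsFit()].
#' @return an [UnmixResult-class].
#' @export
fitSomdiComponents <- function(somdi, library, class,
                               normalizeComponents = TRUE) {
  stopifnot(is(somdi, "SOMDIResult"), is(library, "ComponentLibrary"))
  d <- somdiSpectrum(somdi, class)@intensity
  pos <- pmax(d, 0)
  if (all(pos <= 0))
    nrStop("discriminant vector has no positive part to fit",
           "nrDegenerateInput")
  nnlsFit(ramanSpectrum(somdi@axis, pos), library, includeOffset = FALSE,
          normalizeComponents = normalizeComponents)
}

#' Compare unmixing coefficients across groups
#'
#' Per-component one-way ANOVA of the fitted coefficients across classes.
#' No multiple-testing correction is applied by default; Bonferroni is
#' available. A component with zero variance within and between groups is
#' reported as F = 0, p = 1.
#'
#' @param results long-format data.frame as returned by [unmixCohort()]
#'   (columns `class`, `component`, `coefficient`).
#' @param correction `"none"` (default) or `"bonferroni"`.
#' @return a [GroupComparison-class].
#' @export
groupCompare <- function(results, correction = c("none", "bonferroni")) {
  correction <- match.arg(correction)
  needed <- c("class", "component", "coefficient")
  if (!all(needed %in% colnames(results)))
    nrStop("results must contain class, component and coefficient columns")
  groups <- unique(as.character(results$class))
  if (length(groups) < 2L) nrStop("at least two groups required")
  counts <- table(results$class, results$component)
  if (any(counts < 2L)) nrStop("every group needs at least two samples")
  comps <- unique(as.character(results$component))
  means <- matrix(NA_real_, length(comps), length(groups),
                  dimnames = list(comps, groups))
  vars <- means
  stats <- data.frame(component = comps, F = NA_real_, p = NA_real_)
  for (i in seq_along(comps)) {
    sub <- results[results$component == comps[i], ]
    for (g in groups) {
      v <- sub$coefficient[sub$class == g]
      means[i, g] <- mean(v)
      vars[i, g] <- stats::var(v)
    }
    if (stats::var(sub$coefficient) < .Machine$double.eps) {
      stats$F[i] <- 0; stats$p[i] <- 1
    } else if (all(vars[i, ] < .Machine$double.eps)) {
      # groups internally constant but different: infinite evidence
      stats$F[i] <- Inf; stats$p[i] <- 0
    } else {
      tt <- stats::oneway.test(coefficient ~ class, data = sub,
                               var.equal = TRUE)
      stats$F[i] <- unname(tt$statistic)
      stats$p[i] <- unname(tt$p.value)
    }
  }
  if (correction == "bonferroni")
    stats$p <- stats::p.adjust(stats$p, method = "bonferroni")
  new("GroupComparison", groups = groups, means = means, variances = vars,
      statistics = stats)
}

#' Extract the ANOVA table of a group comparison
#' @param x a [GroupComparison-class].
#' @return data.frame with columns `component`, `F`, `p`.
#' @export
comparisonStats <- function(x) {
  stopifnot(is(x, "GroupComparison"))
  x@statistics
}

#' Group means of a comparison
#' @param x a [GroupComparison-class].
#' @return matrix (components x groups).
#' @export
comparisonMeans <- function(x) {
  stopifnot(is(x, "GroupComparison"))
  x@means
}

setMethod("show", "GroupComparison", function(object) {
  cat(sprintf("GroupComparison across %s:\n",
              paste(object@groups, collapse = ", ")))
  print(cbind(round(object@means, 4),
              F = round(object@statistics$F, 3),
              p = signif(object@statistics$p, 3)))
  invisible(object)
})
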