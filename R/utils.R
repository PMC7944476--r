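# Classed error conditions so callers (and the CLI) can distinguish
# configuration, parsing, range and numeric failures.
nrStop <- function(msg, class = "nrInvalidInput", call. = FALSE) {
  stop(structure(
    class = c(class, "nrError", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

isStrictlyIncreasing <- function(x) {
  length(x) >= 1L && !anyNA(x) && (length(x) == 1L || all(diff(x) > 0))
}

# Robust intensity scale of a spectrum: MAD about the median, floored so a
# flat or near-flat spectrum still yields a usable positive scale.
robustScale <- function(x) {
  max(stats::mad(x), 1e-3 * max(abs(x)), .Machine$double.eps)
}

# Trapezoidal integral on a (possibly non-uniform) axis.
trapezoid <- function(axis, y) {
  n <- length(axis)
  if (n < 2L) return(0)
  sum(diff(axis) * (y[-1] + y[-n]) / 2)
}

#' Stratified train/test split
#'
#' Splits sample indices into train and test sets with per-class proportions
#' preserved. Each class keeps at least one training sample; classes with a
#' single member go entirely to the training set.
#'
#' @param labels character or factor vector of class labels.
#' @param trainFraction fraction of each class assigned to the training set.
#' @param seed integer seed for the shuffling.
#' @return list with integer index vectors `train` and `test`.
#' @export
stratifiedSplit <- function(labels, trainFraction = 0.7, seed = 1L) {
  if (trainFraction <= 0 || trainFraction >= 1)
    nrStop("trainFraction must be in (0, 1)", "nrConfigError")
  labels <- as.character(labels)
  set.seed(as.integer(seed))
  train <- integer(0)
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    nTrain <- max(1L, round(trainFraction * length(idx)))
    nTrain <- min(nTrain, length(idx))
    train <- c(train, sample(idx)[seq_len(nTrain)])
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(labels), train))
}
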