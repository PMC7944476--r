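# Shared fixtures: small axes, band libraries and cohorts built in code.

shortAxis <- function(n = 50) seq(1000, 1098, length.out = n)

# Minimal two-component library on a short axis for unmixing oracles.
twoCompLibrary <- function(axis = shortAxis()) {
  generateComponentLibrary(list(
    A = bandSpec(1020, 14, 1.0, 0.5),
    B = bandSpec(1070, 14, 1.0, 0.5)
  ), axis)
}

threeCompLibrary <- function(axis = shortAxis()) {
  generateComponentLibrary(list(
    A = bandSpec(1015, 12, 1.0, 0.5),
    B = bandSpec(1050, 12, 1.0, 0.5),
    C = bandSpec(1085, 12, 1.0, 0.5)
  ), axis)
}

# Library whose five components are the five isolated marker bands; used
# where per-band ground truth must be recoverable through the full chain.
markerBandLibrary <- function(axis = defaultAxis()) {
  generateComponentLibrary(list(
    phe = bandSpec(1003, 16, 1.0, 0.5),
    cc = bandSpec(1266, 20, 1.0, 0.5),
    amide3 = bandSpec(1337, 20, 1.0, 0.5),
    ch2 = bandSpec(1447, 20, 1.0, 0.5),
    amide1 = bandSpec(1660, 22, 1.0, 0.5)
  ), axis)
}

# Two-class control/sTBI config on the default brain library.
twoClassConfig <- function(nPerClass = 20L, noiseSD = 0.01, spikeRate = 0.2,
                           nAccumulations = 15L, seed = 1L,
                           cardiolipinFactor = 0.5, coefficientCV = 0.15,
                           baselineAmplitude = 0.5) {
  mc <- defaultMeanCoefficients()[c("control", "sTBI"), ]
  mc["sTBI", "cardiolipin"] <- mc["control", "cardiolipin"] * cardiolipinFactor
  cohortConfig(nPerClass = nPerClass, meanCoefficients = mc,
               coefficientCV = coefficientCV, noiseSD = noiseSD,
               spikeRate = spikeRate, nAccumulations = nAccumulations,
               baselineAmplitude = baselineAmplitude, seed = seed)
}

# Column-normalize a spectrum matrix to unit Euclidean norm.
unitColumns <- function(S) apply(S, 2, function(y) y / sqrt(sum(y^2)))

# Exhaustive non-negative grid-search NNLS oracle (2 components, quadratic
# form evaluated over the full grid; independent of the active-set path).
gridSearchNNLS2 <- function(A, y, upper = 1.5, step = 1e-3) {
  g <- seq(0, upper, by = step)
  AtA <- crossprod(A)
  Aty <- crossprod(A, y)
  E <- outer(g^2 * AtA[1, 1] - 2 * g * Aty[1], g^2 * AtA[2, 2] - 2 * g * Aty[2], "+") +
    2 * AtA[1, 2] * outer(g, g)
  idx <- arrayInd(which.min(E), dim(E))
  c(g[idx[1]], g[idx[2]])
}

# Coarse-to-fine grid oracle for 3 components (final local step 1e-3).
gridSearchNNLS3 <- function(A, y, upper = 1.5) {
  best <- NULL
  refine <- function(center, half, step) {
    gs <- lapply(center, function(c0)
      seq(max(0, c0 - half), min(upper, c0 + half), by = step))
    grid <- as.matrix(expand.grid(gs))
    R <- y - A %*% t(grid)
    grid[which.min(colSums(R^2)), ]
  }
  c0 <- refine(rep(upper / 2, 3), upper / 2, 0.05)
  c1 <- refine(c0, 0.06, 5e-3)
  refine(c1, 6e-3, 1e-3)
}

# Karush-Kuhn-Tucker optimality check for an NNLS solution x of min ||Ax-y||.
kktHolds <- function(A, y, x, tol = 1e-6) {
  r <- y - A %*% x
  g <- as.numeric(crossprod(A, r))  # positive gradient => coefficient wants to grow
  scale <- max(abs(g), 1)
  active <- x > tol
  all(abs(g[active]) <= 1e-6 * scale + 1e-8) && all(g[!active] <= 1e-6 * scale + 1e-8)
}
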