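test_that("identity fits: a pure component yields coefficient one, others zero", {
  lib <- twoCompLibrary()
  ax <- wavenumbers(lib)
  s <- ramanSpectrum(ax, componentMatrix(lib)[, "A"])
  fit <- nnlsFit(s, lib, includeOffset = FALSE)
  expect_equal(unname(coef(fit)["A"]), 1, tolerance = 1e-8)
  expect_equal(unname(coef(fit)["B"]), 0, tolerance = 1e-8)
  expect_lt(fit@residualNorm, 1e-8)
})

test_that("noiseless mixtures are recovered exactly", {
  lib <- twoCompLibrary()
  ax <- wavenumbers(lib)
  A <- componentMatrix(lib)
  y <- 0.7 * A[, "A"] + 0.3 * A[, "B"]
  fit <- nnlsFit(ramanSpectrum(ax, y), lib, includeOffset = FALSE)
  expect_equal(unname(coef(fit)), c(0.7, 0.3), tolerance = 1e-6)
})

test_that("non-negativity binds on a pure negative spectrum", {
  lib <- twoCompLibrary()
  ax <- wavenumbers(lib)
  y <- -componentMatrix(lib)[, "A"]
  fit <- nnlsFit(ramanSpectrum(ax, y), lib, includeOffset = FALSE)
  expect_true(all(coef(fit) == 0))
  expect_equal(fit@residualNorm, sqrt(sum(y^2)), tolerance = 1e-10)
})

test_that("fits satisfy the KKT optimality conditions and scale equivariance", {
  set.seed(30)
  lib <- threeCompLibrary()
  ax <- wavenumbers(lib)
  A <- componentMatrix(lib)
  for (i in 1:10) {
    cf <- runif(3, 0, 1) * sample(c(1, 1, 0))[1:3]
    y <- as.numeric(A %*% cf) + rnorm(length(ax), 0, 0.02)
    fit <- nnlsFit(ramanSpectrum(ax, y), lib, includeOffset = FALSE,
                   normalizeComponents = FALSE)
    expect_true(kktHolds(A, y, coef(fit)))
    fitK <- nnlsFit(ramanSpectrum(ax, 3 * y), lib, includeOffset = FALSE,
                    normalizeComponents = FALSE)
    expect_equal(unname(coef(fitK)), 3 * unname(coef(fit)), tolerance = 1e-6)
  }
})

test_that("active-set solutions match the exhaustive grid-search oracle", {
  set.seed(31)
  lib2 <- twoCompLibrary()
  A2 <- componentMatrix(lib2)
  ax <- wavenumbers(lib2)
  for (i in 1:5) {
    truth <- runif(2, 0, 1.2)
    if (i == 3) truth[2] <- 0  # boundary case
    y <- as.numeric(A2 %*% truth) + rnorm(length(ax), 0, 0.02)
    fit <- nnlsFit(ramanSpectrum(ax, y), lib2, includeOffset = FALSE,
                   normalizeComponents = FALSE)
    oracle <- gridSearchNNLS2(A2, y)
    expect_lt(max(abs(unname(coef(fit)) - oracle)), 2e-3)
  }
  lib3 <- threeCompLibrary()
  A3 <- componentMatrix(lib3)
  truth <- c(0.55, 0, 0.85)
  y <- as.numeric(A3 %*% truth) + rnorm(length(ax), 0, 0.01)
  fit <- nnlsFit(ramanSpectrum(ax, y), lib3, includeOffset = FALSE,
                 normalizeComponents = FALSE)
  oracle <- gridSearchNNLS3(A3, y)
  expect_lt(max(abs(unname(coef(fit)) - unname(oracle))), 2e-3)
})

test_that("axis mismatches and degenerate bases are rejected", {
  lib <- twoCompLibrary()
  expect_error(nnlsFit(ramanSpectrum(seq(2000, 2049), runif(50)), lib),
               class = "nrInvalidInput")
  zlib <- lib
  zlib@components[, 2] <- 0
  expect_error(nnlsFit(ramanSpectrum(wavenumbers(lib),
                                     componentMatrix(lib)[, 1]), zlib),
               class = "nrDegenerateBasis")
})

test_that("zero-noise cohorts are unmixed to the exact truth coefficients", {
  lib <- defaultComponentLibrary()
  cfg <- twoClassConfig(nPerClass = 3L, noiseSD = 0, spikeRate = 0,
                        nAccumulations = 2L, coefficientCV = 0.1,
                        baselineAmplitude = 0, seed = 23L)
  coh <- generateCohort(cfg, lib)
  res <- unmixCohort(coh, lib)
  tr <- truthCoefficients(coh)
  for (s in seq_len(nrow(tr))) {
    got <- res$coefficient[res$sample_id == rownames(tr)[s]]
    names(got) <- res$component[res$sample_id == rownames(tr)[s]]
    expect_equal(got[colnames(tr)], tr[s, ], tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
})

test_that("coefficient recovery error shrinks as noise goes to zero", {
  lib <- defaultComponentLibrary()
  rmse <- vapply(c(0.02, 0.005, 0), function(sd0) {
    cfg <- twoClassConfig(nPerClass = 5L, noiseSD = sd0, spikeRate = 0,
                          nAccumulations = 5L, coefficientCV = 0.1,
                          baselineAmplitude = 0, seed = 29L)
    coh <- generateCohort(cfg, lib)
    res <- unmixCohort(coh, lib)
    tr <- truthCoefficients(coh)
    wide <- matrix(res$coefficient, ncol = ncol(tr), byrow = TRUE,
                   dimnames = list(NULL, res$component[seq_len(ncol(tr))]))
    sqrt(mean((wide[, colnames(tr)] - tr)^2))
  }, numeric(1))
  expect_true(all(diff(rmse) < 0))
  expect_lt(rmse[3], 1e-8)
})

test_that("cardiolipin depletion shows up in the fitted group means", {
  lib <- defaultComponentLibrary()
  cfg <- twoClassConfig(nPerClass = 8L, noiseSD = 0.01, spikeRate = 0,
                        nAccumulations = 3L, baselineAmplitude = 0, seed = 37L)
  coh <- generateCohort(cfg, lib)
  res <- unmixCohort(coh, lib)
  card <- res[res$component == "cardiolipin", ]
  expect_lt(mean(card$coefficient[card$class == "sTBI"]),
            mean(card$coefficient[card$class == "control"]))
})

test_that("group comparison: null p-values behave, separation is detected, degenerate data yield F=0", {
  # identical-distribution null: p > 0.05 in at least 90% of replicates
  set.seed(41)
  rejections <- vapply(1:100, function(i) {
    d <- data.frame(class = rep(c("g1", "g2"), each = 10),
                    component = "c",
                    coefficient = rnorm(20, 1, 0.2))
    comparisonStats(groupCompare(d))$p < 0.05
  }, logical(1))
  expect_gte(mean(!rejections), 0.9)

  # 3-sigma mean separation at n = 10 per group is significant
  set.seed(42)
  d <- data.frame(class = rep(c("g1", "g2"), each = 10), component = "c",
                  coefficient = c(rnorm(10, 1, 0.1), rnorm(10, 1.3, 0.1)))
  expect_lt(comparisonStats(groupCompare(d))$p, 0.05)

  # all-identical data: F = 0, p = 1
  d0 <- data.frame(class = rep(c("g1", "g2"), each = 3), component = "c",
                   coefficient = rep(2, 6))
  st <- comparisonStats(groupCompare(d0))
  expect_identical(st$F, 0)
  expect_identical(st$p, 1)

  expect_error(groupCompare(data.frame(class = c("a", "a", "b"),
                                       component = "c",
                                       coefficient = 1:3)),
               class = "nrInvalidInput")
})
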