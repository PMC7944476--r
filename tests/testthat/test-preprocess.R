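test_that("spike-free stacks are passed through as the plain accumulation mean", {
  set.seed(4)
  stack <- matrix(rnorm(8 * 200, mean = 10), nrow = 8)
  out <- removeCosmicRays(stack)
  expect_equal(as.numeric(out), colMeans(stack), tolerance = 1e-12)
  expect_equal(attr(out, "nSpikes"), 0)
})

test_that("an isolated spike in a constant stack is fully repaired", {
  stack <- matrix(5, nrow = 6, ncol = 100)
  stack[3, 40] <- 500
  out <- removeCosmicRays(stack)
  # expected: flagged cell replaced by the median of the other accumulations
  expect_equal(as.numeric(out), rep(5, 100), tolerance = 1e-12)
  expect_equal(attr(out, "nSpikes"), 1)
})

test_that("cleaned synthetic stacks stay within 5 noise SDs of the clean truth", {
  noiseSD <- 0.01
  cfg <- twoClassConfig(nPerClass = 3L, noiseSD = noiseSD, spikeRate = 1,
                        nAccumulations = 15L, seed = 13L)
  coh <- generateCohort(cfg)
  clean <- S4Vectors::metadata(coh)$clean
  for (s in seq_len(ncol(coh))) {
    out <- removeCosmicRays(accumulationStack(coh, s))
    expect_lt(max(abs(as.numeric(out) - clean[, s])), 5 * noiseSD)
  }
})

test_that("cosmic-ray removal is idempotent on the cleaned stack", {
  set.seed(8)
  stack <- matrix(rnorm(10 * 300, mean = 2, sd = 0.05), nrow = 10)
  stack[2, 17] <- 30
  stack[7, 150] <- 55
  once <- removeCosmicRays(stack, collapse = FALSE)
  twice <- removeCosmicRays(once, collapse = FALSE)
  expect_equal(unclass(twice), unclass(once), ignore_attr = TRUE)
  expect_equal(attr(twice, "nSpikes"), 0)
})

test_that("single accumulations fall back to neighbour interpolation with a warning", {
  y <- rep(1, 200)
  y[90] <- 100
  expect_warning(out <- removeCosmicRays(y), "single accumulation")
  expect_lt(max(abs(as.numeric(out) - 1)), 1e-8)
  expect_error(removeCosmicRays(list(rnorm(5), rnorm(6))),
               class = "nrInvalidInput")
})

test_that("baseline subtraction leaves an all-zero spectrum untouched", {
  ax <- defaultAxis()
  out <- subtractBaseline(ramanSpectrum(ax, numeric(length(ax))))
  expect_equal(max(abs(intensities(out))), 0, tolerance = 1e-10)
})

test_that("a pure smooth baseline is absorbed almost completely", {
  ax <- defaultAxis()
  base <- fluorescenceBaseline(ax, amplitude = 0.8, decay = 650)
  out <- suppressWarnings(subtractBaseline(ramanSpectrum(ax, base)))
  rms <- sqrt(mean(intensities(out)^2))
  expect_lt(rms, 0.02 * 0.8)
})

test_that("peak heights of isolated bands survive baseline subtraction within 5%", {
  ax <- defaultAxis()
  bands <- c(1003, 1266, 1337, 1447, 1660)
  amps <- c(0.8, 0.6, 0.5, 1.0, 0.9)
  peaks <- Reduce(`+`, Map(function(c, a) pseudoVoigt(ax, c, 20, a, 0.5),
                           bands, amps))
  set.seed(2)
  y <- peaks + fluorescenceBaseline(ax, 0.5) + rnorm(length(ax), 0, 0.005)
  rec <- suppressWarnings(subtractBaseline(ramanSpectrum(ax, y)))
  truthSp <- ramanSpectrum(ax, peaks)
  for (b in bands)
    expect_lt(abs(peakHeight(rec, b) / peakHeight(truthSp, b) - 1), 0.05)
})

test_that("baseline subtraction commutes with intensity scaling", {
  ax <- defaultAxis()
  set.seed(6)
  y <- pseudoVoigt(ax, 1266, 20, 0.6) + pseudoVoigt(ax, 1660, 24, 1) +
    fluorescenceBaseline(ax, 0.5) + rnorm(length(ax), 0, 0.01)
  r1 <- suppressWarnings(subtractBaseline(ramanSpectrum(ax, y)))
  r2 <- suppressWarnings(subtractBaseline(ramanSpectrum(ax, 4.2 * y)))
  expect_equal(intensities(r2), 4.2 * intensities(r1), tolerance = 1e-6)
})

test_that("resampling: identity, midpoint mean, truncation bounds and range error", {
  ax <- seq(600, 1800, by = 1)
  set.seed(3)
  s <- ramanSpectrum(ax, rnorm(length(ax)))
  expect_equal(intensities(resampleTruncate(s, ax)), intensities(s))

  mid <- resampleTruncate(s, c(700.5, 900.5))
  expect_equal(intensities(mid)[1],
               mean(intensities(s)[ax %in% c(700, 701)]), tolerance = 1e-12)

  full <- ramanSpectrum(probeAxis(), rep(1, length(probeAxis())))
  tr <- resampleTruncate(full, seq(600, 1800, by = 1))
  expect_identical(range(wavenumbers(tr)), c(600, 1800))

  expect_error(resampleTruncate(tr, seq(500, 900, by = 1)), class = "nrRangeError")
})

test_that("resampling fine then back reproduces the original within interpolation error", {
  ax <- seq(600, 1800, by = 2)
  y <- pseudoVoigt(ax, 1266, 24, 1) + pseudoVoigt(ax, 1447, 26, 0.8)
  s <- ramanSpectrum(ax, y)
  fine <- resampleTruncate(s, seq(600, 1800, by = 0.5))
  back <- resampleTruncate(fine, ax)
  expect_lt(max(abs(intensities(back) - y)), 1e-10)  # grid points are preserved
})

test_that("normalization modes behave as defined and reject all-zero input", {
  ax <- seq(600, 700, by = 1)
  s <- ramanSpectrum(ax, runif(length(ax), 0.5, 2))
  expect_identical(normalizeSpectrum(s, "none"), s)
  expect_equal(sum(intensities(normalizeSpectrum(s, "vector"))^2), 1,
               tolerance = 1e-12)
  av <- normalizeSpectrum(s, "area")
  expect_equal(sum(diff(ax) * (intensities(av)[-1] + intensities(av)[-length(ax)]) / 2),
               1, tolerance = 1e-12)
  s7 <- ramanSpectrum(ax, 7 * intensities(s))
  expect_equal(intensities(normalizeSpectrum(s7, "vector")),
               intensities(normalizeSpectrum(s, "vector")), tolerance = 1e-12)
  zero <- ramanSpectrum(ax, numeric(length(ax)))
  expect_error(normalizeSpectrum(zero, "vector"), class = "nrDegenerateInput")
})

test_that("peak height returns band amplitude, zero for flat input, and the windowed max", {
  ax <- seq(600, 1800, by = 1)
  s <- ramanSpectrum(ax, pseudoVoigt(ax, 1447, 18, 2.2))
  expect_equal(peakHeight(s, 1447), 2.2, tolerance = 1e-6)
  expect_equal(peakHeight(ramanSpectrum(ax, numeric(length(ax))), 1447), 0)
  # two overlapping bands: equals the channel-wise max of the summed profile
  y <- pseudoVoigt(ax, 1440, 30, 1) + pseudoVoigt(ax, 1460, 30, 0.9)
  s2 <- ramanSpectrum(ax, y)
  win <- ax >= 1440 & ax <= 1460
  expect_equal(peakHeight(s2, 1450, 10), max(y[win]))
  expect_error(peakHeight(s2, 300), class = "nrRangeError")
})

test_that("band ratio: symmetry at equal amplitudes and monotone growth under depletion", {
  ax <- defaultAxis()
  y <- pseudoVoigt(ax, 1447, 20, 1.3) + pseudoVoigt(ax, 1660, 20, 1.3)
  expect_equal(bandRatio(ramanSpectrum(ax, y), 1447, 1660), 1, tolerance = 1e-6)

  lib <- defaultComponentLibrary()
  A <- componentMatrix(lib)
  mc <- defaultMeanCoefficients()["control", ]
  ratios <- vapply(c(1.0, 0.7, 0.4), function(f) {
    cf <- mc; cf["cardiolipin"] <- mc["cardiolipin"] * f
    bandRatio(ramanSpectrum(wavenumbers(lib), as.numeric(A %*% cf)), 1447, 1660)
  }, numeric(1))
  expect_true(all(diff(ratios) > 0))

  expect_error(bandRatio(ramanSpectrum(ax, numeric(length(ax))), 1447, 1660),
               class = "nrDegenerateInput")
})

test_that("the full preprocessing chain recovers marker-band peak heights within 5%", {
  lib <- markerBandLibrary()
  mc <- rbind(control = c(phe = 0.8, cc = 0.7, amide3 = 0.5, ch2 = 1.0, amide1 = 0.9),
              sTBI = c(phe = 0.8, cc = 0.4, amide3 = 0.5, ch2 = 1.0, amide1 = 0.5))
  cfg <- cohortConfig(nPerClass = 3L, meanCoefficients = mc, noiseSD = 0.008,
                      spikeRate = 0.5, nAccumulations = 10L, seed = 17L)
  coh <- generateCohort(cfg, lib)
  pp <- suppressWarnings(preprocessCohort(coh))
  clean <- S4Vectors::metadata(coh)$clean
  base <- S4Vectors::metadata(coh)$baseline
  ax <- wavenumbers(pp)
  bands <- c(1003, 1266, 1337, 1447, 1660)
  for (s in seq_len(ncol(pp))) {
    rec <- ramanSpectrum(ax, spectraMatrix(pp)[, s])
    tru <- ramanSpectrum(ax, clean[, s] - base)
    for (b in bands)
      expect_lt(abs(peakHeight(rec, b) / peakHeight(tru, b) - 1), 0.05)
  }
})
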