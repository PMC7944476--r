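# BFS over the hex adjacency graph: independent oracle for hexDistance.
bfsHexDistance <- function(a, b, radius = 12) {
  if (all(a == b)) return(0L)
  dirs <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1), c(1, -1), c(-1, 1))
  frontier <- matrix(a, ncol = 2)
  seen <- new.env()
  assign(paste(a, collapse = ","), TRUE, envir = seen)
  d <- 0L
  while (nrow(frontier) > 0 && d <= 2 * radius) {
    d <- d + 1L
    nxt <- NULL
    for (i in seq_len(nrow(frontier))) {
      for (k in 1:6) {
        nb <- frontier[i, ] + dirs[k, ]
        if (all(nb == b)) return(d)
        key <- paste(nb, collapse = ",")
        if (!exists(key, envir = seen) && all(abs(nb) <= radius)) {
          assign(key, TRUE, envir = seen)
          nxt <- rbind(nxt, nb)
        }
      }
    }
    frontier <- if (is.null(nxt)) matrix(numeric(0), ncol = 2) else nxt
  }
  NA_integer_
}

test_that("hex distance: identity, adjacency and agreement with a BFS oracle", {
  expect_identical(hexDistance(c(2, 3), c(2, 3)), 0L)
  dirs <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1), c(1, -1), c(-1, 1))
  for (k in 1:6)
    expect_identical(hexDistance(c(0, 0), dirs[k, ]), 1L)
  set.seed(42)
  for (i in 1:25) {
    a <- sample(-4:4, 2, replace = TRUE)
    b <- sample(-4:4, 2, replace = TRUE)
    expect_identical(hexDistance(a, b), bfsHexDistance(a, b))
  }
  expect_error(hexDistance(c(0.5, 1), c(0, 0)), class = "nrInvalidInput")
})

test_that("training on identical spectra collapses every neuron onto that spectrum", {
  set.seed(1)
  proto <- pseudoVoigt(seq_len(80), 40, 10, 1)
  X <- matrix(rep(proto, 12), ncol = 12)
  model <- trainSOM(X, labels = rep("a", 12),
                    somTrainConfig(gridWidth = 4L, gridHeight = 4L,
                                   nEpochs = 60L, seed = 2L))
  dev <- apply(model@weights, 1, function(w) max(abs(w - proto)))
  expect_lt(max(dev), 1e-3)
})

test_that("training is deterministic given config and seed", {
  set.seed(10)
  X <- matrix(runif(60 * 20), nrow = 60)
  labels <- rep(c("a", "b"), each = 10)
  cfg <- somTrainConfig(gridWidth = 5L, gridHeight = 4L, nEpochs = 20L, seed = 3L)
  m1 <- trainSOM(X, labels, cfg)
  m2 <- trainSOM(X, labels, cfg)
  expect_identical(m1@weights, m2@weights)
  expect_identical(m1@labelWeights, m2@labelWeights)
})

test_that("label weights stay non-negative with row sums bounded by one", {
  set.seed(11)
  X <- matrix(runif(40 * 30), nrow = 40)
  labels <- rep(c("a", "b", "c"), each = 10)
  model <- trainSOM(X, labels, somTrainConfig(gridWidth = 6L, gridHeight = 6L,
                                              nEpochs = 30L, seed = 4L))
  expect_true(all(model@labelWeights >= 0))
  expect_true(all(rowSums(model@labelWeights) <= 1 + 1e-12))
})

test_that("one training step updates neurons with magnitude decaying in hex distance", {
  set.seed(12)
  p <- 20
  m <- 25
  coords <- neuroraman:::hexGridCoords(5L, 5L)
  hexd <- neuroraman:::hexDistanceMatrix(coords)
  W0 <- matrix(runif(m * p), nrow = m)
  x <- runif(p)
  res <- neuroraman:::som_train_cpp(
    Xt = matrix(x, ncol = 1), onehot = matrix(1, 1, 1), order = 0L,
    W0t = t(W0), L0 = matrix(0, m, 1), hexd = hexd,
    lr0 = 0.3, lrEnd = 0.3, sigma0 = 2, sigmaEnd = 2, cosine = FALSE)
  W1 <- t(res$weights)
  bmu <- which.min(colSums((t(W0) - x)^2))
  # per-neuron update fraction lr * exp(-d^2 / (2 sigma^2))
  frac <- vapply(seq_len(m), function(u) {
    num <- W1[u, ] - W0[u, ]
    den <- x - W0[u, ]
    if (max(abs(num)) == 0) 0 else stats::median(num / den)
  }, numeric(1))
  ord <- order(hexd[, bmu])
  expect_true(all(diff(frac[ord]) <= 1e-12))
  expect_equal(frac[bmu], 0.3, tolerance = 1e-12)
})

test_that("BMU mapping matches brute-force nearest-neighbour search", {
  set.seed(13)
  X <- matrix(runif(30 * 24), nrow = 30)
  labels <- rep(c("a", "b"), each = 12)
  model <- trainSOM(X, labels, somTrainConfig(gridWidth = 6L, gridHeight = 5L,
                                              nEpochs = 15L, seed = 7L))
  Q <- matrix(runif(30 * 100), nrow = 30)
  pos <- mapPositions(model, Q)
  for (i in seq_len(ncol(Q))) {
    d <- colSums((t(model@weights) - Q[, i])^2)
    expect_identical(pos$neuron[i], which.min(d))
  }
})

test_that("a spectrum equal to a neuron weight maps to that neuron; ties break low", {
  W <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(0, 1, 0))
  model <- new("SOMModel", gridWidth = 2L, gridHeight = 2L,
               coords = neuroraman:::hexGridCoords(2L, 2L),
               weights = W, labelWeights = matrix(0.4, 4, 2,
                 dimnames = list(NULL, c("a", "b"))),
               classNames = c("a", "b"), axis = numeric(0),
               trainedIterations = 1L, config = list(distance = "euclidean"),
               seed = 1L)
  pos <- mapPositions(model, matrix(c(0, 1, 0), ncol = 1))
  expect_identical(pos$neuron, 2L)  # neurons 2 and 4 tie; lowest index wins
})

test_that("classification returns the BMU's arg-max label with normalized confidence", {
  W <- rbind(c(1, 0), c(0, 1))
  lw <- rbind(c(0.6, 0.2), c(0.25, 0.25))
  colnames(lw) <- c("a", "b")
  model <- new("SOMModel", gridWidth = 2L, gridHeight = 1L,
               coords = neuroraman:::hexGridCoords(2L, 1L),
               weights = W, labelWeights = lw, classNames = c("a", "b"),
               axis = numeric(0), trainedIterations = 1L,
               config = list(distance = "euclidean"), seed = 1L)
  out <- classifySpectra(model, matrix(c(1, 0, 0, 1), nrow = 2))
  expect_identical(out$class, c("a", "a"))  # uniform neuron ties to first class
  expect_equal(out$confidence, c(0.75, 0.5))
  untrained <- model
  untrained@trainedIterations <- 0L
  expect_error(classifySpectra(untrained, matrix(c(1, 0), ncol = 1)),
               class = "nrStateError")
})

test_that("well-separated synthetic classes occupy disjoint map regions", {
  cfg <- twoClassConfig(nPerClass = 12L, noiseSD = 0.005, spikeRate = 0,
                        nAccumulations = 3L, baselineAmplitude = 0, seed = 19L)
  coh <- generateCohort(cfg)
  Sn <- unitColumns(spectraMatrix(coh))
  labels <- classLabels(coh)
  model <- trainSOM(Sn, labels, somTrainConfig(gridWidth = 8L, gridHeight = 8L,
                                               nEpochs = 60L, seed = 8L))
  pos <- mapPositions(model, Sn)
  neuronsA <- unique(pos$neuron[labels == "control"])
  neuronsB <- unique(pos$neuron[labels == "sTBI"])
  expect_length(intersect(neuronsA, neuronsB), 0)
})

test_that("SOM models survive a JSON save/load round trip", {
  set.seed(14)
  X <- matrix(runif(15 * 10), nrow = 15)
  model <- trainSOM(X, rep(c("a", "b"), each = 5),
                    somTrainConfig(gridWidth = 3L, gridHeight = 3L,
                                   nEpochs = 10L, seed = 9L),
                    axis = seq_len(15))
  path <- tempfile(fileext = ".json")
  saveSOMModel(model, path)
  back <- readSOMModel(path)
  expect_equal(back@weights, model@weights, ignore_attr = TRUE)
  expect_equal(unname(back@labelWeights), unname(model@labelWeights))
  expect_identical(back@classNames, model@classNames)
  expect_equal(back@axis, model@axis)
  p1 <- classifySpectra(model, X)
  p2 <- classifySpectra(back, X)
  expect_identical(p1$class, p2$class)
})
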