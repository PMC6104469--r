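# Fast planted-signal design shared by several blocks: y is a linear
# function of the first feature(s), the rest are noise columns.
plantedData <- function(n = 200, p = 8, nSignal = 1, noise = 0,
                        seed = 31) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, sprintf("x%d", seq_len(p))))
  y <- rowSums(X[, seq_len(nSignal), drop = FALSE]) +
       rnorm(n, 0, noise)
  list(X = X, y = y)
}

test_that("evaluation metrics match hand computations", {
  r <- evalMetrics(c(1, 3), c(1, 2))
  expect_equal(r@mae, 0.5)
  expect_equal(r@rmse, sqrt(0.5), tolerance = 1e-12)
  perfect <- evalMetrics(1:10, 1:10)
  expect_equal(perfect@mae, 0)
  expect_equal(perfect@rmse, 0)
  expect_equal(perfect@r2, 1)
  # a constant offset leaves Pearson R2 at 1 but shows up in MAE
  shifted <- evalMetrics(1:10, 1:10 + 0.7)
  expect_equal(shifted@r2, 1)
  expect_equal(shifted@mae, 0.7)
  # coefficient-of-determination variant penalizes the offset
  expect_lt(evalMetrics(1:10, 1:10 + 0.7, r2Method = "cod")@r2, 1)
  expect_error(evalMetrics(1:3, 1:2), "differ in length")
})

test_that("MAE never exceeds RMSE and Pearson R2 stays in [0, 1]", {
  set.seed(32)
  for (rep in 1:20) {
    y <- rnorm(30)
    yhat <- rnorm(30)
    r <- evalMetrics(y, yhat)
    expect_lte(r@mae, r@rmse + 1e-12)
    expect_gte(r@r2, 0)
    expect_lte(r@r2, 1)
  }
})

test_that("random splits are disjoint, exhaustive, sized and reproducible", {
  s <- randomSplit(as.list(1:10), 0.3, seed = 5)
  expect_length(s$train, 7)
  expect_length(s$test, 3)
  expect_setequal(c(s$trainIdx, s$testIdx), 1:10)
  s2 <- randomSplit(as.list(1:10), 0.3, seed = 5)
  expect_identical(s$trainIdx, s2$trainIdx)
  # the database-scale partition arithmetic: 10071 -> 6703 / 3368
  big <- randomSplit(seq_len(10071), 3368 / 10071, seed = 1)
  expect_length(big$trainIdx, 6703)
  expect_length(big$testIdx, 3368)
  expect_error(randomSplit(list(1), 0.3, seed = 1), "at least 2")
})

test_that("the forest recovers a planted linear signal out of bag", {
  d <- plantedData(n = 200, p = 8)
  b <- trainRF(d$X, d$y, nTrees = 300, seed = 41)
  expect_gte(b@oobReport@r2, 0.9)
  expect_identical(b@oobReport@context, "oob")
  expect_identical(b@featureManifest, colnames(d$X))
  # scrambling the labels destroys the out-of-bag signal
  set.seed(42)
  bScr <- trainRF(d$X, sample(d$y), nTrees = 300, seed = 41)
  expect_lte(bScr@oobReport@r2, 0.1)
})

test_that("training is deterministic per seed and validates its inputs", {
  d <- plantedData(n = 80, p = 5)
  b1 <- trainRF(d$X, d$y, nTrees = 100, seed = 7)
  b2 <- trainRF(d$X, d$y, nTrees = 100, seed = 7)
  expect_identical(predict(b1, d$X), predict(b2, d$X))
  expect_identical(b1@hyperparams$mtry, b2@hyperparams$mtry)
  expect_error(trainRF(d$X, rep(1, nrow(d$X))), "constant")
  Xna <- d$X; Xna[1, 1] <- NA
  expect_error(trainRF(Xna, d$y), "missing values")
})

test_that("mtry is tuned by out-of-bag RMSE over the documented grid", {
  d <- plantedData(n = 150, p = 9)
  b <- trainRF(d$X, d$y, nTrees = 200, seed = 8)
  hp <- b@hyperparams
  expect_identical(hp$mtryGrid,
                   as.integer(sort(unique(floor(c(9 / 3, 3, 9 / 2))))))
  expect_equal(hp$mtry, hp$mtryGrid[which.min(hp$oobRmseGrid)])
})

test_that("permutation importance recovers planted relevant features", {
  d <- plantedData(n = 250, p = 10, nSignal = 3)
  b <- trainRF(d$X, d$y, nTrees = 300, seed = 9)
  expect_setequal(importanceSelect(b, k = 3), c("x1", "x2", "x3"))
  all10 <- importanceSelect(b, k = 10)
  expect_length(all10, 10)
  expect_setequal(all10, colnames(d$X))
  expect_error(importanceSelect(b, k = 11), "exceeds")
})

test_that("prediction refuses feature matrices that break the manifest", {
  d <- plantedData(n = 60, p = 5)
  b <- trainRF(d$X, d$y, nTrees = 100, seed = 3)
  expect_error(predict(b, d$X[, 1:4]), "manifest")
  Xperm <- d$X[, c(2, 1, 3, 4, 5)]
  expect_error(predict(b, Xperm), "manifest")
  expect_error(evaluateModel(b, d$X[, 1:4], d$y[1:60]), "manifest")
})

test_that("OOB error tracks test error on iid data", {
  d <- plantedData(n = 500, p = 5, noise = 0.5, seed = 44)
  idx <- randomSplit(seq_len(500), 0.3, seed = 2)
  b <- trainRF(d$X[idx$trainIdx, ], d$y[idx$trainIdx], nTrees = 300,
               seed = 4)
  testRep <- evaluateModel(b, d$X[idx$testIdx, ], d$y[idx$testIdx])
  ratio <- b@oobReport@rmse / testRep@rmse
  expect_gt(ratio, 0.7)
  expect_lt(ratio, 1.4)
})

test_that("y-randomization separates real signal from scrambled labels", {
  d <- plantedData(n = 240, p = 6, noise = 0.3, seed = 45)
  idx <- randomSplit(seq_len(240), 0.3, seed = 3)
  real <- trainRF(d$X[idx$trainIdx, ], d$y[idx$trainIdx], nTrees = 200,
                  seed = 5)
  realR2 <- evaluateModel(b <- real, d$X[idx$testIdx, ],
                          d$y[idx$testIdx])@r2
  reps <- yRandomization(d$X, d$y, idx$trainIdx, idx$testIdx,
                         nRounds = 5, seed = 6, nTrees = 200,
                         mtryGrid = real@hyperparams$mtry)
  expect_length(reps, 5)
  for (r in reps) {
    expect_identical(r@context, "y_random")
    expect_lt(r@r2, realR2 - 0.5)
  }
})

test_that("dataset summaries report count, mean and MAD of the labels", {
  mols <- lapply(1:4, function(i) {
    m <- Molecule3D(paste0("m", i), "C", matrix(0, 1, 3))
    dmLabel(m) <- c(1, 2, 3, 6)[i]
    m
  })
  s <- datasetSummary(mols)
  expect_equal(s$n, 4)
  expect_equal(s$meanDM, 3)
  expect_equal(s$madDM, mean(abs(c(1, 2, 3, 6) - 3)))
})
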