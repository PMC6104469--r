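# Random-forest regression workflow: train/test splitting, OOB-tuned
# training, permutation-importance selection, evaluation and
# y-randomization.  The forests themselves are grown by the randomForest
# package (500 trees by default); this module owns the tuning, manifest
# discipline and validation protocol around them.

#' Regression metrics for a prediction set
#'
#' MAE = mean |yhat - y|, RMSE = sqrt(mean (yhat - y)^2), and R2 as the
#' squared Pearson correlation between predicted and observed values
#' (\code{r2Method = "pearson"}, the default) or the coefficient of
#' determination 1 - SS_res/SS_tot (\code{"cod"}).
#'
#' @param y observed values.
#' @param yhat predicted values.
#' @param context metric context tag ("oob", "test", "cv", "y_random",
#'   "train").
#' @param r2Method R2 definition, \code{"pearson"} or \code{"cod"}.
#' @return An \linkS4class{EvalReport}.
#' @examples
#' evalMetrics(c(1, 3), c(1, 2))  # MAE 0.5, RMSE ~0.7071
#' @export
evalMetrics <- function(y, yhat, context = "test",
                        r2Method = c("pearson", "cod")) {
  r2Method <- match.arg(r2Method)
  if (length(y) != length(yhat))
    stop("y and yhat differ in length (", length(y), " vs ",
         length(yhat), ")")
  if (!length(y)) stop("empty prediction set")
  err <- yhat - y
  r2 <- if (r2Method == "pearson") {
    if (stats::sd(yhat) == 0 || stats::sd(y) == 0) 0
    else stats::cor(y, yhat)^2
  } else {
    1 - sum(err^2) / sum((y - mean(y))^2)
  }
  new("EvalReport", mae = mean(abs(err)), rmse = sqrt(mean(err^2)),
      r2 = r2, n = length(y), context = context)
}

#' Random train/test split
#'
#' Disjoint, exhaustive partition with \code{round(n * (1 -
#' testFraction))} training records, reproducible per seed.
#'
#' @param records list (e.g. of \linkS4class{Molecule3D}) or a vector to
#'   split.
#' @param testFraction fraction assigned to the test set.
#' @param seed integer seed.
#' @return List with elements \code{train} and \code{test} (same type as
#'   \code{records}) and the index vectors \code{trainIdx},
#'   \code{testIdx}.
#' @export
randomSplit <- function(records, testFraction, seed) {
  n <- length(records)
  if (n < 2) stop("need at least 2 records to split")
  stopifnot(testFraction > 0, testFraction < 1)
  nTrain <- round(n * (1 - testFraction))
  nTrain <- min(max(nTrain, 1L), n - 1L)
  set.seed(seed)
  trainIdx <- sort(sample.int(n, nTrain))
  testIdx <- setdiff(seq_len(n), trainIdx)
  list(train = records[trainIdx], test = records[testIdx],
       trainIdx = trainIdx, testIdx = testIdx)
}

.defaultMtryGrid <- function(p) {
  sort(unique(pmax(1L, floor(c(p / 3, sqrt(p), p / 2)))))
}

#' Train a random-forest regressor with OOB-tuned mtry
#'
#' Grows 500-tree forests (default) for each candidate \code{mtry} and
#' keeps the one with the lowest out-of-bag RMSE; the returned bundle
#' carries the feature manifest, the tuning trace and the OOB report.
#' Permutation importances (mean decrease in accuracy) are computed on
#' the final forest.
#'
#' @param X numeric feature matrix with column names (no missing
#'   values).
#' @param y numeric labels (at least two distinct values).
#' @param nTrees number of trees.
#' @param mtryGrid candidate numbers of features tried per split;
#'   defaults to \code{\{p/3, sqrt(p), p/2\}}.
#' @param seed integer seed (forest growth is seeded per candidate, so
#'   two runs with the same seed are identical).
#' @return A \linkS4class{ModelBundle}.
#' @export
trainRF <- function(X, y, nTrees = 500L, mtryGrid = NULL, seed = 1L) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) stop("feature matrix must have column names")
  if (anyNA(X) || anyNA(y)) stop("missing values are not allowed")
  if (length(y) != nrow(X)) stop("label length does not match rows of X")
  if (length(unique(y)) < 2) stop("labels are constant; nothing to learn")
  p <- ncol(X)
  if (is.null(mtryGrid)) mtryGrid <- .defaultMtryGrid(p)
  mtryGrid <- sort(unique(pmin(pmax(as.integer(mtryGrid), 1L), p)))
  oobRmse <- numeric(length(mtryGrid))
  fits <- vector("list", length(mtryGrid))
  for (g in seq_along(mtryGrid)) {
    set.seed(seed)
    fits[[g]] <- randomForest::randomForest(
      x = X, y = y, ntree = nTrees, mtry = mtryGrid[g],
      importance = TRUE)
    oobRmse[g] <- sqrt(mean((fits[[g]]$predicted - y)^2))
  }
  best <- which.min(oobRmse)
  rf <- fits[[best]]
  oob <- evalMetrics(y, rf$predicted, context = "oob")
  new("ModelBundle", forest = rf, featureManifest = colnames(X),
      hyperparams = list(nTrees = as.integer(nTrees),
                         mtry = mtryGrid[best], seed = as.integer(seed),
                         mtryGrid = mtryGrid, oobRmseGrid = oobRmse),
      oobReport = oob)
}

.checkManifest <- function(bundle, X) {
  if (is.null(colnames(X)) ||
      !identical(colnames(X), bundle@featureManifest))
    stop("feature columns do not match the model's manifest ",
         "(exactly the training columns, in order, are required; ",
         "no imputation is performed)")
}

#' Predict from a ModelBundle
#'
#' @param object a \linkS4class{ModelBundle}.
#' @param X feature matrix carrying exactly the manifest's columns in
#'   order.
#' @param ... unused.
#' @return Numeric vector of predicted dipole magnitudes (Debye).
#' @export
setMethod("predict", "ModelBundle", function(object, X, ...) {
  X <- as.matrix(X)
  .checkManifest(object, X)
  # forests restored from disk need the S3 predict method registered
  requireNamespace("randomForest", quietly = TRUE)
  as.numeric(stats::predict(object@forest, X))
})

#' Evaluate a model on a labeled feature matrix
#'
#' @param bundle a \linkS4class{ModelBundle}.
#' @param X feature matrix (must match the manifest).
#' @param y reference labels.
#' @param context metric context tag.
#' @inheritParams evalMetrics
#' @return An \linkS4class{EvalReport}.
#' @export
evaluateModel <- function(bundle, X, y, context = "test",
                          r2Method = c("pearson", "cod")) {
  yhat <- predict(bundle, X)
  evalMetrics(y, yhat, context = context, r2Method = match.arg(r2Method))
}

#' Select the most important features by permutation importance
#'
#' Ranks columns by the forest's mean decrease in accuracy (out-of-bag
#' permutation importance, averaged over trees) and returns the top
#' \code{k} labels; ties are broken by column order.
#'
#' @param bundle a \linkS4class{ModelBundle} trained with importances.
#' @param k number of features to keep (default 75).
#' @return Character vector of \code{k} feature labels, most important
#'   first.
#' @export
importanceSelect <- function(bundle, k = 75L) {
  imp <- randomForest::importance(bundle@forest, type = 1)[, 1]
  labs <- bundle@featureManifest
  if (k > length(labs))
    stop("k = ", k, " exceeds the number of features (", length(labs), ")")
  ord <- order(-imp, seq_along(imp))
  labs[ord][seq_len(k)]
}

#' y-randomization (label scrambling) validation
#'
#' Retrains the model \code{nRounds} times with the training labels
#' randomly permuted (the feature matrix untouched) and evaluates each
#' scrambled model on the untouched test rows.  A real model must vastly
#' outperform the scrambled ones.
#'
#' @param X full feature matrix.
#' @param y full label vector.
#' @param trainIdx,testIdx row indices of the training and test
#'   partitions.
#' @param nRounds number of scrambling rounds (default 5).
#' @param seed integer seed.
#' @param nTrees,mtryGrid forwarded to \code{\link{trainRF}}; pass the
#'   tuned mtry of the real model as a length-1 grid to skip re-tuning.
#' @return List of \code{nRounds} \linkS4class{EvalReport}s with context
#'   \code{"y_random"}.
#' @export
yRandomization <- function(X, y, trainIdx, testIdx, nRounds = 5L,
                           seed = 1L, nTrees = 500L, mtryGrid = NULL) {
  stopifnot(nRounds >= 1)
  reports <- vector("list", nRounds)
  for (r in seq_len(nRounds)) {
    set.seed(seed + r)
    yScr <- sample(y[trainIdx])
    bundle <- trainRF(X[trainIdx, , drop = FALSE], yScr, nTrees = nTrees,
                      mtryGrid = mtryGrid, seed = seed + r)
    rep <- evaluateModel(bundle, X[testIdx, , drop = FALSE], y[testIdx])
    reports[[r]] <- new("EvalReport", mae = rep@mae, rmse = rep@rmse,
                        r2 = rep@r2, n = rep@n, context = "y_random")
  }
  reports
}

#' Summary statistics of a labeled molecule set
#'
#' Count, mean and mean absolute deviation (about the mean) of the
#' dipole labels; the MAD is the conventional scale reference against
#' which model errors are judged.
#'
#' @param mols list of labeled \linkS4class{Molecule3D} objects.
#' @return List with \code{n}, \code{meanDM}, \code{madDM}.
#' @export
datasetSummary <- function(mols) {
  labs <- vapply(mols, dmLabel, 0)
  if (anyNA(labs)) stop("all molecules must carry a dipole label")
  list(n = length(labs), meanDM = mean(labs),
       madDM = mean(abs(labs - mean(labs))))
}
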