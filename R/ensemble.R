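# Tree ensembles built on fitTree/repPrune: bagging (bootstrap rows),
# random subspace (feature subsets, full rows), random forest (bootstrap
# rows + per-node feature sampling), and the pruned single tree
# ("reptree"). Prediction is the plain mean over members.

.ensembleKinds <- c("single_tree", "reptree", "bagging",
                    "random_subspace", "random_forest")

#' Default ensemble parameters
#'
#' \code{minLeaf = 2}, \code{maxDepth = 25}, \code{mtry = max(1,
#' floor(p/3))} (random forest), \code{q = ceiling(p/2)} (random
#' subspace), \code{pruningFraction = 1/3} (reptree grow/prune split),
#' \code{bootstrap = TRUE} (bagging).
#'
#' @param p number of features.
#' @return Named list of defaults.
#' @export
ensembleDefaults <- function(p) {
  list(minLeaf = 2L, maxDepth = 25L, mtry = max(1L, floor(p / 3)),
       q = ceiling(p / 2), pruningFraction = 1 / 3, bootstrap = TRUE)
}

#' Fit a regression-tree ensemble
#'
#' \describe{
#'   \item{single_tree}{one unpruned tree on all rows and features.}
#'   \item{reptree}{one tree grown on a seeded 2/3 subset and pruned by
#'     reduced-error pruning on the held-out 1/3.}
#'   \item{bagging}{\code{k} trees on seeded bootstrap resamples, all
#'     features (set \code{params$bootstrap = FALSE} to disable
#'     resampling, making \code{k = 1} identical to a single tree).}
#'   \item{random_subspace}{\code{k} trees on all rows but seeded feature
#'     subsets of size \code{q} (default \code{ceiling(p/2)}).}
#'   \item{random_forest}{\code{k} trees on bootstrap resamples with a
#'     fresh feature subset of size \code{mtry} (default
#'     \code{max(1, floor(p/3))}) drawn at every node.}
#' }
#' All randomness derives from \code{seed} (member i uses
#' \code{seed + i}), so fits are reproducible bit-for-bit.
#'
#' @param kind one of \code{"single_tree"}, \code{"reptree"},
#'   \code{"bagging"}, \code{"random_subspace"}, \code{"random_forest"}.
#' @param X feature matrix/data.frame with column names.
#' @param y numeric response.
#' @param k ensemble size (default 100; forced to 1 for single trees).
#' @param seed master seed.
#' @param params overrides of \code{\link{ensembleDefaults}}.
#' @return Object of class \code{"EnsembleModel"}.
#' @export
fitEnsemble <- function(kind, X, y, k = 100L, seed = 1L,
                        params = list()) {
  kind <- match.arg(kind, .ensembleKinds)
  X <- as.matrix(X)
  if (is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- nrow(X); p <- ncol(X)
  if (k < 1L) stop("k must be >= 1")
  prm <- utils::modifyList(ensembleDefaults(p), params)
  if (prm$q > p) stop("q (", prm$q, ") exceeds number of features ", p)
  if (prm$mtry > p) stop("mtry (", prm$mtry, ") exceeds number of features ", p)
  if (kind %in% c("single_tree", "reptree")) k <- 1L
  members <- vector("list", k)
  for (i in seq_len(k)) {
    set.seed(seed + i)
    if (kind == "single_tree") {
      tree <- fitTree(X, y, prm$minLeaf, prm$maxDepth)
      feats <- colnames(X)
    } else if (kind == "reptree") {
      perm <- sample.int(n)
      nGrow <- max(2L * prm$minLeaf,
                   n - floor(n * prm$pruningFraction))
      gi <- perm[seq_len(nGrow)]
      pi <- perm[(nGrow + 1L):n]
      if (!length(pi)) stop("training set too small for a pruning split")
      tree <- fitTree(X[gi, , drop = FALSE], y[gi], prm$minLeaf,
                      prm$maxDepth)
      tree <- repPrune(tree, X[pi, , drop = FALSE], y[pi])
      feats <- colnames(X)
    } else if (kind == "bagging") {
      rows <- if (prm$bootstrap) sample.int(n, n, replace = TRUE)
              else seq_len(n)
      tree <- fitTree(X[rows, , drop = FALSE], y[rows], prm$minLeaf,
                      prm$maxDepth)
      feats <- colnames(X)
    } else if (kind == "random_subspace") {
      feats <- colnames(X)[sort(sample.int(p, prm$q))]
      tree <- fitTree(X[, feats, drop = FALSE], y, prm$minLeaf,
                      prm$maxDepth)
    } else { # random_forest
      rows <- sample.int(n, n, replace = TRUE)
      tree <- fitTree(X[rows, , drop = FALSE], y[rows], prm$minLeaf,
                      prm$maxDepth, mtry = prm$mtry)
      feats <- colnames(X)
    }
    members[[i]] <- list(tree = tree, features = feats)
  }
  structure(list(kind = kind, members = members, k = k,
                 seed = seed, params = prm, featureNames = colnames(X)),
            class = "EnsembleModel")
}

#' Predict from an ensemble
#'
#' @param model an \code{"EnsembleModel"}.
#' @param X feature matrix/data.frame containing the training columns.
#' @return Mean of member predictions, one value per row.
#' @export
predictEnsemble <- function(model, X) {
  X <- as.matrix(X)
  preds <- vapply(model$members, function(m)
    predictTree(m$tree, X[, m$features, drop = FALSE]),
    numeric(nrow(X)))
  rowMeans(matrix(preds, nrow = nrow(X)))
}

#' @export
predict.EnsembleModel <- function(object, newdata, ...)
  predictEnsemble(object, newdata)

#' @export
print.EnsembleModel <- function(x, ...) {
  cat("EnsembleModel:", x$kind, "with", x$k, "member(s), seed",
      x$seed, "\n")
  invisible(x)
}

#' k-fold cross-validation of an ensemble learner
#'
#' Seeded shuffle, contiguous fold assignment; every sample is validated
#' exactly once. Pooled metrics are computed on the concatenated
#' out-of-fold predictions.
#'
#' @param kind ensemble kind (see \code{\link{fitEnsemble}}).
#' @param X,y features and response.
#' @param folds number of folds (default 5); must not exceed \code{n}.
#' @param k ensemble size per fold fit.
#' @param seed master seed (fold f fits with seed \code{seed + 1000*f}).
#' @param params parameter overrides.
#' @return list(perFold = list of MetricBundle, pooled = MetricBundle,
#'   foldAssignment = integer vector, oofPredictions = numeric vector).
#' @export
crossValidate <- function(kind, X, y, folds = 5L, k = 100L, seed = 1L,
                          params = list()) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (folds > n) stop("folds (", folds, ") exceeds sample count ", n)
  if (folds < 2L) stop("folds must be >= 2")
  set.seed(seed)
  perm <- sample.int(n)
  sizes <- rep(floor(n / folds), folds)
  extra <- n - sum(sizes)
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  assignment <- integer(n)
  assignment[perm] <- rep(seq_len(folds), times = sizes)
  oof <- numeric(n)
  perFold <- vector("list", folds)
  for (f in seq_len(folds)) {
    hold <- which(assignment == f)
    fit <- fitEnsemble(kind, X[-hold, , drop = FALSE], y[-hold], k = k,
                       seed = seed + 1000L * f, params = params)
    oof[hold] <- predictEnsemble(fit, X[hold, , drop = FALSE])
    perFold[[f]] <- regressionMetrics(y[hold], oof[hold])
  }
  list(perFold = perFold, pooled = regressionMetrics(y, oof),
       foldAssignment = assignment, oofPredictions = oof)
}

#' Compare ensemble learners on an index feature table
#'
#' Computes the index features (default CAR1-CAR9) for every sample,
#' applies one train/test split, fits each requested learner on the
#' training partition and reports train and test metric bundles.
#'
#' @param x a \linkS4class{SpectraSet}.
#' @param featureNames index names used as features (default CAR1-CAR9).
#' @param split a \code{"SplitScheme"} (default seeded 70/30 pooled).
#' @param kinds learner kinds to fit.
#' @param k ensemble size.
#' @param seed master seed for the learner fits.
#' @param params parameter overrides passed to every learner.
#' @param registry index registry.
#' @return data.frame with one row per learner: kind, n_train, n_test and
#'   the six metrics for train and test.
#' @export
runMlComparison <- function(x, featureNames = paste0("CAR", 1:9),
                            split = splitPooled(0.7, seed = 1),
                            kinds = c("random_forest", "reptree",
                                      "random_subspace", "bagging"),
                            k = 100L, seed = 1L, params = list(),
                            registry = builtinIndices()) {
  kinds <- vapply(kinds, function(kk) match.arg(kk, .ensembleKinds),
                  character(1))
  tab <- computeIndexTable(x, featureNames, registry)
  feat <- as.matrix(tab[, featureNames, drop = FALSE])
  car <- as.numeric(colData(x)$carotenoid_ugg)
  ok <- stats::complete.cases(feat) & is.finite(car)
  if (any(!ok))
    message("dropping ", sum(!ok), " sample(s) with undefined features")
  sp <- makeSplit(x, split)
  iTrain <- which(ok & tab$sample_id %in% sp$train)
  iTest <- which(ok & tab$sample_id %in% sp$test)
  rows <- lapply(kinds, function(kind) {
    fit <- fitEnsemble(kind, feat[iTrain, , drop = FALSE], car[iTrain],
                       k = k, seed = seed, params = params)
    mTrain <- regressionMetrics(
      car[iTrain], predictEnsemble(fit, feat[iTrain, , drop = FALSE]))
    mTest <- regressionMetrics(
      car[iTest], predictEnsemble(fit, feat[iTest, , drop = FALSE]))
    as.data.frame(c(list(kind = kind, n_train = mTrain$n,
                         n_test = mTest$n),
                    .bundleCols(mTrain, "train"),
                    .bundleCols(mTest, "test")),
                  stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
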