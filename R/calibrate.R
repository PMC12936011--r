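# Linear index calibration, split schemes and the six-metric evaluation
# bundle.

#' Regression evaluation metrics
#'
#' Computes, with \code{y} the observed and \code{yhat} the predicted
#' values and \code{ybar = mean(y)}:
#' \preformatted{
#'  R2    = 1 - sum((y - yhat)^2) / sum((y - ybar)^2)
#'  RMSE  = sqrt(sum((y - yhat)^2) / n)
#'  NRMSE = RMSE / ybar * 100
#'  MAE   = sum(|yhat - y|) / n
#'  MBE   = sum(y - yhat) / n
#'  NSE   = 1 - sum((y - yhat)^2) / sum((y - ybar)^2)
#' }
#' The MBE sign convention is mean(observed - predicted): negative MBE
#' means overestimation. NSE uses the standard observed-variance
#' denominator; \code{nseAsPrinted = TRUE} switches the denominator to
#' \code{sum((yhat - ybar)^2)} (a variant that normalizes by the spread of
#' the predictions instead).
#'
#' Pairs with a missing (flagged-undefined) value in either vector are
#' dropped before computation.
#'
#' @param yObs observed values (ug/g).
#' @param yPred predicted values (ug/g), same length.
#' @param nseAsPrinted use the predicted-spread NSE denominator.
#' @return Object of class \code{"MetricBundle"}: list with \code{r2},
#'   \code{rmse}, \code{nrmse} (percent), \code{mae}, \code{mbe},
#'   \code{nse}, \code{n}. Zero observed variance flags \code{r2}/
#'   \code{nse} as \code{NA}; zero observed mean flags \code{nrmse}.
#' @examples
#' regressionMetrics(c(2, 4, 6), c(1, 3, 5))
#' @export
regressionMetrics <- function(yObs, yPred, nseAsPrinted = FALSE) {
  if (length(yObs) != length(yPred))
    stop("yObs and yPred must have equal length")
  ok <- is.finite(yObs) & is.finite(yPred)
  y <- yObs[ok]; yh <- yPred[ok]
  n <- length(y)
  if (n < 2) stop("need at least 2 complete pairs (got ", n, ")")
  ybar <- mean(y)
  sse <- sum((y - yh)^2)
  sst <- sum((y - ybar)^2)
  rmse <- sqrt(sse / n)
  r2 <- if (sst > 0) 1 - sse / sst else NA_real_
  nrmse <- if (abs(ybar) > 0) rmse / ybar * 100 else NA_real_
  nseDen <- if (nseAsPrinted) sum((yh - ybar)^2) else sst
  nse <- if (nseDen > 0) 1 - sse / nseDen else NA_real_
  structure(list(r2 = r2, rmse = rmse, nrmse = nrmse,
                 mae = mean(abs(yh - y)), mbe = mean(y - yh),
                 nse = nse, n = n), class = "MetricBundle")
}

#' @export
print.MetricBundle <- function(x, ...) {
  cat(sprintf(
    "MetricBundle (n=%d): R2=%.3f RMSE=%.3f NRMSE=%.2f%% MAE=%.3f MBE=%.3f NSE=%.3f\n",
    x$n, x$r2, x$rmse, x$nrmse, x$mae, x$mbe, x$nse))
  invisible(x)
}

#' Ordinary least-squares index calibration
#'
#' Fits \code{carotenoid = intercept + slope * index} by OLS on
#' pairwise-complete observations.
#'
#' @param indexValues numeric index values (predictor).
#' @param carUgg carotenoid content (response), ug/g.
#' @return list(slope, intercept, n).
#' @export
fitLinearCalibration <- function(indexValues, carUgg) {
  ok <- is.finite(indexValues) & is.finite(carUgg)
  x <- indexValues[ok]; y <- carUgg[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (var(x) == 0) stop("index has zero variance; cannot calibrate")
  fit <- lm(y ~ x)
  cf <- coef(fit)
  list(slope = unname(cf[2]), intercept = unname(cf[1]), n = length(x))
}

#' Year-grouped split scheme
#'
#' @param trainYears,testYears disjoint, non-empty integer year sets.
#' @return Object of class \code{"SplitScheme"}.
#' @export
splitByYears <- function(trainYears, testYears) {
  if (!length(trainYears) || !length(testYears))
    stop("trainYears and testYears must be non-empty")
  if (length(intersect(trainYears, testYears)))
    stop("trainYears and testYears must be disjoint")
  structure(list(kind = "by_years", trainYears = trainYears,
                 testYears = testYears,
                 label = paste0("years:",
                                paste(trainYears, collapse = "+"), "/",
                                paste(testYears, collapse = "+"))),
            class = "SplitScheme")
}

#' Pooled random split scheme
#'
#' Seeded uniform shuffle followed by a \code{floor(n * fraction)} cut.
#'
#' @param trainFraction fraction of samples for training, in (0, 1).
#' @param seed RNG seed for the shuffle.
#' @return Object of class \code{"SplitScheme"}.
#' @export
splitPooled <- function(trainFraction = 2 / 3, seed = 1) {
  if (trainFraction <= 0 || trainFraction >= 1)
    stop("trainFraction must be in (0, 1)")
  structure(list(kind = "pooled_random", trainFraction = trainFraction,
                 seed = seed,
                 label = sprintf("pooled:%.4g:seed=%d", trainFraction,
                                 as.integer(seed))),
            class = "SplitScheme")
}

#' @export
print.SplitScheme <- function(x, ...) {
  cat("SplitScheme", x$label, "\n")
  invisible(x)
}

#' Partition a sample table according to a split scheme
#'
#' @param x a \linkS4class{SpectraSet} (or data.frame with
#'   \code{sample_id} and, for year schemes, \code{year}).
#' @param scheme a \code{"SplitScheme"}.
#' @return list(train, test) of sample ids; exact disjoint partition.
#' @export
makeSplit <- function(x, scheme) {
  meta <- if (methods::is(x, "SpectraSet")) as.data.frame(colData(x))
          else as.data.frame(x)
  ids <- meta$sample_id
  if (scheme$kind == "by_years") {
    yrs <- meta$year
    missing <- setdiff(c(scheme$trainYears, scheme$testYears), unique(yrs))
    if (length(missing))
      stop("requested year(s) absent from data: ",
           paste(missing, collapse = ", "))
    list(train = ids[yrs %in% scheme$trainYears],
         test = ids[yrs %in% scheme$testYears])
  } else {
    n <- length(ids)
    set.seed(scheme$seed)
    perm <- sample.int(n)
    nTrain <- floor(n * scheme$trainFraction + 1e-9)
    list(train = ids[perm[seq_len(nTrain)]],
         test = ids[perm[(nTrain + 1):n]])
  }
}

.bundleCols <- function(b, suffix) {
  out <- b[c("r2", "rmse", "nrmse", "mae", "mbe", "nse")]
  names(out) <- paste0(names(out), "_", suffix)
  out
}

#' Evaluate a suite of indices over split schemes
#'
#' For every (scheme, index) pair: fit a linear calibration on the
#' training partition, predict both partitions, and report both metric
#' bundles. Within each scheme rows are sorted by test R2 (descending).
#' Index/partition combinations where the calibration is impossible (all
#' values undefined, or zero variance) are reported with
#' \code{status = "failed"} and the run continues.
#'
#' @param x a \linkS4class{SpectraSet}.
#' @param names index names (default the nine CAR indices).
#' @param schemes list of \code{"SplitScheme"} objects.
#' @param registry index registry (default built-ins).
#' @return data.frame: scheme, index, slope, intercept, n_train, n_test,
#'   the six metrics for train and test, status.
#' @export
evaluateIndexSuite <- function(x, names = paste0("CAR", 1:9), schemes,
                               registry = builtinIndices()) {
  if (!length(names) || !length(schemes)) stop("empty names or schemes")
  tab <- computeIndexTable(x, names, registry)
  meta <- as.data.frame(colData(x))
  car <- meta$carotenoid_ugg
  rows <- list()
  for (scheme in schemes) {
    sp <- makeSplit(x, scheme)
    iTrain <- match(sp$train, tab$sample_id)
    iTest <- match(sp$test, tab$sample_id)
    for (nm in names) {
      v <- tab[[nm]]
      row <- tryCatch({
        fit <- fitLinearCalibration(v[iTrain], car[iTrain])
        predTrain <- fit$intercept + fit$slope * v[iTrain]
        predTest <- fit$intercept + fit$slope * v[iTest]
        mTrain <- regressionMetrics(car[iTrain], predTrain)
        mTest <- regressionMetrics(car[iTest], predTest)
        c(list(scheme = scheme$label, index = nm, slope = fit$slope,
               intercept = fit$intercept, n_train = mTrain$n,
               n_test = mTest$n),
          .bundleCols(mTrain, "train"), .bundleCols(mTest, "test"),
          list(status = "ok"))
      }, error = function(e) {
        c(list(scheme = scheme$label, index = nm, slope = NA_real_,
               intercept = NA_real_, n_train = NA_integer_,
               n_test = NA_integer_),
          setNames(as.list(rep(NA_real_, 12)),
                   c(paste0(c("r2", "rmse", "nrmse", "mae", "mbe", "nse"),
                            "_train"),
                     paste0(c("r2", "rmse", "nrmse", "mae", "mbe", "nse"),
                            "_test"))),
          list(status = paste0("failed: ", conditionMessage(e))))
      })
      rows[[length(rows) + 1L]] <- as.data.frame(row,
                                                 stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  # sort by test R2 descending within scheme, keeping scheme order
  schemeOrder <- vapply(schemes, function(s) s$label, character(1))
  out <- out[order(match(out$scheme, schemeOrder),
                   ifelse(is.na(out$r2_test), Inf, -out$r2_test)), ]
  rownames(out) <- NULL
  out
}
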