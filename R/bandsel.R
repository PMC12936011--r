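# Sensitive-band selection: PCA loadings, varimax rotation, the
# Kaiser-Meyer-Olkin sampling-adequacy statistic, and loading-peak reading.

#' Kaiser-Meyer-Olkin sampling adequacy
#'
#' \code{KMO = sum(r_ij^2) / (sum(r_ij^2) + sum(p_ij^2))} over all pairs
#' \code{i != j}, where \code{r} are simple correlations and \code{p} the
#' anti-image partial correlations obtained from the inverse correlation
#' matrix. Values near 1 indicate that variables share common variance and
#' factor analysis is appropriate.
#'
#' @param X numeric data matrix (samples x variables, >= 3 variables and
#'   more samples than variables), or a correlation matrix (square,
#'   symmetric, unit diagonal).
#' @param ridge ridge added to a near-singular correlation matrix before
#'   inversion (default 1e-8); failure after the ridge is an error.
#' @return KMO statistic in \code{[0, 1]}.
#' @export
kmo <- function(X, ridge = 1e-8) {
  X <- as.matrix(X)
  isCor <- nrow(X) == ncol(X) &&
    isTRUE(all.equal(unname(diag(X)), rep(1, ncol(X)))) &&
    isTRUE(all.equal(X, t(X), tolerance = 1e-8))
  if (isCor) {
    R <- X
  } else {
    if (ncol(X) < 3) stop("need at least 3 variables")
    if (nrow(X) <= ncol(X))
      stop("need more samples than variables (or pass a correlation matrix)")
    R <- cor(X)
  }
  p <- ncol(R)
  off <- upper.tri(R)
  if (any(abs(R[off]) > 1 - 1e-12))
    stop("perfectly correlated variable pair; correlation matrix singular")
  inv <- tryCatch(solve(R), error = function(e) NULL)
  if (is.null(inv)) {
    warning("near-singular correlation matrix; applying ridge ", ridge)
    inv <- tryCatch(solve(R + diag(ridge, p)), error = function(e)
      stop("correlation matrix singular even after ridge"))
  }
  d <- 1 / sqrt(diag(inv))
  P <- -inv * tcrossprod(d)      # anti-image partial correlations
  sumR2 <- sum(R[off]^2)
  sumP2 <- sum(P[off]^2)
  sumR2 / (sumR2 + sumP2)
}

#' Principal-component loadings
#'
#' Eigendecomposition of the correlation (default) or covariance matrix.
#' Loadings are component weights scaled so squared column sums equal the
#' component variances (eigenvalues); explained-variance percentages are
#' relative to the total variance of all variables.
#'
#' @param X numeric data matrix, samples x variables; column names (or a
#'   \code{wavelengths} argument) identify the variables.
#' @param nComponents number of components to retain.
#' @param standardize use the correlation matrix (default TRUE). Constant
#'   variables are an error under standardization, named in the message.
#' @param wavelengths optional numeric wavelengths, one per column.
#' @return Object of class \code{"LoadingMatrix"}: list with
#'   \code{wavelengths}, \code{loadings} (variables x components),
#'   \code{explainedVariancePct} (non-increasing), \code{totalVariance}.
#' @export
pcaLoadings <- function(X, nComponents = 5, standardize = TRUE,
                        wavelengths = NULL) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (nComponents < 1 || nComponents > p)
    stop("nComponents must be in [1, ncol(X)]")
  if (standardize) {
    sds <- apply(X, 2, sd)
    if (any(sds == 0)) {
      nm <- colnames(X)[sds == 0]
      if (is.null(nm)) nm <- which(sds == 0)
      stop("constant variable(s) under standardization: ",
           paste(head(nm, 5), collapse = ", "))
    }
    S <- cor(X)
  } else {
    S <- cov(X)
  }
  ee <- eigen(S, symmetric = TRUE)
  vals <- pmax(ee$values, 0)
  k <- nComponents
  vec <- ee$vectors[, seq_len(k), drop = FALSE]
  # deterministic sign: largest-|loading| entry positive
  for (j in seq_len(k)) {
    i <- which.max(abs(vec[, j]))
    if (vec[i, j] < 0) vec[, j] <- -vec[, j]
  }
  L <- vec %*% diag(sqrt(vals[seq_len(k)]), k)
  wl <- if (!is.null(wavelengths)) as.numeric(wavelengths)
        else .parseWavelengthCols(colnames(X))
  rownames(L) <- colnames(X)
  colnames(L) <- paste0("PC", seq_len(k))
  structure(list(wavelengths = wl, loadings = L,
                 explainedVariancePct = 100 * vals[seq_len(k)] / sum(vals),
                 totalVariance = sum(vals)),
            class = "LoadingMatrix")
}

#' @export
print.LoadingMatrix <- function(x, ...) {
  cat("LoadingMatrix:", nrow(x$loadings), "variables x",
      ncol(x$loadings), "components\n")
  cat("  explained variance (%):",
      paste(sprintf("%.2f", x$explainedVariancePct), collapse = ", "), "\n")
  invisible(x)
}

#' Varimax rotation criterion
#'
#' Sum over components of the variance of squared loadings,
#' \code{sum_j [ mean(L_j^4) - mean(L_j^2)^2 ]}. Varimax rotation
#' maximizes this quantity over orthogonal rotations.
#'
#' @param L loadings matrix or \code{"LoadingMatrix"}.
#' @return Criterion value (scalar).
#' @export
varimaxCriterion <- function(L) {
  if (inherits(L, "LoadingMatrix")) L <- L$loadings
  L2 <- L^2
  sum(colMeans(L2^2) - colMeans(L2)^2)
}

#' Varimax rotation
#'
#' Classic Kaiser pairwise-rotation varimax with optional row
#' normalization: for every pair of components the closed-form optimal
#' planar angle is applied, and sweeps repeat until no pair moves. Row
#' communalities (row sums of squared loadings) are preserved exactly up
#' to numerical error, and the criterion value (of the normalized
#' loadings when \code{kaiserNormalize = TRUE}) never decreases relative
#' to the unrotated loadings.
#'
#' @param L a \code{"LoadingMatrix"} (from \code{\link{pcaLoadings}}) or a
#'   plain loadings matrix with >= 2 columns.
#' @param kaiserNormalize normalize rows to unit communality during the
#'   rotation (default TRUE, standard practice).
#' @param tol convergence tolerance on the relative criterion increase.
#' @param maxIter maximum iterations; non-convergence is a warning and the
#'   best iterate is returned.
#' @return Same class as the input. For a \code{"LoadingMatrix"} the
#'   explained-variance percentages are recomputed from the rotated
#'   loadings and columns re-ordered by decreasing variance; the rotation
#'   matrix is attached as attribute \code{"rotmat"}.
#' @export
varimaxRotate <- function(L, kaiserNormalize = TRUE, tol = 1e-6,
                          maxIter = 500L) {
  obj <- NULL
  if (inherits(L, "LoadingMatrix")) { obj <- L; L <- L$loadings }
  L <- as.matrix(L)
  if (ncol(L) < 2) stop("need at least 2 components to rotate")
  p <- nrow(L)
  sc <- if (kaiserNormalize) sqrt(rowSums(L^2)) else rep(1, p)
  sc[sc == 0] <- 1
  x <- L / sc
  k <- ncol(x)
  TT <- diag(k)
  z <- x
  converged <- FALSE
  for (i in seq_len(maxIter)) {
    maxAngle <- 0
    for (a in seq_len(k - 1)) for (b in (a + 1):k) {
      u <- z[, a]^2 - z[, b]^2
      v <- 2 * z[, a] * z[, b]
      num <- sum(2 * u * v) - 2 * sum(u) * sum(v) / p
      den <- sum(u^2 - v^2) - (sum(u)^2 - sum(v)^2) / p
      theta <- atan2(num, den) / 4
      if (abs(theta) < 1e-15) next
      maxAngle <- max(maxAngle, abs(theta))
      G <- diag(k)
      G[a, a] <- cos(theta);  G[b, b] <- cos(theta)
      G[a, b] <- -sin(theta); G[b, a] <- sin(theta)
      z <- z %*% G
      TT <- TT %*% G
    }
    if (maxAngle < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("varimax did not converge in ", maxIter,
            " iterations; returning best iterate")
  rot <- (x %*% TT) * sc
  # order components by decreasing variance, fix sign deterministically
  v <- colSums(rot^2)
  ord <- order(v, decreasing = TRUE)
  rot <- rot[, ord, drop = FALSE]
  TT <- TT[, ord, drop = FALSE]
  for (j in seq_len(k)) {
    iMax <- which.max(abs(rot[, j]))
    if (rot[iMax, j] < 0) { rot[, j] <- -rot[, j]; TT[, j] <- -TT[, j] }
  }
  dimnames(rot) <- list(rownames(L), paste0("RC", seq_len(k)))
  if (is.null(obj)) return(structure(rot, rotmat = TT))
  obj$loadings <- rot
  obj$explainedVariancePct <- 100 * colSums(rot^2) / obj$totalVariance
  attr(obj, "rotmat") <- TT
  obj
}

#' Select pigment-sensitive bands from a loading profile
#'
#' Takes the \code{k} tallest local maxima of the absolute loading profile
#' along wavelength, greedily enforcing a minimum pairwise separation.
#' Boundary points count as local maxima; equal heights break ties toward
#' the lower wavelength. The profile can be smoothed by a centered moving
#' average before peak reading to suppress sampling ripples.
#'
#' @param L a \code{"LoadingMatrix"} with non-null wavelengths.
#' @param component which component's loadings to read (default 1).
#' @param k number of bands to select.
#' @param minSeparationNm minimum pairwise separation (default 15 nm).
#' @param smoothNm full width (nm) of the moving-average smoother applied
#'   to the |loading| profile before peak detection; 0 disables smoothing.
#' @return Object of class \code{"BandSelection"}: list with
#'   \code{selectedNm} (ascending), \code{criterion} (data.frame of peak
#'   wavelength, height, component), \code{component}. If fewer than
#'   \code{k} admissible peaks exist, all found are returned with a
#'   warning.
#' @export
selectSensitiveBands <- function(L, component = 1, k = 4,
                                 minSeparationNm = 15, smoothNm = 0) {
  if (!inherits(L, "LoadingMatrix")) stop("L must be a LoadingMatrix")
  wl <- L$wavelengths
  if (is.null(wl) || any(is.na(wl)))
    stop("LoadingMatrix has no usable wavelengths")
  if (component < 1 || component > ncol(L$loadings))
    stop("component ", component, " does not exist")
  if (k < 1) stop("k must be >= 1")
  prof <- abs(L$loadings[, component])
  if (smoothNm > 0) {
    half <- smoothNm / 2
    prof <- vapply(seq_along(wl), function(i)
      mean(prof[abs(wl - wl[i]) <= half]), numeric(1))
  }
  n <- length(prof)
  isMax <- logical(n)
  if (n >= 2) {
    isMax[1] <- prof[1] > prof[2]
    isMax[n] <- prof[n] > prof[n - 1]
  }
  if (n >= 3) {
    mid <- 2:(n - 1)
    isMax[mid] <- prof[mid] >= prof[mid - 1] & prof[mid] > prof[mid + 1]
  }
  cand <- which(isMax)
  cand <- cand[order(-prof[cand], wl[cand])]
  sel <- integer(0)
  for (i in cand) {
    if (all(abs(wl[i] - wl[sel]) >= minSeparationNm)) sel <- c(sel, i)
    if (length(sel) == k) break
  }
  if (length(sel) < k)
    warning("only ", length(sel), " admissible peak(s) found (requested ",
            k, ")")
  ord <- order(wl[sel])
  structure(list(
    selectedNm = wl[sel][ord],
    criterion = data.frame(wavelength_nm = wl[sel][ord],
                           height = unname(prof[sel][ord]),
                           component = component),
    component = component), class = "BandSelection")
}

#' @export
print.BandSelection <- function(x, ...) {
  cat("BandSelection (component ", x$component, "): ",
      paste(x$selectedNm, collapse = ", "), " nm\n", sep = "")
  invisible(x)
}

#' Correlation of an external variable with component scores
#'
#' Projects a supplementary variable (e.g. carotenoid content) into the
#' component space as the correlation between the variable and each
#' component's scores.
#'
#' @param X data matrix used for the PCA (samples x variables).
#' @param L the \code{"LoadingMatrix"}.
#' @param v numeric variable, one value per sample.
#' @param standardize must match the \code{pcaLoadings} call.
#' @return Named numeric vector of correlations, one per component.
#' @export
componentVariableCorrelation <- function(X, L, v, standardize = TRUE) {
  X <- as.matrix(X)
  Xc <- scale(X, center = TRUE, scale = standardize)
  W <- L$loadings
  scores <- Xc %*% W          # up to component scaling; correlation only
  out <- drop(cor(scores, v))
  names(out) <- colnames(W)
  out
}
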