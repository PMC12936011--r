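# KMO, PCA loadings, varimax rotation and sensitive-band selection.

test_that("KMO matches the equicorrelation closed form", {
  R <- matrix(0.5, 3, 3); diag(R) <- 1
  # partials of an equicorrelated trio with r = 0.5 are 1/3 each
  expect_equal(kmo(R), 0.25 / (0.25 + 1 / 9), tolerance = 1e-12)
  expect_equal(kmo(R), 0.6923, tolerance = 1e-4)
})

test_that("KMO agrees with a regression-residual partial-correlation oracle", {
  set.seed(31)
  for (i in 1:15) {
    n <- 60; p <- sample(4:7, 1)
    F1 <- rnorm(n)
    X <- sapply(seq_len(p), function(j) 0.8 * F1 + rnorm(n))
    expect_equal(kmo(X), oracleKMO(X), tolerance = 1e-10)
  }
})

test_that("KMO stays in [0,1] and approaches 1 for a strong common factor", {
  set.seed(17)
  for (i in 1:20) {
    X <- matrix(rnorm(40 * 5), 40, 5)
    v <- kmo(X)
    expect_gte(v, 0)
    expect_lte(v, 1)
  }
  # many equicorrelated variables: partials shrink, KMO -> 1
  R <- matrix(0.5, 60, 60); diag(R) <- 1
  expect_gt(kmo(R), 0.95)
})

test_that("KMO rejects degenerate inputs", {
  X <- matrix(rnorm(30), 10, 3)
  X <- cbind(X, X[, 1])                       # duplicated variable
  expect_error(kmo(X), "singular|correlated")
  expect_error(kmo(matrix(rnorm(20), 10, 2)), "at least 3")
  expect_error(kmo(matrix(rnorm(12), 3, 4)), "more samples")
})

test_that("PCA explained variance matches closed forms", {
  # rank-1 data: first component explains everything
  set.seed(2)
  base <- rnorm(6)
  X <- outer(rnorm(20), base)
  L <- pcaLoadings(X, 2, standardize = FALSE)
  expect_equal(L$explainedVariancePct[1], 100, tolerance = 1e-9)

  # exact sample covariance [[2,1],[1,2]]: eigenvalues 3 and 1 -> 75/25
  s1 <- c(-3, -1, 1, 3); s1 <- s1 / sd(s1) * sqrt(3)
  s2 <- c(1, -1, -1, 1); s2 <- s2 / sd(s2)
  e1 <- c(1, 1) / sqrt(2); e2 <- c(1, -1) / sqrt(2)
  X2 <- outer(s1, e1) + outer(s2, e2)
  expect_equal(unname(cov(X2)), matrix(c(2, 1, 1, 2), 2), tolerance = 1e-12)
  L2 <- pcaLoadings(X2, 2, standardize = FALSE)
  expect_equal(L2$explainedVariancePct, c(75, 25), tolerance = 1e-9)
})

test_that("PCA agrees with an eigendecomposition oracle on random data", {
  set.seed(13)
  for (i in 1:20) {
    X <- matrix(rnorm(20 * 8), 20, 8)
    L <- pcaLoadings(X, 8, standardize = TRUE)
    ev <- sort(eigen(cor(X), only.values = TRUE)$values,
               decreasing = TRUE)
    expect_equal(L$explainedVariancePct, 100 * ev / sum(ev),
                 tolerance = 1e-8)
    # loading column norms are sqrt(eigenvalue)
    expect_equal(unname(colSums(L$loadings^2)), ev, tolerance = 1e-8)
    expect_true(all(diff(L$explainedVariancePct) <= 1e-12))
  }
})

test_that("PCA names constant variables rejected under standardization", {
  X <- cbind(a = rnorm(10), b = rep(2, 10), c = rnorm(10))
  expect_error(pcaLoadings(X, 2, standardize = TRUE), "b")
})

test_that("varimax preserves communalities and orthogonality", {
  set.seed(19)
  for (i in 1:10) {
    L <- matrix(rnorm(30 * 3), 30, 3)
    R <- varimaxRotate(L)
    TT <- attr(R, "rotmat")
    expect_equal(crossprod(TT), diag(3), tolerance = 1e-9)
    expect_equal(rowSums(unclass(R)^2), rowSums(L^2), tolerance = 1e-9)
    # raw criterion is non-decreasing when rotating without normalization
    Rraw <- varimaxRotate(L, kaiserNormalize = FALSE)
    expect_gte(varimaxCriterion(unclass(Rraw)),
               varimaxCriterion(L) - 1e-12)
    # Kaiser rotation maximizes the criterion of the normalized loadings
    sc <- sqrt(rowSums(L^2))
    expect_gte(varimaxCriterion(unclass(R) / sc),
               varimaxCriterion(L / sc) - 1e-12)
  }
})

test_that("varimax leaves perfect simple structure fixed", {
  L <- rbind(matrix(c(rep(1, 10), rep(0, 10)), 10, 2),
             matrix(c(rep(0, 8), rep(1, 8)), 8, 2))
  L <- L * runif(18, 0.5, 1.5)
  R <- unclass(varimaxRotate(L, kaiserNormalize = FALSE))
  # up to column order/sign, the rotation is the identity
  M <- abs(cor(L, R))
  expect_equal(sort(apply(M, 1, max)), c(1, 1), tolerance = 1e-6)
  expect_equal(abs(det(attr(varimaxRotate(L), "rotmat"))), 1,
               tolerance = 1e-9)
})

test_that("varimax recovers a 45-degree mixed simple structure", {
  set.seed(8)
  S <- cbind(c(abs(rnorm(12, 2)), rep(0, 12)),
             c(rep(0, 12), abs(rnorm(12, 2))))
  L <- S %*% rot2(pi / 4)
  R <- unclass(varimaxRotate(L, kaiserNormalize = FALSE))
  critPkg <- varimaxCriterion(R)
  # brute-force 1-D grid search over rotation angle
  critGrid <- max(vapply(seq(0, pi / 2, length.out = 20001), function(th)
    oracleVarimaxCriterion(L %*% rot2(th)), numeric(1)))
  expect_equal(critPkg, critGrid, tolerance = 1e-4)
  # rotated loadings are simple again: one dominant entry per row
  domin <- apply(abs(R), 1, max) / sqrt(rowSums(R^2))
  expect_gt(min(domin), 0.99)
})

test_that("varimax agrees with the stats reference implementation", {
  set.seed(23)
  L <- matrix(rnorm(40 * 3), 40, 3)
  sc <- sqrt(rowSums(L^2))     # both maximize the normalized criterion
  ours <- varimaxCriterion(unclass(varimaxRotate(L, tol = 1e-10)) / sc)
  ref <- varimaxCriterion(unclass(stats::varimax(L, normalize = TRUE,
                                                 eps = 1e-10)$loadings) / sc)
  expect_equal(ours, ref, tolerance = 1e-8)
})

test_that("band selection finds constructed peaks with separation and ties", {
  wl <- seq(400, 1000, by = 1)
  prof <- 0.1 +
    1.0 * exp(-((wl - 550)^2) / 50) + 0.9 * exp(-((wl - 678)^2) / 50) +
    0.8 * exp(-((wl - 700)^2) / 50) + 0.7 * exp(-((wl - 800)^2) / 50)
  L <- structure(list(wavelengths = wl,
                      loadings = matrix(prof, ncol = 1),
                      explainedVariancePct = 100, totalVariance = 1),
                 class = "LoadingMatrix")
  sel <- selectSensitiveBands(L, 1, k = 4, minSeparationNm = 15)
  expect_equal(sel$selectedNm, c(550, 678, 700, 800))

  # monotone profile: boundary maximum at the top wavelength
  L$loadings <- matrix(seq_along(wl), ncol = 1)
  expect_equal(selectSensitiveBands(L, 1, k = 1)$selectedNm, 1000)

  # equal peaks tie-break to the lower wavelength
  prof2 <- exp(-((wl - 500)^2) / 18) + exp(-((wl - 600)^2) / 18)
  L$loadings <- matrix(prof2, ncol = 1)
  expect_equal(selectSensitiveBands(L, 1, k = 1)$selectedNm, 500)

  # fewer peaks than requested: warning, return what exists
  L$loadings <- matrix(exp(-((wl - 640)^2) / 18), ncol = 1)
  expect_warning(s4 <- selectSensitiveBands(L, 1, k = 3), "admissible")
  expect_equal(s4$selectedNm, 640)

  expect_error(selectSensitiveBands(L, 5, k = 1), "component")
})

test_that("synthetic study selection recovers the pigment-sensitive bands", {
  s <- generateStudy(generatorConfig(seed = 2024))
  X <- t(reflectance(s))
  L <- pcaLoadings(X, 2, standardize = FALSE,
                   wavelengths = wavelengths(s))
  expect_gt(L$explainedVariancePct[1], 50)   # dominant pigment component
  R <- varimaxRotate(L)
  bands <- sort(c(
    selectSensitiveBands(R, 1, k = 3, minSeparationNm = 15,
                         smoothNm = 7)$selectedNm,
    selectSensitiveBands(R, 2, k = 1, minSeparationNm = 15,
                         smoothNm = 7)$selectedNm))
  for (target in c(550, 678, 700))
    expect_lte(min(abs(bands - target)), 20, label = paste("band", target))
})
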