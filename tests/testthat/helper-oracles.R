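# Independent oracles, coded separately from the package implementation.

# --- spectra fixtures -------------------------------------------------------

toySpectrum <- function() {
  wl <- c(445, 500, 531, 550, 570, 678, 680, 700, 760, 800)
  refl <- c(8, 10, 12, 14, 13, 6, 6, 10, 48, 50)
  list(wl = wl, refl = refl)
}

flatSpectraSet <- function(level = 50, n = 1) {
  wl <- seq(400, 1000, by = 1)
  SpectraSet(matrix(level, length(wl), n), wl,
             data.frame(sample_id = paste0("s", seq_len(n)),
                        carotenoid_ugg = rep(300, n)))
}

randomSpectraSet <- function(n, seed = 1, lo = 5, hi = 60) {
  set.seed(seed)
  wl <- seq(400, 1000, by = 1)
  refl <- matrix(runif(length(wl) * n, lo, hi), length(wl), n)
  SpectraSet(refl, wl,
             data.frame(sample_id = paste0("s", seq_len(n)),
                        carotenoid_ugg = runif(n, 100, 500)))
}

# --- index oracles: direct arithmetic over a lookup closure ----------------
# bv(center, window): window 0 = linear interpolation, else window mean.
oracleBand <- function(wl, refl) {
  function(center, window = 0) {
    if (window > 0) {
      sel <- wl >= center - window / 2 & wl <= center + window / 2
      return(mean(refl[sel]))
    }
    stats::approx(wl, refl, xout = center)$y
  }
}

oracleIndexFuns <- list(
  RARS   = function(bv) bv(760) / bv(500),
  SIPI   = function(bv) (bv(800) - bv(445)) / (bv(800) - bv(680)),
  PSSR   = function(bv) bv(800) / bv(500),
  CRI550 = function(bv) 1 / bv(510) - 1 / bv(550),
  CRI700 = function(bv) 1 / bv(510) - 1 / bv(700),
  mCRI_G = function(bv) (1 / bv(515, 10) - 1 / bv(565, 10)) * bv(800),
  mCRI_RE = function(bv) (1 / bv(515, 10) - 1 / bv(700, 20)) * bv(800),
  PRI    = function(bv) (bv(531) - bv(570)) / (bv(531) + bv(570)),
  CAR1   = function(bv) bv(700) / bv(678),
  CAR2   = function(bv) bv(700) / bv(800),
  CAR3   = function(bv) (bv(550) + bv(700)) / bv(678),
  CAR4   = function(bv) (bv(550) + bv(700)) / bv(800),
  CAR5   = function(bv) bv(550) / bv(678),
  CAR6   = function(bv) bv(550) / bv(800),
  CAR7   = function(bv) (bv(550) + bv(700)) / (bv(678) + bv(800)),
  CAR8   = function(bv) bv(700) / (bv(678) + bv(800)),
  CAR9   = function(bv) bv(550) / (bv(678) + bv(800)))

# --- metric oracle ----------------------------------------------------------

oracleMetrics <- function(y, p) {
  n <- length(y)
  ybar <- sum(y) / n
  sse <- 0; sae <- 0; sbe <- 0; sst <- 0
  for (i in seq_len(n)) {
    e <- y[i] - p[i]
    sse <- sse + e^2
    sae <- sae + abs(p[i] - y[i])
    sbe <- sbe + e
    sst <- sst + (y[i] - ybar)^2
  }
  rmse <- sqrt(sse / n)
  list(r2 = 1 - sse / sst, rmse = rmse, nrmse = rmse / ybar * 100,
       mae = sae / n, mbe = sbe / n, nse = 1 - sse / sst)
}

# --- wet-lab oracle ---------------------------------------------------------

oracleCarotenoid <- function(A470, A644, A663, V, w) {
  (1000 * A470 - 3.27 * (12.21 * A663 - 2.81 * A644) -
     104 * (20.13 * A644 - 5.03 * A663)) / 229 / (V / w)
}

# --- KMO oracle: partial correlations via regression residuals -------------

oracleKMO <- function(X) {
  p <- ncol(X)
  R <- stats::cor(X)
  P <- matrix(0, p, p)
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    others <- setdiff(seq_len(p), c(i, j))
    ri <- stats::resid(stats::lm(X[, i] ~ X[, others]))
    rj <- stats::resid(stats::lm(X[, j] ~ X[, others]))
    P[i, j] <- P[j, i] <- stats::cor(ri, rj)
  }
  off <- upper.tri(R)
  sum(R[off]^2) / (sum(R[off]^2) + sum(P[off]^2))
}

# --- varimax criterion oracle (independent coding) -------------------------

oracleVarimaxCriterion <- function(L) {
  p <- nrow(L)
  total <- 0
  for (j in seq_len(ncol(L))) {
    s <- L[, j]^2
    total <- total + sum((s - mean(s))^2) / p
  }
  total
}

rot2 <- function(theta)
  matrix(c(cos(theta), -sin(theta), sin(theta), cos(theta)), 2, 2)

# --- brute-force regression tree -------------------------------------------
# Exhaustive search over all features and all midpoint thresholds,
# minimizing child SSE directly; same stopping rules and tie-breaks
# (lowest feature, lowest threshold) as the package contract.

oracleTree <- function(X, y, minLeaf = 2, maxDepth = 25, depth = 0) {
  n <- length(y)
  node <- list(leaf = TRUE, value = mean(y), n = n)
  if (depth >= maxDepth || n < 2 * minLeaf || all(y == y[1])) return(node)
  sseOf <- function(v) sum((v - mean(v))^2)
  parentSse <- sseOf(y)
  eps <- 1e-10 * (sum(y^2) + 1)   # same tie tolerance as the contract
  best <- NULL
  for (f in seq_len(ncol(X))) {
    xs <- sort(unique(X[, f]))
    if (length(xs) < 2) next
    for (t in (head(xs, -1) + tail(xs, -1)) / 2) {
      li <- X[, f] <= t
      if (sum(li) < minLeaf || sum(!li) < minLeaf) next
      gain <- parentSse - sseOf(y[li]) - sseOf(y[!li])
      if (is.null(best) || gain > best$gain + eps)
        best <- list(feature = f, threshold = t, gain = gain)
    }
  }
  if (is.null(best) || best$gain <= eps) return(node)
  li <- X[, best$feature] <= best$threshold
  list(leaf = FALSE, feature = colnames(X)[best$feature],
       threshold = best$threshold, value = mean(y), n = n,
       left = oracleTree(X[li, , drop = FALSE], y[li], minLeaf,
                         maxDepth, depth + 1),
       right = oracleTree(X[!li, , drop = FALSE], y[!li], minLeaf,
                          maxDepth, depth + 1))
}

expectSameTree <- function(a, b, tol = 1e-10) {
  expect_equal(isTRUE(a$leaf), isTRUE(b$leaf))
  expect_equal(a$value, b$value, tolerance = tol)
  expect_equal(a$n, b$n)
  if (!isTRUE(a$leaf) && !isTRUE(b$leaf)) {
    expect_identical(a$feature, b$feature)
    expect_equal(a$threshold, b$threshold, tolerance = tol)
    expectSameTree(a$left, b$left, tol)
    expectSameTree(a$right, b$right, tol)
  }
}

treeSse <- function(tree, X, y) sum((y - predictTree(tree, X))^2)
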