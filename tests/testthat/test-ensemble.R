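# Regression trees, reduced-error pruning, ensembles, cross-validation.

test_that("tree fits separable and constant data exactly", {
  X <- matrix(c(-5:-1, 1:5), ncol = 1, dimnames = list(NULL, "x"))
  y <- as.numeric(X[, 1] >= 0)
  tr <- fitTree(X, y)
  expect_equal(countNodes(tr), 3)          # one split
  expect_equal(predictTree(tr, X), y)

  trc <- fitTree(X, rep(7, 10))
  expect_true(trc$leaf)
  expect_equal(trc$value, 7)
  expect_equal(predictTree(trc, X), rep(7, 10))
})

test_that("best split matches a hand-checked 6-point case", {
  X <- matrix(c(1, 2, 3, 10, 11, 12), ncol = 1,
              dimnames = list(NULL, "x"))
  y <- c(1.0, 1.2, 0.9, 5.0, 5.2, 4.9)
  tr <- fitTree(X, y, minLeaf = 2, maxDepth = 1)
  expect_false(tr$leaf)
  expect_equal(tr$threshold, 6.5)          # midpoint of 3 and 10
  expect_equal(tr$left$value, mean(y[1:3]))
  expect_equal(tr$right$value, mean(y[4:6]))
})

test_that("full-feature trees equal the exhaustive best-split oracle", {
  set.seed(55)
  for (i in 1:12) {
    n <- sample(8:30, 1); p <- sample(1:3, 1)
    X <- matrix(round(rnorm(n * p), 2), n, p,
                dimnames = list(NULL, paste0("x", seq_len(p))))
    y <- rnorm(n) + X[, 1]
    tr <- fitTree(X, y)
    or <- oracleTree(X, y)
    expectSameTree(tr, or)
  }
})

test_that("reduced-error pruning never hurts held-out SSE or size", {
  set.seed(66)
  shrunk <- 0
  for (i in 1:30) {
    n <- 60
    X <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("a", "b")))
    y <- rnorm(n)                            # pure noise
    Xp <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("a", "b")))
    yp <- rnorm(n)
    tr <- fitTree(X, y)
    pr <- repPrune(tr, Xp, yp)
    expect_lte(treeSse(pr, Xp, yp), treeSse(tr, Xp, yp) + 1e-9)
    expect_lte(countNodes(pr), countNodes(tr))
    if (countNodes(pr) < countNodes(tr)) shrunk <- shrunk + 1
  }
  expect_gt(shrunk, 15)      # noise trees usually shrink

  # single leaf is a fixed point
  leafTree <- fitTree(matrix(1:4, ncol = 1, dimnames = list(NULL, "x")),
                      rep(3, 4))
  expect_identical(repPrune(leafTree,
                            matrix(1:4, ncol = 1,
                                   dimnames = list(NULL, "x")),
                            rep(3, 4)),
                   leafTree)

  # pruning with the perfectly fit training set changes nothing
  X <- matrix(c(-3, -2, -1, 1, 2, 3), ncol = 1,
              dimnames = list(NULL, "x"))
  y <- c(0, 0, 0, 1, 1, 1)
  tr2 <- fitTree(X, y)
  pr2 <- repPrune(tr2, X, y)
  expect_equal(predictTree(pr2, X), y)
  expect_equal(countNodes(pr2), countNodes(tr2))
})

test_that("ensembles of a constant response predict that constant", {
  X <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  y <- rep(4.2, 20)
  for (kind in c("single_tree", "reptree", "bagging", "random_subspace",
                 "random_forest")) {
    m <- fitEnsemble(kind, X, y, k = 5, seed = 2)
    expect_equal(predictEnsemble(m, X), rep(4.2, 20), label = kind)
  }
})

test_that("bagging without bootstrap at k = 1 is a single tree", {
  set.seed(3)
  X <- matrix(rnorm(60), 30, 2, dimnames = list(NULL, c("a", "b")))
  y <- X[, 1] + rnorm(30, 0, 0.2)
  m <- fitEnsemble("bagging", X, y, k = 1, seed = 5,
                   params = list(bootstrap = FALSE))
  tr <- fitTree(X, y)
  expect_equal(predictEnsemble(m, X), predictTree(tr, X))
})

test_that("ensembles are reproducible and member-order invariant", {
  set.seed(14)
  X <- matrix(rnorm(120), 40, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- X[, 1] - 0.5 * X[, 2] + rnorm(40, 0, 0.3)
  m1 <- fitEnsemble("random_forest", X, y, k = 12, seed = 9)
  m2 <- fitEnsemble("random_forest", X, y, k = 12, seed = 9)
  expect_identical(predictEnsemble(m1, X), predictEnsemble(m2, X))

  m3 <- m1
  m3$members <- rev(m3$members)
  expect_equal(predictEnsemble(m3, X), predictEnsemble(m1, X),
               tolerance = 1e-12)

  expect_error(fitEnsemble("random_subspace", X, y, k = 2,
                           params = list(q = 9)), "exceeds")
  expect_error(fitEnsemble("random_forest", X, y, k = 2,
                           params = list(mtry = 7)), "exceeds")
  expect_error(fitEnsemble("gradient_boost", X, y), "arg")
})

test_that("bagging stabilizes predictions relative to a single tree", {
  set.seed(28)
  nTest <- 40
  Xtest <- matrix(rnorm(nTest * 2), nTest, 2,
                  dimnames = list(NULL, c("a", "b")))
  predsB <- matrix(0, nTest, 20); predsS <- matrix(0, nTest, 20)
  for (s in 1:20) {
    set.seed(1000 + s)
    X <- matrix(rnorm(120 * 2), 120, 2,
                dimnames = list(NULL, c("a", "b")))
    y <- X[, 1] + rnorm(120, 0, 1)
    predsB[, s] <- predictEnsemble(
      fitEnsemble("bagging", X, y, k = 25, seed = s), Xtest)
    predsS[, s] <- predictTree(fitTree(X, y), Xtest)
  }
  expect_lt(mean(apply(predsB, 1, var)), mean(apply(predsS, 1, var)))
})

test_that("cross-validation folds are balanced, exhaustive, reproducible", {
  X <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  y <- rnorm(10)
  cv <- crossValidate("single_tree", X, y, folds = 5, k = 1, seed = 4)
  expect_equal(as.integer(table(cv$foldAssignment)), rep(2L, 5))
  expect_length(cv$perFold, 5)
  cv2 <- crossValidate("single_tree", X, y, folds = 5, k = 1, seed = 4)
  expect_identical(cv$foldAssignment, cv2$foldAssignment)
  expect_identical(cv$oofPredictions, cv2$oofPredictions)
  expect_error(crossValidate("single_tree", X, y, folds = 11), "exceeds")
})

test_that("cross-validation is perfect on tree-learnable structure", {
  X <- matrix(c(-9, -7, -5, -3, -1, 1, 3, 5, 7, 9), ncol = 1,
              dimnames = list(NULL, "x"))
  y <- as.numeric(X[, 1] > 0) * 5
  cv <- crossValidate("single_tree", X, y, folds = 5, k = 1, seed = 2)
  expect_equal(cv$pooled$r2, 1, tolerance = 1e-12)
  expect_equal(cv$oofPredictions, y)
})

test_that("tree serialization round-trips and rules read as if-then", {
  set.seed(31)
  X <- matrix(rnorm(60), 30, 2, dimnames = list(NULL, c("a", "b")))
  y <- X[, 1] + rnorm(30, 0, 0.3)
  tr <- fitTree(X, y)
  tr2 <- treeFromJSON(treeToJSON(tr))
  expect_equal(predictTree(tr2, X), predictTree(tr, X))
  expect_equal(countNodes(tr2), countNodes(tr))
  rules <- treeRules(tr)
  expect_true(any(grepl("<=", rules)))
  expect_true(any(grepl("->", rules)))
})

test_that("the learner comparison reports every requested kind", {
  s <- generateStudy(generatorConfig(nSamples = 90, seed = 5))
  rep <- suppressMessages(runMlComparison(
    s, split = splitPooled(0.7, seed = 5),
    kinds = c("random_forest", "reptree", "random_subspace", "bagging"),
    k = 15, seed = 5))
  expect_equal(nrow(rep), 4)
  expect_setequal(rep$kind, c("random_forest", "reptree",
                              "random_subspace", "bagging"))
  expect_equal(rep$n_train[1], 63)
  expect_equal(rep$n_test[1], 27)
  expect_true(all(rep$r2_train > 0))
  expect_error(suppressMessages(runMlComparison(s, kinds = "nope")), "arg")
})
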