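# Metrics bundle, OLS calibration, split schemes and the index suite.

test_that("metrics reproduce hand-worked values", {
  m <- regressionMetrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(m$rmse, 0); expect_equal(m$mae, 0); expect_equal(m$mbe, 0)
  expect_equal(m$r2, 1); expect_equal(m$nse, 1)

  m2 <- regressionMetrics(c(2, 4, 6), c(1, 3, 5))
  expect_equal(m2$rmse, 1)
  expect_equal(m2$mae, 1)
  expect_equal(m2$mbe, 1)          # observed - predicted: underestimation
  expect_equal(m2$nrmse, 25.0)

  # predicting the observed mean gives NSE exactly 0
  y <- c(3, 7, 11, 2)
  m3 <- regressionMetrics(y, rep(mean(y), 4))
  expect_equal(m3$nse, 0)

  # printed-variant NSE normalizes by the predictions' spread
  m4 <- regressionMetrics(c(2, 4, 6), c(1, 3, 5), nseAsPrinted = TRUE)
  expect_equal(m4$nse, 1 - 3 / 11)
})

test_that("metrics agree with an independently coded oracle", {
  set.seed(41)
  for (i in 1:1000) {
    n <- sample(2:40, 1)
    y <- rnorm(n, 300, 80); p <- y + rnorm(n, 0, 30)
    m <- regressionMetrics(y, p)
    o <- oracleMetrics(y, p)
    for (nm in names(o))
      expect_equal(m[[nm]], o[[nm]], tolerance = 1e-10, label = nm)
  }
})

test_that("degenerate metric inputs are flagged, not fatal", {
  m <- regressionMetrics(c(5, 5, 5), c(4, 5, 6))
  expect_true(is.na(m$r2)); expect_true(is.na(m$nse))
  expect_false(is.na(m$rmse))
  m2 <- regressionMetrics(c(-1, 0, 1), c(0, 0, 0))
  expect_true(is.na(m2$nrmse))
  # flagged-missing pairs are dropped
  m3 <- regressionMetrics(c(2, NA, 4, 6), c(1, 9, 3, 5))
  expect_equal(m3$n, 3)
  expect_equal(m3$rmse, 1)
  expect_error(regressionMetrics(c(1, NA), c(1, 2)), "at least 2")
})

test_that("translation shifts NRMSE but not RMSE/MAE/MBE", {
  set.seed(6)
  y <- rnorm(20, 100, 10); p <- y + rnorm(20, 2, 5)
  a <- regressionMetrics(y, p)
  b <- regressionMetrics(y + 50, p + 50)
  expect_equal(a$rmse, b$rmse)
  expect_equal(a$mae, b$mae)
  expect_equal(a$mbe, b$mbe)
  expect_equal(b$nrmse, a$rmse / (mean(y) + 50) * 100)
})

test_that("OLS calibration matches closed-form least squares", {
  f <- fitLinearCalibration(c(5, 6, 7), 2 * c(5, 6, 7) + 1)
  expect_equal(f$slope, 2, tolerance = 1e-12)
  expect_equal(f$intercept, 1, tolerance = 1e-12)

  f2 <- fitLinearCalibration(c(0, 1, 2), c(1, 3, 4))
  expect_equal(f2$slope, 1.5, tolerance = 1e-10)
  expect_equal(f2$intercept, 7 / 6, tolerance = 1e-10)
  expect_equal(f2$intercept, 1.1667, tolerance = 1e-4)

  expect_error(fitLinearCalibration(rep(2, 5), rnorm(5)), "variance")
  expect_error(fitLinearCalibration(c(1, 2), c(1, 2)), "at least 3")
})

test_that("train-set OLS predictions give R2 = NSE and zero MBE", {
  set.seed(9)
  for (i in 1:10) {
    x <- rnorm(30); y <- 2 + 3 * x + rnorm(30)
    f <- fitLinearCalibration(x, y)
    pred <- f$intercept + f$slope * x
    m <- regressionMetrics(y, pred)
    expect_equal(m$mbe, 0, tolerance = 1e-9)
    expect_equal(m$r2, m$nse, tolerance = 1e-9)
    expect_equal(m$r2, cor(x, y)^2, tolerance = 1e-9)
  }
})

test_that("split schemes partition exactly and deterministically", {
  meta <- data.frame(sample_id = paste0("s", 1:9),
                     carotenoid_ugg = 1:9,
                     year = rep(c(2021, 2022, 2023), each = 3))
  s <- SpectraSet(matrix(50, 2, 9), c(500, 600), meta)

  sp <- makeSplit(s, splitByYears(c(2021, 2022), 2023))
  expect_setequal(sp$test, paste0("s", 7:9))
  expect_setequal(c(sp$train, sp$test), meta$sample_id)
  expect_length(intersect(sp$train, sp$test), 0)

  sp2 <- makeSplit(s, splitPooled(2 / 3, seed = 5))
  expect_length(sp2$train, 6)
  expect_length(sp2$test, 3)
  sp3 <- makeSplit(s, splitPooled(2 / 3, seed = 5))
  expect_identical(sp2, sp3)

  meta10 <- data.frame(sample_id = paste0("s", 1:10),
                       carotenoid_ugg = 1:10)
  s10 <- SpectraSet(matrix(50, 2, 10), c(500, 600), meta10)
  sp4 <- makeSplit(s10, splitPooled(0.7, seed = 1))
  expect_length(sp4$train, 7)
  expect_length(sp4$test, 3)

  expect_error(makeSplit(s, splitByYears(2021, 2030)), "2030")
  expect_error(splitByYears(2021, 2021), "disjoint")
  expect_error(splitPooled(1.2), "in \\(0, 1\\)")
})

test_that("index suite reports all scheme x index cells, ranked by test R2", {
  s <- generateStudy(generatorConfig(nSamples = 135, seed = 12))
  schemes <- list(splitByYears(c(2021, 2022), 2023),
                  splitByYears(c(2021, 2023), 2022),
                  splitByYears(c(2022, 2023), 2021),
                  splitPooled(2 / 3, seed = 12))
  rep <- suppressMessages(evaluateIndexSuite(s, paste0("CAR", 1:9),
                                             schemes))
  expect_equal(nrow(rep), 36)
  expect_equal(as.integer(table(rep$scheme)), rep(9L, 4))
  for (sc in unique(rep$scheme)) {
    r2 <- rep$r2_test[rep$scheme == sc]
    expect_true(all(diff(r2[!is.na(r2)]) <= 1e-12))
  }
  expect_true(all(rep$status == "ok"))
  expect_error(evaluateIndexSuite(s, "CAR1",
                                  list(splitByYears(2021, 2030))), "2030")
})

test_that("an index that generates the response ranks first", {
  set.seed(77)
  s <- randomSpectraSet(120, seed = 77)
  tab <- suppressMessages(computeIndexTable(s, "CAR7"))
  meta <- as.data.frame(sampleData(s))
  meta$carotenoid_ugg <- 100 + 50 * tab$CAR7 + rnorm(120, 0, 0.3)
  s2 <- SpectraSet(reflectance(s), wavelengths(s), meta)
  rep <- suppressMessages(
    evaluateIndexSuite(s2, paste0("CAR", 1:9),
                       list(splitPooled(2 / 3, seed = 1))))
  expect_equal(rep$index[1], "CAR7")
  expect_gt(rep$r2_test[1], 0.95)
})
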