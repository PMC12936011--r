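# End-to-end pipeline: simulate (or load) -> indices -> band selection ->
# calibration -> ensemble comparison, with deterministic CSV reports.

.fmt6 <- function(df) {
  for (j in seq_along(df))
    if (is.double(df[[j]])) df[[j]] <- signif(df[[j]], 6)
  df
}

#' Default pipeline configuration
#'
#' @param seed master seed.
#' @return Nested list understood by \code{\link{runPipeline}}: either a
#'   \code{simulate} block (generator arguments) or an \code{input} path;
#'   \code{indices} (names or "all"); \code{schemes} (list of scheme
#'   descriptors); \code{bandsel} (components, kPrimary, kSecondary,
#'   minSeparationNm, smoothNm, kmoStepNm); \code{ml} (kinds, trees,
#'   trainFraction, cvFolds).
#' @export
pipelineDefaults <- function(seed = 1L) {
  list(
    seed = seed,
    simulate = list(nSamples = 540L, noiseSdPct = 0.5),
    input = NULL,
    indices = "all",
    schemes = list(
      list(kind = "by_years", train = c(2021, 2022), test = 2023),
      list(kind = "by_years", train = c(2021, 2023), test = 2022),
      list(kind = "by_years", train = c(2022, 2023), test = 2021),
      list(kind = "pooled_random", trainFraction = 2 / 3)),
    bandsel = list(components = 2L, kPrimary = 3L, kSecondary = 1L,
                   minSeparationNm = 15, smoothNm = 7, kmoStepNm = 25),
    ml = list(kinds = c("random_forest", "reptree", "random_subspace",
                        "bagging"),
              trees = 100L, trainFraction = 0.7, cvFolds = 0L))
}

.resolveScheme <- function(s, seed) {
  if (inherits(s, "SplitScheme")) return(s)
  if (s$kind == "by_years") splitByYears(s$train, s$test)
  else splitPooled(s$trainFraction, seed = if (is.null(s$seed)) seed
                                           else s$seed)
}

#' Run the full analysis pipeline
#'
#' Stages: (1) simulate a study table or load one from disk; (2) compute
#' the index table; (3) covariance-PCA + varimax band selection with a KMO
#' adequacy check on a wavelength subsample; (4) per-index linear
#' calibration over the configured split schemes; (5) ensemble-learner
#' comparison on the CAR features. Writes \code{indices.csv},
#' \code{loadings.csv}, \code{calibration_report.csv},
#' \code{ml_report.csv} and \code{run.log} into \code{outDir}. Reports are
#' deterministic: identical config and seed give byte-identical files
#' (floats at 6 significant digits).
#'
#' @param config nested list as in \code{\link{pipelineDefaults}}, or the
#'   path of a YAML file holding one; missing entries take defaults.
#' @param outDir output directory (created if needed).
#' @param seed overrides \code{config$seed} when non-NULL.
#' @return Invisibly, a list with the in-memory stage results.
#' @export
runPipeline <- function(config = list(), outDir, seed = NULL) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(pipelineDefaults(), config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (!is.null(config$input) && !is.null(config$simulate) &&
      length(config$input))
    stop("config must name exactly one of 'input' or 'simulate'")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  logLines <- character(0)
  logIt <- function(...) logLines <<- c(logLines, paste0(...))
  logIt("caroSpectra pipeline, package version ",
        as.character(utils::packageVersion("caroSpectra")))
  logIt("seed: ", cfg$seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(c(logLines, paste0("ERROR in stage ", name, ": ",
                                    conditionMessage(e))),
                 file.path(outDir, "run.log"))
      stop("stage ", name, ": ", conditionMessage(e), call. = FALSE)
    })
  }

  study <- stage("input", {
    if (!is.null(cfg$input) && length(cfg$input)) {
      if (!file.exists(cfg$input))
        stop("input file not found: ", cfg$input)
      logIt("input: ", cfg$input)
      readSampleTable(cfg$input, layout = "wide")
    } else {
      sim <- cfg$simulate
      sim$seed <- cfg$seed
      gcfg <- do.call(generatorConfig, sim)
      logIt("simulate: n=", gcfg$nSamples, " noiseSdPct=",
            gcfg$noiseSdPct, " seed=", gcfg$seed)
      generateStudy(gcfg)
    }
  })
  logIt("samples: ", ncol(study), "; wavelengths: ", nrow(study))

  idxNames <- if (identical(cfg$indices, "all")) names(builtinIndices())
              else cfg$indices
  idxTab <- stage("indices", {
    tab <- withCallingHandlers(
      computeIndexTable(study, idxNames),
      message = function(m) {
        logIt(sub("\n$", "", conditionMessage(m)))
        invokeRestart("muffleMessage")
      })
    tab
  })
  data.table::fwrite(.fmt6(idxTab), file.path(outDir, "indices.csv"))
  logIt("indices.csv: ", nrow(idxTab), " x ", ncol(idxTab) - 1L)

  bandsel <- stage("bandsel", {
    bs <- cfg$bandsel
    X <- t(reflectance(study))
    colnames(X) <- paste0("wl_", wavelengths(study))
    L <- pcaLoadings(X, nComponents = bs$components, standardize = FALSE,
                     wavelengths = wavelengths(study))
    logIt("explained variance %: ",
          paste(sprintf("%.3f", L$explainedVariancePct), collapse = ", "))
    R <- varimaxRotate(L)
    selP <- selectSensitiveBands(R, component = 1, k = bs$kPrimary,
                                 minSeparationNm = bs$minSeparationNm,
                                 smoothNm = bs$smoothNm)
    selS <- if (bs$kSecondary > 0 && bs$components >= 2)
      selectSensitiveBands(R, component = 2, k = bs$kSecondary,
                           minSeparationNm = bs$minSeparationNm,
                           smoothNm = bs$smoothNm)$selectedNm
      else numeric(0)
    bands <- sort(unique(c(selP$selectedNm, selS)))
    logIt("selected bands (nm): ", paste(bands, collapse = ", "))
    wl <- wavelengths(study)
    sub <- seq(1, length(wl), by = max(1L, round(bs$kmoStepNm /
                                                   median(diff(wl)))))
    kmoVal <- kmo(X[, sub, drop = FALSE])
    logIt(sprintf("KMO (every %g nm, %d variables): %.4f",
                  bs$kmoStepNm, length(sub), kmoVal))
    carCor <- componentVariableCorrelation(X, R, carotenoid(study),
                                           standardize = FALSE)
    logIt("carotenoid-score correlation: ",
          paste(sprintf("%s=%.3f", names(carCor), carCor),
                collapse = ", "))
    loadDf <- data.frame(wavelength_nm = L$wavelengths,
                         L$loadings, R$loadings, check.names = FALSE)
    data.table::fwrite(.fmt6(loadDf), file.path(outDir, "loadings.csv"))
    list(loadings = L, rotated = R, bands = bands, kmo = kmoVal,
         carCor = carCor)
  })

  calib <- stage("calibrate", {
    schemes <- lapply(cfg$schemes, .resolveScheme, seed = cfg$seed)
    carNames <- intersect(paste0("CAR", 1:9), idxNames)
    rep <- evaluateIndexSuite(study, carNames, schemes)
    data.table::fwrite(.fmt6(rep),
                       file.path(outDir, "calibration_report.csv"))
    logIt("calibration_report.csv: ", nrow(rep), " rows")
    rep
  })

  ml <- stage("ml", {
    m <- cfg$ml
    rep <- runMlComparison(
      study, split = splitPooled(m$trainFraction, seed = cfg$seed),
      kinds = m$kinds, k = m$trees, seed = cfg$seed)
    if (!is.null(m$cvFolds) && m$cvFolds >= 2) {
      tab <- computeIndexTable(study, paste0("CAR", 1:9))
      feat <- as.matrix(tab[, paste0("CAR", 1:9)])
      cvRows <- lapply(m$kinds, function(kind) {
        cv <- crossValidate(kind, feat, carotenoid(study),
                            folds = m$cvFolds, k = m$trees,
                            seed = cfg$seed)
        logIt(sprintf("cv %s: pooled R2=%.3f RMSE=%.3f", kind,
                      cv$pooled$r2, cv$pooled$rmse))
        data.frame(kind = kind, cv_r2 = cv$pooled$r2,
                   cv_rmse = cv$pooled$rmse)
      })
      rep <- merge(rep, do.call(rbind, cvRows), by = "kind", sort = FALSE)
    }
    data.table::fwrite(.fmt6(rep), file.path(outDir, "ml_report.csv"))
    logIt("ml_report.csv: ", nrow(rep), " rows")
    rep
  })

  writeLines(logLines, file.path(outDir, "run.log"))
  invisible(list(study = study, indices = idxTab, bandsel = bandsel,
                 calibration = calib, ml = ml))
}
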