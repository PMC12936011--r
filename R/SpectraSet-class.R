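#' SpectraSet: leaf reflectance spectra joined to pigment measurements
#'
#' A \code{SpectraSet} extends \link[SummarizedExperiment]{SummarizedExperiment}
#' with wavelengths as rows and samples as columns. The single assay
#' \code{"reflectance"} holds percent reflectance (0-100); \code{rowData}
#' carries the wavelength grid (nm, strictly increasing, possibly irregular)
#' and \code{colData} the per-sample study metadata: \code{sample_id},
#' \code{carotenoid_ugg} (ug/g fresh weight), \code{chlorophyll_ugg},
#' \code{year}, \code{stage} (BBCH code), \code{site_id}, \code{irrigated}.
#'
#' @slot .. see \code{SummarizedExperiment}; no additional slots.
#' @aliases SpectraSet-class
#' @export
setClass("SpectraSet", contains = "SummarizedExperiment")

setValidity("SpectraSet", function(object) {
  msg <- character(0)
  if (!"reflectance" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'reflectance' is required")
  wl <- rowData(object)$wavelength_nm
  if (is.null(wl)) {
    msg <- c(msg, "rowData column 'wavelength_nm' is required")
  } else {
    if (any(!is.finite(wl))) msg <- c(msg, "wavelengths must be finite")
    if (any(diff(wl) <= 0))
      msg <- c(msg, "wavelengths must be strictly increasing")
  }
  if ("reflectance" %in% SummarizedExperiment::assayNames(object)) {
    r <- SummarizedExperiment::assay(object, "reflectance")
    if (any(!is.finite(r))) msg <- c(msg, "reflectance must be finite")
  }
  cd <- colData(object)
  if (!"sample_id" %in% colnames(cd)) {
    msg <- c(msg, "colData column 'sample_id' is required")
  } else if (anyDuplicated(cd$sample_id)) {
    msg <- c(msg, "sample_id values must be unique")
  }
  if (!"carotenoid_ugg" %in% colnames(cd))
    msg <- c(msg, "colData column 'carotenoid_ugg' is required")
  if (length(msg)) msg else TRUE
})

#' Construct a SpectraSet
#'
#' @param reflectance numeric matrix, wavelengths x samples, percent units.
#' @param wavelengths numeric vector of wavelengths in nm, strictly
#'   increasing, one per row of \code{reflectance}.
#' @param sampleData data.frame (or DataFrame) of per-sample metadata with at
#'   least \code{sample_id} and \code{carotenoid_ugg}; one row per column of
#'   \code{reflectance}.
#' @return A validated \linkS4class{SpectraSet}. Reflectance outside
#'   \code{[0, 100]} is allowed but flagged with a warning.
#' @examples
#' wl <- seq(400, 1000, by = 100)
#' refl <- matrix(50, length(wl), 2)
#' meta <- data.frame(sample_id = c("a", "b"), carotenoid_ugg = c(300, 400))
#' s <- SpectraSet(refl, wl, meta)
#' @export
SpectraSet <- function(reflectance, wavelengths, sampleData) {
  reflectance <- as.matrix(reflectance)
  if (nrow(reflectance) != length(wavelengths))
    stop("nrow(reflectance) must equal length(wavelengths)")
  sampleData <- S4Vectors::DataFrame(sampleData, check.names = FALSE)
  if (nrow(sampleData) != ncol(reflectance))
    stop("sampleData must have one row per spectrum")
  nOut <- sum(reflectance < 0 | reflectance > 100, na.rm = TRUE)
  if (nOut > 0)
    warning(nOut, " reflectance value(s) outside [0, 100]")
  dimnames(reflectance) <- list(NULL, sampleData$sample_id)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(reflectance = reflectance),
    rowData = S4Vectors::DataFrame(wavelength_nm = as.numeric(wavelengths)),
    colData = sampleData)
  new("SpectraSet", se)
}

#' @rdname wavelengths
#' @export
setMethod("wavelengths", "SpectraSet", function(x)
  as.numeric(rowData(x)$wavelength_nm))

#' @rdname reflectance
#' @export
setMethod("reflectance", "SpectraSet", function(x)
  SummarizedExperiment::assay(x, "reflectance"))

#' @rdname sampleData
#' @export
setMethod("sampleData", "SpectraSet", function(x) colData(x))

#' @rdname carotenoid
#' @export
setMethod("carotenoid", "SpectraSet", function(x)
  as.numeric(colData(x)$carotenoid_ugg))

setMethod("show", "SpectraSet", function(object) {
  wl <- wavelengths(object)
  cat("SpectraSet with", ncol(object), "spectra on", length(wl),
      "wavelengths\n")
  cat("  grid: ", min(wl), "-", max(wl), " nm\n", sep = "")
  car <- colData(object)$carotenoid_ugg
  if (length(car) && any(is.finite(car)))
    cat(sprintf("  carotenoid_ugg: %.1f-%.1f (mean %.1f)\n",
                min(car, na.rm = TRUE), max(car, na.rm = TRUE),
                mean(car, na.rm = TRUE)))
  extra <- setdiff(colnames(colData(object)),
                   c("sample_id", "carotenoid_ugg"))
  if (length(extra))
    cat("  metadata:", paste(extra, collapse = ", "), "\n")
})

# Interpolation / window lookup on a raw grid. Shared by both bandValue
# methods; `refl` may be a vector or a wavelength x sample matrix.
.bandLookup <- function(wl, refl, wavelengthNm, windowNm) {
  if (!is.numeric(wavelengthNm) || length(wavelengthNm) != 1L)
    stop("wavelengthNm must be a single number")
  if (windowNm < 0) stop("windowNm must be >= 0")
  mat <- is.matrix(refl)
  if (windowNm > 0) {
    inWin <- which(wl >= wavelengthNm - windowNm / 2 &
                   wl <= wavelengthNm + windowNm / 2)
    if (!length(inWin))
      stop("window [", wavelengthNm - windowNm / 2, ", ",
           wavelengthNm + windowNm / 2, "] nm contains no grid point")
    if (mat) return(colMeans(refl[inWin, , drop = FALSE]))
    return(mean(refl[inWin]))
  }
  if (wavelengthNm < wl[1] || wavelengthNm > wl[length(wl)])
    stop("wavelength ", wavelengthNm, " nm outside grid range [",
         wl[1], ", ", wl[length(wl)], "]")
  hit <- which(wl == wavelengthNm)
  if (length(hit)) {
    if (mat) return(refl[hit[1], ]) else return(refl[hit[1]])
  }
  hi <- which(wl > wavelengthNm)[1]
  lo <- hi - 1L
  f <- (wavelengthNm - wl[lo]) / (wl[hi] - wl[lo])
  if (mat) (1 - f) * refl[lo, ] + f * refl[hi, ]
  else (1 - f) * refl[lo] + f * refl[hi]
}

#' @rdname bandValue
#' @export
setMethod("bandValue", "SpectraSet",
  function(x, wavelengthNm, windowNm = 0, ...) {
    .bandLookup(wavelengths(x), reflectance(x), wavelengthNm, windowNm)
  })

#' @rdname bandValue
#' @param wavelengths numeric grid for the numeric-vector method.
#' @export
setMethod("bandValue", "numeric",
  function(x, wavelengthNm, windowNm = 0, ..., wavelengths) {
    if (length(x) != length(wavelengths))
      stop("reflectance and wavelengths differ in length")
    .bandLookup(as.numeric(wavelengths), as.numeric(x),
                wavelengthNm, windowNm)
  })

#' @rdname averageReplicates
#' @export
setMethod("averageReplicates", "SpectraSet", function(x, groups) {
  ids <- colData(x)$sample_id
  if (!all(ids %in% names(groups)))
    stop("groups must name every sample_id; missing: ",
         paste(head(setdiff(ids, names(groups)), 5), collapse = ", "))
  grp <- as.character(groups[ids])
  uniq <- unique(grp)
  refl <- reflectance(x)
  newRefl <- vapply(uniq, function(g)
    rowMeans(refl[, grp == g, drop = FALSE]), numeric(nrow(refl)))
  cd <- as.data.frame(colData(x))
  metaCols <- setdiff(colnames(cd), "sample_id")
  newMeta <- lapply(uniq, function(g) {
    sub <- cd[grp == g, metaCols, drop = FALSE]
    for (cl in metaCols) {
      u <- unique(sub[[cl]])
      u <- u[!is.na(u)]
      if (length(unique(sub[[cl]])) > 1L && length(u) > 1L)
        stop("conflicting metadata '", cl, "' within group '", g, "'")
    }
    sub[1, , drop = FALSE]
  })
  newMeta <- do.call(rbind, newMeta)
  newMeta$sample_id <- uniq
  rownames(newMeta) <- NULL
  SpectraSet(newRefl, wavelengths(x),
             newMeta[, c("sample_id", metaCols), drop = FALSE])
})
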