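#' @import methods
#' @importFrom stats approx cor cov dnorm pnorm rnorm runif sd var lm coef
#'   median uniroot prcomp quantile setNames complete.cases
#' @importFrom utils head tail
NULL

#' Wavelength grid of a spectra container
#'
#' @param x a \linkS4class{SpectraSet}.
#' @return Numeric vector of wavelengths in nm, strictly increasing.
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' Reflectance matrix accessor
#'
#' @param x a \linkS4class{SpectraSet}.
#' @return Numeric matrix (wavelengths x samples) of percent reflectance.
#' @export
setGeneric("reflectance", function(x) standardGeneric("reflectance"))

#' Per-sample metadata accessor
#'
#' @param x a \linkS4class{SpectraSet}.
#' @return A \code{DataFrame} with one row per sample.
#' @export
setGeneric("sampleData", function(x) standardGeneric("sampleData"))

#' Carotenoid content accessor
#'
#' @param x a \linkS4class{SpectraSet}.
#' @return Numeric vector of carotenoid content (ug/g fresh weight).
#' @export
setGeneric("carotenoid", function(x) standardGeneric("carotenoid"))

#' Reflectance at a wavelength
#'
#' Looks up percent reflectance at \code{wavelengthNm}. With
#' \code{windowNm = 0} the value is linearly interpolated between the two
#' bracketing grid points (an exact grid hit returns the stored value);
#' with \code{windowNm > 0} it is the unweighted mean of all grid points
#' whose wavelength lies in \code{[center - w/2, center + w/2]}.
#'
#' @param x a \linkS4class{SpectraSet} or a numeric reflectance vector.
#' @param wavelengthNm query wavelength in nm; must lie within the grid.
#' @param windowNm full window width in nm (default 0 = interpolation).
#' @param ... for the numeric method, \code{wavelengths=} gives the grid.
#' @return For a \code{SpectraSet}, a named numeric vector (one value per
#'   sample); for a numeric vector, a single value.
#' @export
setGeneric("bandValue", function(x, wavelengthNm, windowNm = 0, ...)
  standardGeneric("bandValue"))

#' Average replicate measurements
#'
#' Collapses technical replicates (e.g. triplicate scans of one leaf) to a
#' single spectrum per physical leaf by per-wavelength arithmetic mean.
#' Metadata must agree within each group.
#'
#' @param x a \linkS4class{SpectraSet}.
#' @param groups named character vector mapping every sample_id to a leaf id.
#' @return A \code{SpectraSet} with one record per leaf id.
#' @export
setGeneric("averageReplicates", function(x, groups)
  standardGeneric("averageReplicates"))

#' Evaluate a spectral index
#'
#' @param x a \linkS4class{SpectraSet} or numeric reflectance vector.
#' @param definition a \linkS4class{SpectralIndex}.
#' @param ... for the numeric method, \code{wavelengths=} gives the grid.
#' @return Numeric value(s); undefined results (denominator magnitude below
#'   1e-12, or non-finite) are returned as \code{NA} rather than errors.
#' @export
setGeneric("computeIndex", function(x, definition, ...)
  standardGeneric("computeIndex"))
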