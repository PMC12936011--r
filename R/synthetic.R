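# Synthetic study generator: pigment sampling with the field campaign's
# summary statistics, a Gaussian-absorption + logistic red-edge leaf
# reflectance model, and balanced year/stage/site assignment.

#' Generator configuration
#'
#' Defaults emulate the field study conditions: 540 samples over three
#' years x three BBCH stages x five sites, carotenoid in
#' [114.72, 526.97] ug/g with mean 382.31 and sd 86.02, a
#' carotenoid-chlorophyll squared correlation of 0.925, and 0.5 percent
#' reflectance noise.
#'
#' @param nSamples total samples (default 540).
#' @param carRangeUgg carotenoid truncation range, ug/g.
#' @param carMeanSdUgg target mean and sd of carotenoid, ug/g.
#' @param chlCarR2Target target squared correlation between carotenoid and
#'   total chlorophyll (must be < 1).
#' @param noiseSdPct additive reflectance noise sd, percent units.
#' @param years study years.
#' @param stages BBCH stage labels.
#' @param nSites number of sampling sites (site S1 is non-irrigated).
#' @param yearCarOffsetUgg named per-year shifts of the carotenoid mean
#'   (applied inside the truncated draw so the range always holds).
#' @param chlPerCar,chlBaseUgg slope/intercept of the chlorophyll coupling
#'   (ug/g total chlorophyll per ug/g carotenoid).
#' @param chlabRatio chlorophyll a:b ratio (default 3).
#' @param seed master seed; pigment, spectral-noise and assignment
#'   substreams are derived from it.
#' @return list of class \code{"GeneratorConfig"}.
#' @export
generatorConfig <- function(nSamples = 540L,
                            carRangeUgg = c(114.72, 526.97),
                            carMeanSdUgg = c(382.31, 86.02),
                            chlCarR2Target = 0.925,
                            noiseSdPct = 0.5,
                            years = c(2021L, 2022L, 2023L),
                            stages = c("BBCH16", "BBCH51", "BBCH79"),
                            nSites = 5L,
                            yearCarOffsetUgg = c("2021" = 20, "2022" = -28,
                                                 "2023" = 8),
                            chlPerCar = 5.5, chlBaseUgg = 100,
                            chlabRatio = 3, seed = 1L) {
  if (carRangeUgg[1] >= carRangeUgg[2]) stop("invalid carotenoid range")
  if (noiseSdPct < 0) stop("noiseSdPct must be >= 0")
  if (chlCarR2Target >= 1 || chlCarR2Target <= 0)
    stop("chlCarR2Target must be in (0, 1)")
  structure(as.list(environment()), class = "GeneratorConfig")
}

#' Leaf spectral model
#'
#' Reflectance is a NIR plateau minus pigment-scaled Gaussian absorption
#' features, attenuated by a logistic red-edge transition so the visible
#' range lies below the NIR: \code{R(l) = plateau - (1 - L(l)) * A(l)}
#' with \code{L} a logistic in wavelength centered on the red edge. The
#' red-edge center shifts with total chlorophyll (the classic red-edge
#' shift) and carries an independent structural jitter. Absorption
#' features (center nm, width nm, strength in percent reflectance per
#' ug/g): carotenoid at 465 and 535 nm; chlorophyll at 430 nm, a broad
#' green-range depression at 565 nm, a weak extract-position band at
#' 644 nm and the in-vivo red absorption at 678 nm. A pigment-independent
#' visible floor (backscatter) is a broad Gaussian at 550 nm.
#'
#' @param nirPlateauPct NIR plateau level, percent (default 50).
#' @param visibleFloor list(amplitude, center, width) of the non-pigment
#'   visible depression.
#' @param features data.frame(pigment, center, width, strength).
#' @param redEdgeCenterNm base red-edge center (default 700 nm).
#' @param redEdgeWidthNm logistic width (default 8 nm).
#' @param redEdgeShiftNmPerUgg red-edge shift per ug/g chlorophyll about
#'   \code{chlRefUgg}.
#' @param chlRefUgg reference chlorophyll for the shift (default 2200).
#' @param redEdgeJitterSdNm sd of the structural red-edge jitter (nm).
#' @return list of class \code{"SpectralModel"}.
#' @export
spectralModel <- function(nirPlateauPct = 50,
                          visibleFloor = list(amplitude = 8, center = 550,
                                              width = 150),
                          features = data.frame(
                            pigment = c("car", "car", "chl", "chl", "chl",
                                        "chl"),
                            center = c(465, 535, 430, 565, 644, 678),
                            width = c(32, 28, 28, 45, 16, 9),
                            strength = c(0.0045, 0.002, 0.0050, 0.0016,
                                         0.0005, 0.0130)),
                          redEdgeCenterNm = 700, redEdgeWidthNm = 8,
                          redEdgeShiftNmPerUgg = 0.012,
                          chlRefUgg = 2200, redEdgeJitterSdNm = 3) {
  if (any(features$width <= 0)) stop("feature widths must be positive")
  if (any(features$strength < 0)) stop("feature strengths must be >= 0")
  structure(as.list(environment()), class = "SpectralModel")
}

.gauss <- function(l, center, width) exp(-((l - center)^2) / (2 * width^2))

# Truncated-normal mean correction: underlying mean mu such that the
# truncated distribution has the requested mean.
.truncnormMu <- function(targetMean, sd, lo, hi) {
  f <- function(mu) {
    a <- (lo - mu) / sd; b <- (hi - mu) / sd
    Z <- pnorm(b) - pnorm(a)
    mu + sd * (dnorm(a) - dnorm(b)) / Z - targetMean
  }
  uniroot(f, c(targetMean - 4 * sd, targetMean + 4 * sd))$root
}

.truncnormSd <- function(mu, sd, lo, hi) {
  a <- (lo - mu) / sd; b <- (hi - mu) / sd
  Z <- pnorm(b) - pnorm(a)
  sd * sqrt(1 + (a * dnorm(a) - b * dnorm(b)) / Z -
              ((dnorm(a) - dnorm(b)) / Z)^2)
}

.rtruncnorm <- function(n, mu, sd, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    draw <- rnorm(max(2L * (n - length(out)), 16L), mu, sd)
    out <- c(out, draw[draw >= lo & draw <= hi])
  }
  out[seq_len(n)]
}

#' Sample pigment contents
#'
#' Carotenoid is drawn from a truncated normal whose underlying mean is
#' corrected so the truncated mean matches the configured target; total
#' chlorophyll couples linearly to carotenoid with noise scaled so the
#' realized squared correlation approaches \code{chlCarR2Target}.
#' Chlorophyll a and b split in the configured ratio.
#'
#' @param cfg a \code{"GeneratorConfig"}.
#' @param n number of samples (default \code{cfg$nSamples}).
#' @param meanShiftUgg shift of the carotenoid mean (used for year
#'   effects); the truncation range is unchanged.
#' @param seed RNG seed (default derived from \code{cfg$seed}).
#' @return data.frame(carotenoid_ugg, chlorophyll_ugg, chla_ugg,
#'   chlb_ugg); empty for \code{n = 0}.
#' @export
samplePigments <- function(cfg, n = cfg$nSamples, meanShiftUgg = 0,
                           seed = cfg$seed + 101L) {
  if (n == 0)
    return(data.frame(carotenoid_ugg = numeric(0),
                      chlorophyll_ugg = numeric(0),
                      chla_ugg = numeric(0), chlb_ugg = numeric(0)))
  set.seed(seed)
  lo <- cfg$carRangeUgg[1]; hi <- cfg$carRangeUgg[2]
  m <- cfg$carMeanSdUgg[1] + meanShiftUgg
  s <- cfg$carMeanSdUgg[2]
  mu <- .truncnormMu(m, s, lo, hi)
  car <- .rtruncnorm(n, mu, s, lo, hi)
  sdCar <- .truncnormSd(mu, s, lo, hi)
  sdEps <- cfg$chlPerCar * sdCar * sqrt(1 / cfg$chlCarR2Target - 1)
  chl <- cfg$chlBaseUgg + cfg$chlPerCar * car + rnorm(n, 0, sdEps)
  chl <- pmax(chl, 1)
  fa <- cfg$chlabRatio / (cfg$chlabRatio + 1)
  data.frame(carotenoid_ugg = car, chlorophyll_ugg = chl,
             chla_ugg = fa * chl, chlb_ugg = (1 - fa) * chl)
}

# Core renderer: returns wavelengths x samples matrix of pre-noise
# reflectance for pigment vectors car, chl and per-sample jitter.
.renderMatrix <- function(car, chl, model, wavelengths, jitterNm) {
  wl <- as.numeric(wavelengths)
  fl <- model$visibleFloor
  A <- matrix(fl$amplitude * .gauss(wl, fl$center, fl$width),
              length(wl), length(car))
  for (i in seq_len(nrow(model$features))) {
    ft <- model$features[i, ]
    pig <- if (ft$pigment == "car") car else chl
    A <- A + outer(ft$strength * .gauss(wl, ft$center, ft$width), pig)
  }
  ctr <- model$redEdgeCenterNm +
    model$redEdgeShiftNmPerUgg * (chl - model$chlRefUgg) + jitterNm
  L <- 1 / (1 + exp(-sweep(matrix(wl, length(wl), length(car)), 2, ctr) /
                      model$redEdgeWidthNm))
  model$nirPlateauPct - (1 - L) * A
}

#' Render one leaf reflectance spectrum
#'
#' @param carUgg carotenoid content, ug/g.
#' @param chlUgg total chlorophyll content, ug/g.
#' @param model a \code{"SpectralModel"}.
#' @param wavelengths grid in nm (default 1 nm from 400 to 1000).
#' @param noiseSdPct additive Gaussian noise sd in percent reflectance.
#' @param seed RNG seed for the noise (ignored at zero noise).
#' @param redEdgeJitterNm structural red-edge offset for this sample
#'   (default 0).
#' @return Numeric reflectance vector, clipped to [0.1, 99]. A model whose
#'   strengths drive the pre-clip median reflectance negative is an error.
#' @export
renderSpectrum <- function(carUgg, chlUgg, model = spectralModel(),
                           wavelengths = seq(400, 1000, by = 1),
                           noiseSdPct = 0.5, seed = NULL,
                           redEdgeJitterNm = 0) {
  pre <- .renderMatrix(carUgg, chlUgg, model, wavelengths,
                       redEdgeJitterNm)[, 1]
  if (median(pre) < 0)
    stop("pre-clip median reflectance negative; model strengths too large")
  if (noiseSdPct > 0) {
    if (!is.null(seed)) set.seed(seed)
    pre <- pre + rnorm(length(pre), 0, noiseSdPct)
  }
  pmin(pmax(pre, 0.1), 99)
}

#' Generate a synthetic study table
#'
#' Balanced assignment over years x stages x sites (remainder distributed
#' round-robin), per-year carotenoid mean offsets so year-grouped
#' validation is non-trivial, pigment-dependent spectra via
#' \code{\link{renderSpectrum}}'s model, and seeded noise. All randomness
#' flows from \code{cfg$seed} through named substreams (pigments, jitter,
#' noise), so runs are reproducible.
#'
#' @param cfg a \code{"GeneratorConfig"}.
#' @param model a \code{"SpectralModel"}.
#' @param wavelengths grid in nm (default 1 nm from 400 to 1000).
#' @return A \linkS4class{SpectraSet} with full study metadata.
#' @examples
#' s <- generateStudy(generatorConfig(nSamples = 45, seed = 7))
#' @export
generateStudy <- function(cfg = generatorConfig(),
                          model = spectralModel(),
                          wavelengths = seq(400, 1000, by = 1)) {
  n <- cfg$nSamples
  cells <- expand.grid(site = seq_len(cfg$nSites), stage = cfg$stages,
                       year = cfg$years, stringsAsFactors = FALSE)
  idx <- rep(seq_len(nrow(cells)), length.out = n)  # round-robin remainder
  assign <- cells[idx, ]
  ord <- order(assign$year, assign$stage, assign$site)
  assign <- assign[ord, ]
  # per-year pigments with mean offsets, distinct substream per year
  yrs <- sort(unique(assign$year))
  pig <- vector("list", length(yrs))
  for (j in seq_along(yrs)) {
    yr <- yrs[j]
    nY <- sum(assign$year == yr)
    off <- cfg$yearCarOffsetUgg[as.character(yr)]
    if (is.na(off)) off <- 0
    pig[[j]] <- samplePigments(cfg, nY, meanShiftUgg = off,
                               seed = cfg$seed + 101L + j)
  }
  pig <- do.call(rbind, pig)
  set.seed(cfg$seed + 202L)
  jitter <- rnorm(n, 0, model$redEdgeJitterSdNm)
  pre <- .renderMatrix(pig$carotenoid_ugg, pig$chlorophyll_ugg, model,
                       wavelengths, jitter)
  if (median(pre) < 0)
    stop("pre-clip median reflectance negative; model strengths too large")
  set.seed(cfg$seed + 303L)
  if (cfg$noiseSdPct > 0)
    pre <- pre + matrix(rnorm(length(pre), 0, cfg$noiseSdPct), nrow(pre))
  refl <- pmin(pmax(pre, 0.1), 99)
  meta <- data.frame(
    sample_id = sprintf("S%04d", seq_len(n)),
    carotenoid_ugg = pig$carotenoid_ugg,
    chlorophyll_ugg = pig$chlorophyll_ugg,
    year = assign$year,
    stage = assign$stage,
    site_id = paste0("site", assign$site),
    irrigated = assign$site != 1L,
    stringsAsFactors = FALSE)
  SpectraSet(refl, wavelengths, meta)
}
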