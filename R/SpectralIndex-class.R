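#' SpectralIndex: a named band-arithmetic formula
#'
#' Represents one vegetation index as a set of reflectance bands (center
#' wavelength plus optional averaging window) and an arithmetic formula
#' over them. Band labels are \code{R<center>} for point bands and
#' \code{R<lo>_<hi>} for window bands, e.g. \code{(1/R510_520 -
#' 1/R560_570) * R800}.
#'
#' @slot name index name, unique within a registry.
#' @slot family \code{"classical"} or \code{"CAR"}.
#' @slot bands data.frame with columns \code{label}, \code{wavelength_nm},
#'   \code{window_nm}.
#' @slot formula character expression over the band labels.
#' @slot denominators character vector of sub-expressions whose magnitude
#'   below 1e-12 flags the result as undefined (\code{NA}).
#' @export
setClass("SpectralIndex",
  representation(name = "character", family = "character",
                 bands = "data.frame", formula = "character",
                 denominators = "character"))

setValidity("SpectralIndex", function(object) {
  msg <- character(0)
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "name must be a single non-empty string")
  if (!object@family %in% c("classical", "CAR", "custom"))
    msg <- c(msg, "family must be 'classical', 'CAR' or 'custom'")
  need <- c("label", "wavelength_nm", "window_nm")
  if (!all(need %in% colnames(object@bands)))
    msg <- c(msg, "bands needs columns label, wavelength_nm, window_nm")
  else {
    vars <- all.vars(parse(text = object@formula)[[1]])
    bad <- setdiff(vars, object@bands$label)
    if (length(bad))
      msg <- c(msg, paste0("formula references unknown band(s): ",
                           paste(bad, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SpectralIndex
#'
#' @param name index name.
#' @param formula character formula over band labels (\code{R550} etc.).
#' @param bands data.frame(label, wavelength_nm, window_nm); if omitted,
#'   point bands are inferred from labels of the form \code{R<number>} and
#'   window bands from \code{R<lo>_<hi>}.
#' @param family \code{"classical"}, \code{"CAR"} or \code{"custom"}.
#' @param denominators character vector of denominator sub-expressions
#'   checked against zero before evaluation.
#' @return A \linkS4class{SpectralIndex}.
#' @export
SpectralIndex <- function(name, formula, bands = NULL,
                          family = "custom", denominators = character(0)) {
  if (is.null(bands)) {
    labs <- all.vars(parse(text = formula)[[1]])
    bands <- do.call(rbind, lapply(labs, function(l) {
      m <- regmatches(l, regexec("^R([0-9.]+)_([0-9.]+)$", l))[[1]]
      if (length(m) == 3) {
        lo <- as.numeric(m[2]); hi <- as.numeric(m[3])
        return(data.frame(label = l, wavelength_nm = (lo + hi) / 2,
                          window_nm = hi - lo))
      }
      m <- regmatches(l, regexec("^R([0-9.]+)$", l))[[1]]
      if (length(m) == 2)
        return(data.frame(label = l, wavelength_nm = as.numeric(m[2]),
                          window_nm = 0))
      stop("cannot infer band from label '", l, "'; supply bands=")
    }))
  }
  new("SpectralIndex", name = name, family = family, bands = bands,
      formula = formula, denominators = denominators)
}

setMethod("show", "SpectralIndex", function(object) {
  cat("SpectralIndex ", object@name, " [", object@family, "]: ",
      object@formula, "\n", sep = "")
})

#' Built-in index registry
#'
#' Returns the 17 built-in index definitions: the eight classical forms
#' (RARS, SIPI, PSSR, CRI550, CRI700, mCRI_G, mCRI_RE, PRI) and the nine
#' maize-specific CAR indices built from reflectance at 550, 678, 700 and
#' 800 nm:
#' \preformatted{
#'  CAR1 = R700/R678            CAR2 = R700/R800
#'  CAR3 = (R550+R700)/R678     CAR4 = (R550+R700)/R800
#'  CAR5 = R550/R678            CAR6 = R550/R800
#'  CAR7 = (R550+R700)/(R678+R800)
#'  CAR8 = R700/(R678+R800)     CAR9 = R550/(R678+R800)
#' }
#' The mCRI forms use 10 nm windows at 510-520 and 560-570 nm, a 20 nm
#' window at 690-710 nm, and an NIR anchor band (default 800 nm,
#' configurable).
#'
#' @param nirNm NIR anchor wavelength for the mCRI indices (default 800).
#' @return Named list of \linkS4class{SpectralIndex} objects, length 17.
#' @examples
#' reg <- builtinIndices()
#' names(reg)
#' @export
builtinIndices <- function(nirNm = 800) {
  nir <- paste0("R", format(nirNm, scientific = FALSE))
  idx <- list(
    SpectralIndex("RARS", "R760/R500", family = "classical",
                  denominators = "R500"),
    SpectralIndex("SIPI", "(R800 - R445)/(R800 - R680)",
                  family = "classical", denominators = "R800 - R680"),
    SpectralIndex("PSSR", "R800/R500", family = "classical",
                  denominators = "R500"),
    SpectralIndex("CRI550", "1/R510 - 1/R550", family = "classical",
                  denominators = c("R510", "R550")),
    SpectralIndex("CRI700", "1/R510 - 1/R700", family = "classical",
                  denominators = c("R510", "R700")),
    SpectralIndex("mCRI_G",
                  paste0("(1/R510_520 - 1/R560_570) * ", nir),
                  family = "classical",
                  denominators = c("R510_520", "R560_570")),
    SpectralIndex("mCRI_RE",
                  paste0("(1/R510_520 - 1/R690_710) * ", nir),
                  family = "classical",
                  denominators = c("R510_520", "R690_710")),
    SpectralIndex("PRI", "(R531 - R570)/(R531 + R570)",
                  family = "classical", denominators = "R531 + R570"),
    SpectralIndex("CAR1", "R700/R678", family = "CAR",
                  denominators = "R678"),
    SpectralIndex("CAR2", "R700/R800", family = "CAR",
                  denominators = "R800"),
    SpectralIndex("CAR3", "(R550 + R700)/R678", family = "CAR",
                  denominators = "R678"),
    SpectralIndex("CAR4", "(R550 + R700)/R800", family = "CAR",
                  denominators = "R800"),
    SpectralIndex("CAR5", "R550/R678", family = "CAR",
                  denominators = "R678"),
    SpectralIndex("CAR6", "R550/R800", family = "CAR",
                  denominators = "R800"),
    SpectralIndex("CAR7", "(R550 + R700)/(R678 + R800)", family = "CAR",
                  denominators = "R678 + R800"),
    SpectralIndex("CAR8", "R700/(R678 + R800)", family = "CAR",
                  denominators = "R678 + R800"),
    SpectralIndex("CAR9", "R550/(R678 + R800)", family = "CAR",
                  denominators = "R678 + R800"))
  names(idx) <- vapply(idx, function(d) d@name, character(1))
  idx
}

# Evaluate one definition against band values stored in an environment of
# vectors (one element per sample). Returns NA where any denominator has
# magnitude < 1e-12 or the result is non-finite.
.evalIndex <- function(definition, env) {
  n <- length(get(definition@bands$label[1], envir = env))
  undef <- rep(FALSE, n)
  for (d in definition@denominators) {
    v <- eval(parse(text = d)[[1]], envir = env)
    undef <- undef | !is.finite(v) | abs(v) < 1e-12
  }
  out <- eval(parse(text = definition@formula)[[1]], envir = env)
  out[undef | !is.finite(out)] <- NA_real_
  out
}

.bandEnv <- function(definition, wl, refl) {
  env <- new.env(parent = baseenv())
  for (i in seq_len(nrow(definition@bands))) {
    b <- definition@bands[i, ]
    assign(b$label, .bandLookup(wl, refl, b$wavelength_nm, b$window_nm),
           envir = env)
  }
  env
}

#' @rdname computeIndex
#' @export
setMethod("computeIndex", "SpectraSet", function(x, definition, ...) {
  env <- .bandEnv(definition, wavelengths(x), reflectance(x))
  out <- .evalIndex(definition, env)
  names(out) <- colData(x)$sample_id
  out
})

#' @rdname computeIndex
#' @param wavelengths numeric grid for the numeric-vector method.
#' @export
setMethod("computeIndex", "numeric",
  function(x, definition, ..., wavelengths) {
    env <- .bandEnv(definition, as.numeric(wavelengths), as.numeric(x))
    unname(.evalIndex(definition, env))
  })

#' Compute an index table
#'
#' Evaluates several indices for every sample. Undefined values propagate
#' as \code{NA} (never silent zeros); per-index counts of undefined values
#' are reported via \code{message}.
#'
#' @param x a \linkS4class{SpectraSet} with at least one sample.
#' @param names character vector of index names (default: all built-ins),
#'   or a named list of \linkS4class{SpectralIndex} objects.
#' @param registry registry to resolve names in (default
#'   \code{\link{builtinIndices}()}).
#' @return data.frame with \code{sample_id} followed by one numeric column
#'   per index.
#' @export
computeIndexTable <- function(x, names = NULL,
                              registry = builtinIndices()) {
  if (ncol(x) == 0L) stop("empty SpectraSet")
  defs <- if (is.list(names) && length(names) &&
              methods::is(names[[1]], "SpectralIndex")) {
    names
  } else {
    if (is.null(names)) names <- base::names(registry)
    bad <- setdiff(names, base::names(registry))
    if (length(bad))
      stop("unknown index name(s): ", paste(bad, collapse = ", "))
    registry[names]
  }
  out <- data.frame(sample_id = colData(x)$sample_id,
                    stringsAsFactors = FALSE)
  for (d in defs) {
    v <- computeIndex(x, d)
    nUndef <- sum(is.na(v))
    if (nUndef > 0)
      message("index ", d@name, ": ", nUndef, " undefined value(s)")
    out[[d@name]] <- unname(v)
  }
  out
}

#' Export an index registry to a plain-text definition file
#'
#' Tab-separated file with columns name, family, formula, bands (encoded
#' \code{label:wavelength:window} separated by \code{;}) and denominators
#' (separated by \code{|}). Readable back with
#' \code{\link{importIndexRegistry}}.
#'
#' @param registry named list of \linkS4class{SpectralIndex}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
exportIndexRegistry <- function(registry, path) {
  rows <- lapply(registry, function(d) {
    data.frame(
      name = d@name, family = d@family, formula = d@formula,
      bands = paste(sprintf("%s:%g:%g", d@bands$label,
                            d@bands$wavelength_nm, d@bands$window_nm),
                    collapse = ";"),
      denominators = paste(d@denominators, collapse = "|"))
  })
  data.table::fwrite(do.call(rbind, rows), path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Import an index registry from a plain-text definition file
#'
#' @param path file written by \code{\link{exportIndexRegistry}} (or edited
#'   by hand in the same format).
#' @return Named list of \linkS4class{SpectralIndex}.
#' @export
importIndexRegistry <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE, colClasses = "character")
  out <- lapply(seq_len(nrow(dt)), function(i) {
    parts <- strsplit(strsplit(dt$bands[i], ";")[[1]], ":")
    bands <- do.call(rbind, lapply(parts, function(p)
      data.frame(label = p[1], wavelength_nm = as.numeric(p[2]),
                 window_nm = as.numeric(p[3]))))
    den <- dt$denominators[i]
    den <- if (is.na(den) || !nzchar(den)) character(0)
           else strsplit(den, "|", fixed = TRUE)[[1]]
    SpectralIndex(dt$name[i], dt$formula[i], bands = bands,
                  family = dt$family[i], denominators = den)
  })
  names(out) <- dt$name
  out
}
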