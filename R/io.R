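# Delimited-text I/O for sample tables. Wide layout: one row per sample,
# metadata columns followed by one column per wavelength (named "wl_<nm>"
# or a bare number). Long layout: (sample_id, wavelength, reflectance)
# triples plus a separate metadata table.

.metaCols <- c("sample_id", "carotenoid_ugg", "chlorophyll_ugg", "year",
               "stage", "site_id", "irrigated")

.parseWavelengthCols <- function(nms) {
  m <- regmatches(nms, regexec("^(?:wl_?|X)?([0-9]+(?:\\.[0-9]+)?)$", nms))
  wl <- vapply(m, function(x) if (length(x) == 2) as.numeric(x[2])
               else NA_real_, numeric(1))
  wl
}

#' Read a sample table from delimited text
#'
#' The delimiter is auto-detected among comma, semicolon and tab; the first
#' row is the header; the decimal separator is \code{"."}. Rows with
#' non-numeric reflectance are rejected with a warning naming their ids.
#' A missing \code{carotenoid_ugg} column or (long layout) inconsistent
#' wavelength grids across samples are hard errors.
#'
#' @param path file path (wide layout), or the triples file (long layout).
#' @param layout \code{"wide"} or \code{"long"}.
#' @param metadataPath for \code{layout = "long"}, path of the metadata
#'   table (sample_id plus metadata columns).
#' @return A \linkS4class{SpectraSet} on a single shared grid.
#' @export
readSampleTable <- function(path, layout = c("wide", "long"),
                            metadataPath = NULL) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("input file not found: ", path)
  dt <- data.table::fread(path, sep = "auto", header = TRUE,
                          data.table = FALSE, check.names = FALSE)
  if (layout == "wide") {
    wl <- .parseWavelengthCols(names(dt))
    specCols <- which(!is.na(wl))
    if (!length(specCols)) stop("no wavelength columns found")
    if (!"carotenoid_ugg" %in% names(dt))
      stop("missing required column 'carotenoid_ugg'")
    if (!"sample_id" %in% names(dt))
      stop("missing required column 'sample_id'")
    ord <- order(wl[specCols])
    specCols <- specCols[ord]
    refl <- suppressWarnings(
      vapply(specCols, function(j) as.numeric(dt[[j]]),
             numeric(nrow(dt))))
    refl <- matrix(refl, nrow = nrow(dt))
    bad <- apply(refl, 1, function(r) any(!is.finite(r)))
    if (any(bad)) {
      warning("rejected ", sum(bad), " row(s) with non-numeric ",
              "reflectance: ",
              paste(head(dt$sample_id[bad], 10), collapse = ", "))
      dt <- dt[!bad, , drop = FALSE]
      refl <- refl[!bad, , drop = FALSE]
    }
    meta <- dt[, intersect(.metaCols, names(dt)), drop = FALSE]
    meta$carotenoid_ugg <- as.numeric(meta$carotenoid_ugg)
    return(SpectraSet(t(refl), wl[specCols], meta))
  }
  # long layout
  need <- c("sample_id", "wavelength", "reflectance")
  if (!all(need %in% names(dt)))
    stop("long layout needs columns: ", paste(need, collapse = ", "))
  if (is.null(metadataPath))
    stop("layout='long' requires metadataPath")
  meta <- data.table::fread(metadataPath, sep = "auto", header = TRUE,
                            data.table = FALSE, check.names = FALSE)
  if (!"carotenoid_ugg" %in% names(meta))
    stop("missing required column 'carotenoid_ugg'")
  ids <- unique(dt$sample_id)
  byId <- split(dt, factor(dt$sample_id, levels = ids))
  gridRef <- sort(byId[[1]]$wavelength)
  refl <- matrix(NA_real_, length(gridRef), length(ids))
  for (i in seq_along(ids)) {
    sub <- byId[[i]]
    o <- order(sub$wavelength)
    if (!isTRUE(all.equal(sub$wavelength[o], gridRef)))
      stop("sample '", ids[i], "' has an inconsistent wavelength grid")
    v <- suppressWarnings(as.numeric(sub$reflectance[o]))
    refl[, i] <- v
  }
  bad <- apply(refl, 2, function(r) any(!is.finite(r)))
  if (any(bad)) {
    warning("rejected ", sum(bad), " sample(s) with non-numeric ",
            "reflectance: ", paste(head(ids[bad], 10), collapse = ", "))
    refl <- refl[, !bad, drop = FALSE]
    ids <- ids[!bad]
  }
  meta <- meta[match(ids, meta$sample_id), , drop = FALSE]
  if (any(is.na(meta$sample_id)))
    stop("metadata table missing sample id(s): ",
         paste(head(ids[is.na(meta$sample_id)], 5), collapse = ", "))
  SpectraSet(refl, gridRef, meta)
}

#' Write a sample table as delimited text
#'
#' Wide layout with wavelength columns named \code{wl_<nm>}. Numeric values
#' are written with 17 significant digits so a write/read round trip is
#' bit-exact for finite doubles.
#'
#' @param x a \linkS4class{SpectraSet}.
#' @param path output path.
#' @param sep field delimiter (default comma).
#' @return \code{path}, invisibly.
#' @export
writeSampleTable <- function(x, path, sep = ",") {
  meta <- as.data.frame(colData(x))
  refl <- t(reflectance(x))
  wl <- wavelengths(x)
  fmt <- function(v) {
    if (is.double(v)) sub("^\\s+", "", sprintf("%.17g", v)) else v
  }
  out <- as.data.frame(lapply(meta, fmt), stringsAsFactors = FALSE,
                       check.names = FALSE)
  for (j in seq_along(wl))
    out[[paste0("wl_", format(wl[j], scientific = FALSE))]] <-
      fmt(refl[, j])
  data.table::fwrite(out, path, sep = sep, quote = FALSE)
  invisible(path)
}
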