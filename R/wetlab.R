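# Spectrophotometric pigment arithmetic for 80% acetone extracts read at
# 470, 644 and 663 nm, plus the exact algebraic inverse used by the
# synthetic generator for round-trip testing.

#' Chlorophyll a concentration from extract absorbance
#'
#' \code{12.21 * A663 - 2.81 * A644}, in ug/ml of extract.
#'
#' @param A663,A644 absorbance (dimensionless), finite.
#' @return Chlorophyll a in ug/ml. Negative values (nonphysical absorbance
#'   combinations) are returned with a warning, not clamped.
#' @export
chlorophyllA <- function(A663, A644) {
  out <- 12.21 * A663 - 2.81 * A644
  if (any(out < 0, na.rm = TRUE))
    warning("negative chlorophyll a value(s); check absorbance inputs")
  out
}

#' Chlorophyll b concentration from extract absorbance
#'
#' \code{20.13 * A644 - 5.03 * A663}, in ug/ml of extract.
#'
#' @param A644,A663 absorbance (dimensionless), finite.
#' @return Chlorophyll b in ug/ml; negative values warned, not clamped.
#' @export
chlorophyllB <- function(A644, A663) {
  out <- 20.13 * A644 - 5.03 * A663
  if (any(out < 0, na.rm = TRUE))
    warning("negative chlorophyll b value(s); check absorbance inputs")
  out
}

#' Carotenoid content from extract absorbance
#'
#' Computes \code{(1000*A470 - 3.27*chla - 104*chlb) / 229} and scales by
#' the extract geometry \code{V/w} (V = extract volume in ml, w = fresh
#' tissue weight in g). Two scalings are exposed because the source
#' formula's trailing \code{/(V/w)} divides by the volume-to-weight ratio
#' where conventional fresh-weight scaling multiplies by it:
#' \code{"as_printed"} (default) divides, \code{"volume_multiplied"}
#' multiplies. With \code{V == w} both agree.
#'
#' @param A470,A644,A663 absorbance values (dimensionless).
#' @param V extract volume in ml (> 0).
#' @param w fresh tissue weight in g (> 0).
#' @param scaling \code{"as_printed"} or \code{"volume_multiplied"}.
#' @return Carotenoid content in ug/g fresh weight. Negative values are
#'   warned about and returned, since they diagnose nonphysical inputs.
#' @examples
#' carotenoidContent(1, 0, 0, V = 1, w = 1)  # 1000/229
#' @export
carotenoidContent <- function(A470, A644, A663, V = 1, w = 1,
                              scaling = c("as_printed", "volume_multiplied")) {
  scaling <- match.arg(scaling)
  if (any(V <= 0) || any(w <= 0)) stop("V and w must be positive")
  chla <- 12.21 * A663 - 2.81 * A644
  chlb <- 20.13 * A644 - 5.03 * A663
  core <- (1000 * A470 - 3.27 * chla - 104 * chlb) / 229
  out <- if (scaling == "as_printed") core / (V / w) else core * (V / w)
  if (any(out < 0, na.rm = TRUE))
    warning("negative carotenoid value(s); check absorbance inputs")
  out
}

#' Absorbance triple reproducing given pigment values
#'
#' Exact algebraic inverse of \code{\link{carotenoidContent}},
#' \code{\link{chlorophyllA}} and \code{\link{chlorophyllB}}: solves the
#' 2x2 linear system for (A663, A644) from the chlorophyll pair, then A470
#' from the carotenoid equation under the chosen scaling.
#'
#' @param carUgg carotenoid content, ug/g fresh weight.
#' @param chla,chlb chlorophyll a and b, ug/ml of extract, >= 0.
#' @param V,w extract geometry as in \code{\link{carotenoidContent}}.
#' @param scaling as in \code{\link{carotenoidContent}}.
#' @return data.frame with columns A470, A644, A663. Inputs implying a
#'   negative absorbance raise an error naming the offending value.
#' @export
pigmentsToAbsorbance <- function(carUgg, chla, chlb, V = 1, w = 1,
                                 scaling = c("as_printed",
                                             "volume_multiplied")) {
  scaling <- match.arg(scaling)
  if (any(V <= 0) || any(w <= 0)) stop("V and w must be positive")
  det <- 12.21 * 20.13 - 2.81 * 5.03
  A663 <- (20.13 * chla + 2.81 * chlb) / det
  A644 <- (5.03 * chla + 12.21 * chlb) / det
  core <- if (scaling == "as_printed") carUgg * (V / w) else carUgg / (V / w)
  A470 <- (229 * core + 3.27 * chla + 104 * chlb) / 1000
  for (nm in c("A470", "A644", "A663")) {
    v <- get(nm)
    if (any(v < -1e-12, na.rm = TRUE))
      stop("pigment values imply negative ", nm, " (", min(v), ")")
  }
  data.frame(A470 = pmax(A470, 0), A644 = pmax(A644, 0),
             A663 = pmax(A663, 0))
}

#' Read an absorbance table
#'
#' Delimited text with columns sample_id, A470, A644, A663, V, w
#' (delimiter auto-detected among comma, semicolon and tab).
#'
#' @param path file path.
#' @return data.frame with the six columns, numerics coerced.
#' @export
readAbsorbanceTable <- function(path) {
  dt <- data.table::fread(path, sep = "auto", header = TRUE,
                          data.table = FALSE)
  need <- c("sample_id", "A470", "A644", "A663", "V", "w")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop("absorbance table missing column(s): ", paste(miss, collapse = ", "))
  for (cl in setdiff(need, "sample_id")) dt[[cl]] <- as.numeric(dt[[cl]])
  dt[, need]
}
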