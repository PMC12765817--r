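#' @include methods.R
NULL

# Remapped 1-digit class legend. IGBP forest subclasses keep their codes 1-5;
# the remaining IGBP classes are aggregated so every code fits one digit and
# the two-digit change code stays collision-free.
remapLegend <- data.frame(
  code = 1:9,
  name = c("ENF", "EBF", "DNF", "DBF", "MF",
           "shrub/grass", "cropland", "built", "other/water"),
  stringsAsFactors = FALSE
)
forestCodes <- 1:5

#' Remap IGBP class codes to the 1-digit change-coding domain
#'
#' Forest subclasses (IGBP 1-5: ENF, EBF, DNF, DBF, MF) are kept; shrub,
#' savanna and grassland (6-10) map to 6; cropland and mosaics (12, 14) to 7;
#' built (13) to 8; everything else (wetland 11, snow 15, barren 16,
#' water 17) to 9. This keeps the two-digit code \eqn{C = 10A + B} uniquely
#' decodable.
#'
#' @param x integer vector/matrix/array of IGBP codes (1-17).
#' @return Same shape, codes in 1..9.
#' @export
remapIgbp <- function(x) {
  lut <- c(1, 2, 3, 4, 5, 6, 6, 6, 6, 6, 9, 7, 8, 7, 9, 9, 9)
  bad <- !is.na(x) & (x < 1 | x > 17 | x != floor(x))
  if (any(bad)) stop("IGBP codes must be integers in 1..17")
  out <- x
  out[!is.na(x)] <- lut[x[!is.na(x)]]
  out
}

#' Two-digit land-use change (tupu) code
#'
#' Encodes a beginning/end class pair as \eqn{C = 10A + B}; the factor 10
#' guarantees a unique, directly readable code as long as both classes are
#' single-digit, which is why inputs must already be remapped to 1..9
#' (\code{\link{remapIgbp}}). E.g. \code{encodeChange(1, 2) == 12}: evergreen
#' needleleaf forest converted to evergreen broadleaf forest.
#'
#' @param a beginning class code(s) in 1..9.
#' @param b ending class code(s) in 1..9.
#' @return Integer code(s) \code{10 * a + b}.
#' @examples
#' encodeChange(1, 2)            # 12, ENF -> EBF
#' decodeChange(encodeChange(5, 5))
#' @export
encodeChange <- function(a, b) {
  if (any(is.na(a)) || any(is.na(b))) stop("class codes must not be NA")
  if (any(a != floor(a)) || any(b != floor(b)) ||
      any(a < 1 | a > 9) || any(b < 1 | b > 9)) {
    stop("class codes must be integers in 1..9 (remap first); the factor-10 ",
         "code is ambiguous outside that range")
  }
  as.integer(10 * a + b)
}

#' @rdname encodeChange
#' @param C two-digit code(s) produced by \code{encodeChange}.
#' @export
decodeChange <- function(C) {
  C <- as.integer(C)
  if (any(C < 11 | C > 99, na.rm = TRUE)) stop("codes must lie in 11..99")
  list(from = C %/% 10L, to = C %% 10L)
}

#' Classify stable vs changing forest from an annual land-cover cube
#'
#' A pixel is stable forest (SF) when it holds one identical forest subclass
#' (remapped codes 1-5) in every year of the period; it is changing forest
#' (CF) when it is forest in at least one year and either shifts between
#' forest subclasses or transitions between forest and non-forest.
#' Never-forest pixels stay unlabeled. The per-pixel change code is built
#' from the first and last year via \code{\link{encodeChange}} (the period
#' endpoints are what the two-digit overlay encodes); with
#' \code{endpointOnly = TRUE} the SF/CF decision too uses only the endpoints
#' rather than the full sequence.
#'
#' @param landcover categorical \linkS4class{AnnualCube} of IGBP codes
#'   (1-17; remapped internally) covering the full study period.
#' @param endpointOnly classify from first/last year only (default FALSE:
#'   the full sequence decides, so a transient one-year excursion counts as
#'   change).
#' @return A \linkS4class{ChangeMap}.
#' @export
classifyForestDynamics <- function(landcover, endpointOnly = FALSE) {
  d <- dim(landcover)
  if (d[3] < 2L) stop("need at least two years of land cover")
  arr <- remapIgbp(gridValues(landcover))
  flat <- matrix(arr, d[1] * d[2], d[3])
  isF <- !is.na(flat) & flat <= max(forestCodes)
  everForest <- rowSums(isF) > 0L
  complete <- rowSums(is.na(flat)) == 0L
  if (endpointOnly) {
    same <- flat[, 1] == flat[, d[3]]
    sf <- complete & isF[, 1] & isF[, d[3]] & same
  } else {
    allSameForest <- isF[, 1] &
      rowSums(flat == flat[, 1]) == d[3]  # NA-safe: complete required below
    allSameForest[is.na(allSameForest)] <- FALSE
    sf <- complete & rowSums(isF) == d[3] & allSameForest
  }
  cf <- complete & everForest & !sf
  code <- rep(NA_integer_, nrow(flat))
  lab <- sf | cf
  code[lab] <- encodeChange(flat[lab, 1], flat[lab, d[3]])
  codes <- sort(unique(code[!is.na(code)]))
  dec <- decodeChange(codes)
  legend <- data.frame(
    code = codes,
    from = remapLegend$name[dec$from],
    to = remapLegend$name[dec$to],
    stringsAsFactors = FALSE
  )
  new("ChangeMap",
      code = matrix(code, d[1], d[2]),
      sfMask = matrix(sf, d[1], d[2]),
      cfMask = matrix(cf, d[1], d[2]),
      legend = legend,
      transform = gridTransform(landcover),
      crs = gridCrs(landcover))
}

#' Summarise a ChangeMap by subregion
#'
#' SF/CF pixel counts, areas and proportions (over labeled pixels) plus
#' change-code frequencies, overall and per subregion.
#'
#' @param cm a \linkS4class{ChangeMap}.
#' @param subregions optional \linkS4class{RasterGrid} or matrix of
#'   subregion labels, geometry-aligned with the map.
#' @param pixelArea area of one pixel (e.g. km2).
#' @return List of two data.frames: \code{dynamics} (SF/CF shares) and
#'   \code{codes} (code frequencies).
#' @export
changeSummary <- function(cm, subregions = NULL, pixelArea = 1) {
  if (is(subregions, "RasterGrid")) {
    if (!identical(dim(gridValues(subregions)), dim(changeCode(cm)))) {
      stop("subregion grid is not aligned with the change map")
    }
    subregions <- gridValues(subregions)
  }
  lab <- ifelse(sfMask(cm), "SF", ifelse(cfMask(cm), "CF", NA_character_))
  dim(lab) <- dim(changeCode(cm))
  dynamics <- areaProportions(lab, subregions = subregions,
                              pixelArea = pixelArea)
  codes <- areaProportions(changeCode(cm), subregions = subregions,
                           pixelArea = pixelArea)
  names(codes)[names(codes) == "class"] <- "code"
  list(dynamics = dynamics, codes = codes)
}
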