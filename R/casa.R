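#' @include methods.R
NULL

FPAR_MAX <- 0.95
FPAR_MIN <- 0.001
PAR_FRACTION <- 0.5
TE2_MAX <- 1.184
daysInMonth <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)

#' Light-use-efficiency parameter table
#'
#' Per-class NDVImin/NDVImax and maximal light-use efficiency
#' \eqn{\varepsilon^*} (gC/MJ) on the remapped 1-digit class domain
#' (\code{\link{remapIgbp}}). The shipped defaults follow the standard
#' regional parameterization for Chinese vegetation types and are meant to
#' be edited: pass your own CSV with columns \code{class_code},
#' \code{NDVImin}, \code{NDVImax}, \code{epsilon_star}.
#'
#' @param path optional CSV path; default: the table shipped with the
#'   package.
#' @return data.frame with one row per class code.
#' @export
casaParams <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "casa_params.csv", package = "forestNPP")
  }
  p <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("class_code", "NDVImin", "NDVImax", "epsilon_star")
  if (!all(need %in% names(p))) {
    stop("parameter table must have columns ", paste(need, collapse = ", "))
  }
  if (any(p$NDVImin >= p$NDVImax)) stop("NDVImin must be < NDVImax")
  if (any(p$epsilon_star <= 0)) stop("epsilon_star must be > 0")
  p
}

# per-layer lookup of a class-indexed parameter
classLookup <- function(classGrid, params, column) {
  lut <- rep(NA_real_, max(params$class_code))
  lut[params$class_code] <- params[[column]]
  out <- lut[classGrid]
  if (any(is.na(out) & !is.na(classGrid))) {
    missing <- sort(unique(classGrid[is.na(out) & !is.na(classGrid)]))
    stop("no CASA parameters for class code(s): ",
         paste(missing, collapse = ", "))
  }
  dim(out) <- dim(classGrid)
  out
}

#' FPAR from NDVI
#'
#' Fraction of photosynthetically active radiation absorbed by the canopy,
#' taken as the mean of two estimates, each linear between its class-specific
#' bounds and clipped to [0.001, 0.95]: the NDVI estimate
#' \eqn{(NDVI - NDVI_{min})/(NDVI_{max} - NDVI_{min})} and the simple-ratio
#' estimate with \eqn{SR = (1 + NDVI)/(1 - NDVI)} scaled between the class
#' SRmin/SRmax (the transforms of NDVImin/NDVImax).
#'
#' @param ndvi \linkS4class{MonthlyCube} of NDVI in [-1, 1].
#' @param landcover categorical \linkS4class{AnnualCube} of IGBP classes
#'   (remapped internally); the class of each pixel-year selects the bounds.
#' @param params parameter table from \code{\link{casaParams}}.
#' @return \linkS4class{MonthlyCube} of FPAR.
#' @export
computeFpar <- function(ndvi, landcover, params = casaParams()) {
  stopIfMisaligned(ndvi, landcover, what = "NDVI and land cover")
  vals <- gridValues(ndvi)
  if (any(vals < -1 | vals > 1, na.rm = TRUE)) {
    stop("NDVI outside [-1, 1]")
  }
  lc <- remapIgbp(gridValues(landcover))
  years <- cubeYears(ndvi)
  out <- array(NA_real_, dim(vals))
  for (k in seq_along(years)) {
    yi <- match(years[k], cubeYears(landcover))
    if (is.na(yi)) stop("land cover missing year ", years[k])
    cls <- lc[, , yi]
    nmin <- classLookup(cls, params, "NDVImin")
    nmax <- classLookup(cls, params, "NDVImax")
    v <- vals[, , k]
    fNdvi <- (v - nmin) / (nmax - nmin) * (FPAR_MAX - FPAR_MIN) + FPAR_MIN
    sr <- (1 + v) / (1 - v)
    srmin <- (1 + nmin) / (1 - nmin)
    srmax <- (1 + nmax) / (1 - nmax)
    fSr <- (sr - srmin) / (srmax - srmin) * (FPAR_MAX - FPAR_MIN) + FPAR_MIN
    f <- (fNdvi + fSr) / 2
    out[, , k] <- pmin(pmax(f, FPAR_MIN), FPAR_MAX)
  }
  monthlyCube(out, cubeYears(ndvi), cubeMonths(ndvi),
              transform = gridTransform(ndvi), crs = gridCrs(ndvi))
}

#' APAR from FPAR and shortwave radiation
#'
#' \eqn{APAR = SOL \times FPAR \times 0.5}, where SOL (MJ m-2 month-1) is the
#' monthly total shortwave converted from the mean flux density (W m-2) by
#' \eqn{\times 86400 \times \mathrm{days} \times 10^{-6}}, and 0.5 is the
#' photosynthetically active fraction of total solar radiation. Calendar
#' month lengths, no leap-day refinement.
#'
#' @param fpar \linkS4class{MonthlyCube} from \code{\link{computeFpar}}.
#' @param srad \linkS4class{MonthlyCube} of mean shortwave flux (W m-2).
#' @return \linkS4class{MonthlyCube} of APAR (MJ m-2 month-1).
#' @export
computeApar <- function(fpar, srad) {
  stopIfMisaligned(fpar, srad, what = "FPAR and srad")
  sv <- gridValues(srad)
  if (any(sv < 0, na.rm = TRUE)) stop("negative solar radiation")
  days <- daysInMonth[cubeMonths(srad)]
  sol <- sweep(sv, 3, 86400 * days * 1e-6, "*")
  monthlyCube(sol * gridValues(fpar) * PAR_FRACTION,
              cubeYears(fpar), cubeMonths(fpar),
              transform = gridTransform(fpar), crs = gridCrs(fpar))
}

#' Temperature stress scalars
#'
#' The optimal temperature \eqn{T_{opt}} of each pixel-year is the mean
#' temperature of the month with maximal NDVI. Then
#' \eqn{T_{\varepsilon1} = 0.8 + 0.02 T_{opt} - 0.0005 T_{opt}^2}
#' (clipped to [0, 1]) penalizes extreme growing-season temperatures, and
#' \deqn{T_{\varepsilon2} = \frac{1.184}{1 + e^{0.2 (T_{opt} - 10 - T)}}
#'   \cdot \frac{1}{1 + e^{0.3 (-T_{opt} - 10 + T)}}}
#' (clipped to [0, 1.184]) penalizes months departing from it.
#'
#' @param tem \linkS4class{MonthlyCube} of mean temperature (deg C).
#' @param ndvi \linkS4class{MonthlyCube} of NDVI (picks the peak month).
#' @return List: \code{te1}, \code{te2} (MonthlyCubes), \code{topt}
#'   (\linkS4class{AnnualCube}).
#' @export
temperatureStress <- function(tem, ndvi) {
  stopIfMisaligned(tem, ndvi, what = "temperature and NDVI")
  tv <- gridValues(tem); nv <- gridValues(ndvi)
  years <- sort(unique(cubeYears(tem)))
  d <- dim(tv)
  topt <- array(NA_real_, c(d[1], d[2], length(years)))
  te1 <- array(NA_real_, d)
  te2 <- array(NA_real_, d)
  for (k in seq_along(years)) {
    sel <- which(cubeYears(tem) == years[k])
    nY <- nv[, , sel, drop = FALSE]
    tY <- tv[, , sel, drop = FALSE]
    # month index of the NDVI maximum, per pixel
    best <- apply(nY, c(1, 2), function(v) {
      if (all(is.na(v))) NA_integer_ else which.max(v)
    })
    ij <- which(!is.na(best))
    toptY <- matrix(NA_real_, d[1], d[2])
    rc <- arrayInd(ij, c(d[1], d[2]))
    toptY[ij] <- tY[cbind(rc, best[ij])]
    topt[, , k] <- toptY
    t1 <- 0.8 + 0.02 * toptY - 0.0005 * toptY^2
    t1 <- pmin(pmax(t1, 0), 1)
    for (m in sel) {
      te1[, , m] <- t1
      tm <- tv[, , m]
      t2 <- TE2_MAX / (1 + exp(0.2 * (toptY - 10 - tm))) /
        (1 + exp(0.3 * (-toptY - 10 + tm)))
      te2[, , m] <- pmin(pmax(t2, 0), TE2_MAX)
    }
  }
  tr <- gridTransform(tem); crs <- gridCrs(tem)
  list(
    te1 = monthlyCube(te1, cubeYears(tem), cubeMonths(tem), tr, crs),
    te2 = monthlyCube(te2, cubeYears(tem), cubeMonths(tem), tr, crs),
    topt = annualCube(topt, years, tr, crs)
  )
}

#' Thornthwaite potential evapotranspiration
#'
#' Monthly PET (mm) from monthly mean temperature: heat index
#' \eqn{I = \sum (T/5)^{1.514}} over the year's months with \eqn{T > 0},
#' exponent \eqn{a = 6.75\times10^{-7} I^3 - 7.71\times10^{-5} I^2 +
#' 1.792\times10^{-2} I + 0.49239}, and
#' \eqn{PET = 16 (10 T / I)^a} for \eqn{T > 0}, else 0. No day-length
#' correction at this scale.
#'
#' @param tem \linkS4class{MonthlyCube} of temperature (deg C).
#' @return \linkS4class{MonthlyCube} of PET (mm/month).
#' @export
thornthwaitePet <- function(tem) {
  tv <- gridValues(tem)
  years <- sort(unique(cubeYears(tem)))
  pet <- array(0, dim(tv))
  for (k in seq_along(years)) {
    sel <- which(cubeYears(tem) == years[k])
    tY <- tv[, , sel, drop = FALSE]
    hi <- pmax(tY, 0) / 5
    I <- apply(hi^1.514, c(1, 2), sum)
    a <- 6.75e-7 * I^3 - 7.71e-5 * I^2 + 1.792e-2 * I + 0.49239
    for (j in seq_along(sel)) {
      tm <- tY[, , j]
      p <- ifelse(tm > 0 & I > 0, 16 * (10 * tm / I)^a, 0)
      p[is.na(tm)] <- NA_real_
      pet[, , sel[j]] <- p
    }
  }
  monthlyCube(pet, cubeYears(tem), cubeMonths(tem),
              transform = gridTransform(tem), crs = gridCrs(tem))
}

# Estimated (actual) evapotranspiration from the coupled
# precipitation-net-radiation closed form, with net radiation approximated
# from PET and precipitation:
#   Rn  = sqrt(PET * P) * (0.369 + 0.598 * sqrt(PET / P))
#   EET = P * Rn * (P^2 + Rn^2 + P * Rn) / ((P + Rn) * (P^2 + Rn^2))
# capped at PET; zero when P = 0 or PET = 0.
actualEvapotranspiration <- function(pre, pet) {
  ok <- !is.na(pre) & !is.na(pet) & pre > 0 & pet > 0
  eet <- numeric(length(pre))
  p <- pre[ok]; q <- pet[ok]
  rn <- sqrt(q * p) * (0.369 + 0.598 * sqrt(q / p))
  e <- p * rn * (p^2 + rn^2 + p * rn) / ((p + rn) * (p^2 + rn^2))
  eet[ok] <- pmin(e, q)
  eet[is.na(pre) | is.na(pet)] <- NA_real_
  dim(eet) <- dim(pre)
  eet
}

#' Moisture stress scalar
#'
#' \eqn{W_\varepsilon = 0.5 + 0.5\, EET/PET}, clipped to [0.5, 1], with PET
#' by \code{\link{thornthwaitePet}} and EET by a coupled
#' precipitation-radiation estimate (see
#' \code{forestNPP:::actualEvapotranspiration}). Months with PET = 0
#' (freezing) fall back to \eqn{W_\varepsilon = 0.5}.
#'
#' @param pre \linkS4class{MonthlyCube} of precipitation (mm/month).
#' @param tem \linkS4class{MonthlyCube} of temperature (deg C).
#' @return \linkS4class{MonthlyCube} of the moisture scalar in [0.5, 1].
#' @export
waterStress <- function(pre, tem) {
  stopIfMisaligned(pre, tem, what = "precipitation and temperature")
  pv <- gridValues(pre)
  if (any(pv < 0, na.rm = TRUE)) stop("negative precipitation")
  pet <- gridValues(thornthwaitePet(tem))
  eet <- actualEvapotranspiration(pv, pet)
  we <- ifelse(pet > 0, 0.5 + 0.5 * eet / pet, 0.5)
  we <- pmin(pmax(we, 0.5), 1)
  we[is.na(pv) | is.na(pet)] <- NA_real_
  monthlyCube(we, cubeYears(pre), cubeMonths(pre),
              transform = gridTransform(pre), crs = gridCrs(pre))
}

#' Monthly and annual NPP from APAR and the stress scalars
#'
#' \eqn{NPP = APAR \times \varepsilon}, with the actual light-use efficiency
#' \eqn{\varepsilon = T_{\varepsilon1} T_{\varepsilon2} W_\varepsilon
#' \varepsilon^*(class)}. Annual NPP is the calendar-year sum of the 12
#' monthly grids.
#'
#' @param apar \linkS4class{MonthlyCube} from \code{\link{computeApar}}.
#' @param stress list from \code{\link{temperatureStress}} (\code{te1},
#'   \code{te2}) plus the \code{we} cube from \code{\link{waterStress}}.
#' @param params table from \code{\link{casaParams}}.
#' @param landcover categorical \linkS4class{AnnualCube} of IGBP classes.
#' @return List: \code{monthly} (\linkS4class{MonthlyCube}, gC m-2 month-1),
#'   \code{annual} (\linkS4class{AnnualCube}, gC m-2 a-1), \code{apar}.
#' @export
computeNpp <- function(apar, stress, params = casaParams(), landcover) {
  stopIfMisaligned(apar, stress$te1, stress$te2, stress$we, landcover,
                   what = "CASA inputs")
  lc <- remapIgbp(gridValues(landcover))
  av <- gridValues(apar)
  years <- cubeYears(apar); months <- cubeMonths(apar)
  monthly <- array(NA_real_, dim(av))
  for (k in seq_along(years)) {
    yi <- match(years[k], cubeYears(landcover))
    if (is.na(yi)) stop("land cover missing year ", years[k])
    eps <- classLookup(lc[, , yi], params, "epsilon_star")
    monthly[, , k] <- av[, , k] *
      gridValues(stress$te1)[, , k] *
      gridValues(stress$te2)[, , k] *
      gridValues(stress$we)[, , k] * eps
  }
  ys <- sort(unique(years))
  d <- dim(av)
  annual <- array(NA_real_, c(d[1], d[2], length(ys)))
  for (k in seq_along(ys)) {
    annual[, , k] <- apply(monthly[, , years == ys[k], drop = FALSE],
                           c(1, 2), sum)
  }
  tr <- gridTransform(apar); crs <- gridCrs(apar)
  list(
    monthly = monthlyCube(monthly, years, months, tr, crs),
    annual = annualCube(annual, ys, tr, crs),
    apar = apar
  )
}

#' One-call CASA NPP estimate
#'
#' Chains \code{\link{computeFpar}}, \code{\link{computeApar}},
#' \code{\link{temperatureStress}}, \code{\link{waterStress}} and
#' \code{\link{computeNpp}}.
#'
#' @param ndvi,landcover,pre,tem,srad aligned input cubes.
#' @param params table from \code{\link{casaParams}}.
#' @return As \code{\link{computeNpp}}, plus the stress cubes.
#' @export
casaNpp <- function(ndvi, landcover, pre, tem, srad, params = casaParams()) {
  fpar <- computeFpar(ndvi, landcover, params)
  apar <- computeApar(fpar, srad)
  ts <- temperatureStress(tem, ndvi)
  we <- waterStress(pre, tem)
  stress <- list(te1 = ts$te1, te2 = ts$te2, we = we, topt = ts$topt)
  est <- computeNpp(apar, stress, params, landcover)
  c(est, list(fpar = fpar, stress = stress))
}

#' Validate an NPP estimate against a reference product
#'
#' Ordinary least squares of the estimate on the reference over pooled
#' pixel-years (masked pairs excluded): reports the coefficient of
#' determination R2, the RMSE of est vs ref (gC m-2 a-1), and n.
#'
#' @param est,ref aligned \linkS4class{AnnualCube}s over the same years.
#' @return List with \code{r2}, \code{rmse}, \code{n}.
#' @export
validateAgainstReference <- function(est, ref) {
  stopIfMisaligned(est, ref, what = "estimate and reference")
  if (!identical(cubeYears(est), cubeYears(ref))) {
    stop("estimate and reference cover different years")
  }
  e <- as.vector(gridValues(est)); r <- as.vector(gridValues(ref))
  ok <- !is.na(e) & !is.na(r)
  if (sum(ok) < 3L) stop("fewer than 3 joint unmasked pixel-years")
  fit <- stats::lm(e[ok] ~ r[ok])
  list(
    r2 = summary(fit)$r.squared,
    rmse = sqrt(mean((e[ok] - r[ok])^2)),
    n = sum(ok)
  )
}
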