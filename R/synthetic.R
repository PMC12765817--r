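#' @include casa.R
NULL

# smooth standardized Gaussian random field by FFT low-pass filtering of
# white noise; `scale` is the correlation length in pixels
smoothField <- function(nr, nc, scale = 8) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  fx <- c(0:(nr %/% 2), -((nr - nr %/% 2 - 1):1)) / nr
  fy <- c(0:(nc %/% 2), -((nc - nc %/% 2 - 1):1)) / nc
  k2 <- outer(fx^2, fy^2, "+")
  filt <- exp(-2 * (pi * scale)^2 * k2)
  f <- Re(stats::fft(stats::fft(z) * filt, inverse = TRUE)) / (nr * nc)
  (f - mean(f)) / stats::sd(f)
}

rescaleTo <- function(x, lo, hi) {
  r <- range(x)
  if (diff(r) == 0) return(matrix((lo + hi) / 2, nrow(x), ncol(x)))
  lo + (x - r[1]) / (r[2] - r[1]) * (hi - lo)
}

#' Slope and aspect from an elevation grid
#'
#' Central finite differences (one-sided at the edges). Slope in degrees;
#' aspect as the compass bearing of steepest descent in [0, 360) degrees
#' (0 = north, 90 = east), with flat cells assigned aspect 0.
#'
#' @param elevation \linkS4class{RasterGrid} of elevation (m); pixel size is
#'   taken from its geotransform.
#' @return List of two \linkS4class{RasterGrid}s: \code{slope}, \code{aspect}.
#' @export
terrainDerivatives <- function(elevation) {
  z <- gridValues(elevation)
  tr <- gridTransform(elevation)
  dx <- tr[2]; dy <- abs(tr[6])
  nr <- nrow(z); nc <- ncol(z)
  gradAlong <- function(m, h) {
    g <- m
    g[, 2:(ncol(m) - 1)] <- (m[, 3:ncol(m)] - m[, 1:(ncol(m) - 2)]) / (2 * h)
    g[, 1] <- (m[, 2] - m[, 1]) / h
    g[, ncol(m)] <- (m[, ncol(m)] - m[, ncol(m) - 1]) / h
    g
  }
  dzdx <- gradAlong(z, dx)                 # eastward derivative
  dzdy <- -t(gradAlong(t(z), dy))          # northward (rows run south)
  slope <- atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi
  aspect <- (atan2(-dzdx, -dzdy) * 180 / pi) %% 360
  aspect[dzdx == 0 & dzdy == 0] <- 0
  list(
    slope = RasterGrid(slope, tr, gridCrs(elevation)),
    aspect = RasterGrid(aspect, tr, gridCrs(elevation))
  )
}

#' Generate synthetic terrain
#'
#' Smooth random elevation in [500, 4500] m on a 500 m grid, with slope and
#' aspect derived by finite differences
#' (\code{\link{terrainDerivatives}}).
#'
#' @param nrow,ncol grid dimensions, each >= 16.
#' @param seed integer seed; regeneration is bit-identical.
#' @param cellsize pixel size in map units (m).
#' @return List of \linkS4class{RasterGrid}s: \code{elevation},
#'   \code{slope}, \code{aspect}.
#' @export
generateTerrain <- function(nrow = 64, ncol = 64, seed = 1, cellsize = 500) {
  if (nrow < 16 || ncol < 16) stop("grid must be at least 16 x 16")
  set.seed(seed)
  # fixed correlation lengths (in pixels): larger grids then carry more
  # independent terrain patches, stabilizing field statistics
  f <- smoothField(nrow, ncol, scale = 6) +
    0.35 * smoothField(nrow, ncol, scale = 3)
  tr <- c(0, cellsize, 0, nrow * cellsize, 0, -cellsize)
  elevation <- RasterGrid(rescaleTo(f, 500, 4500), tr, "local")
  c(list(elevation = elevation), terrainDerivatives(elevation))
}

#' Generate synthetic monthly climate driven by elevation
#'
#' Temperature: sea-level seasonal cycle minus a lapse-rate term
#' (\code{lapseRate} deg C per km of elevation), plus a north-south
#' latitudinal gradient (\code{latRange} deg C from the coldest northern
#' row to the warmest southern row), a smooth spatial anomaly and white
#' noise. The latitudinal and anomaly terms give temperature variation
#' that is independent of elevation, without which any
#' temperature-elevation interaction in a downstream response would be
#' statistically unidentifiable. Precipitation: a smooth spatial field of monthly
#' normals (wet south-west, default 40-180 mm) modulated by a monsoon
#' seasonal cycle, plus an optional linear yearly trend and noise. Solar
#' radiation: seasonal cycle around ~450 W m-2 with a smooth spatial
#' pattern; strictly positive.
#'
#' @param elevation \linkS4class{RasterGrid} from
#'   \code{\link{generateTerrain}}.
#' @param years integer vector of calendar years.
#' @param seed integer seed.
#' @param lapseRate temperature lapse rate, deg C per km.
#' @param preTrend linear trend of the annual-mean monthly precipitation,
#'   mm per year.
#' @param latRange south-minus-north temperature difference (deg C) across
#'   the grid.
#' @param noiseSd white-noise standard deviations, a named list with
#'   \code{tem}, \code{pre}, \code{srad} (set to 0 for exact fields).
#' @return List of \linkS4class{MonthlyCube}s: \code{pre}, \code{tem},
#'   \code{srad}.
#' @export
generateClimate <- function(elevation, years, seed = 1, lapseRate = 6.5,
                            preTrend = 0, latRange = 8,
                            noiseSd = list(tem = 0.5, pre = 6, srad = 8)) {
  set.seed(seed + 1L)
  z <- gridValues(elevation)
  nr <- nrow(z); nc <- ncol(z)
  ny <- length(years)
  # elevation-independent temperature structure (latitudinal gradient over
  # a stylized province-scale domain, plus a smooth mesoclimatic anomaly);
  # without it temperature would be a near-deterministic function of
  # elevation and no temperature x elevation effect could be identified
  temAnom <- 3.0 * smoothField(nr, nc, scale = 6) +
    matrix(seq(-latRange / 2, latRange / 2, length.out = nr), nr, nc)
  # monthly normals averaging ~95 mm (~1100 mm/yr) with a wet-south-west
  # gradient, so the 100-125 mm response band is well populated
  preBase <- rescaleTo(
    0.8 * smoothField(nr, nc, scale = 8) +
      outer(seq(0.8, -0.8, length.out = nr), seq(-0.6, 0.6, length.out = nc),
            "+"),
    30, 160)
  sradAnom <- 15 * smoothField(nr, nc, scale = 8)
  months <- rep(1:12, ny)
  yearsIdx <- rep(seq_len(ny), each = 12)
  nt <- ny * 12
  tem <- array(NA_real_, c(nr, nc, nt))
  pre <- array(NA_real_, c(nr, nc, nt))
  srad <- array(NA_real_, c(nr, nc, nt))
  for (k in seq_len(nt)) {
    m <- months[k]; yi <- yearsIdx[k]
    seas <- cos(2 * pi * (m - 7) / 12)
    # sea-level reference chosen so the domain-mean annual temperature sits
    # near 16 degC, matching a warm low-latitude mountain province
    temK <- 31 + 6 * seas - lapseRate * z / 1000 + temAnom
    preK <- preBase * (1 + 0.8 * seas) + preTrend * (yi - 1)
    sradK <- 450 + 80 * cos(2 * pi * (m - 6.5) / 12) + sradAnom +
      3 * z / 1000
    if (noiseSd$tem > 0) temK <- temK + stats::rnorm(nr * nc, 0, noiseSd$tem)
    if (noiseSd$pre > 0) preK <- preK + stats::rnorm(nr * nc, 0, noiseSd$pre)
    if (noiseSd$srad > 0) {
      sradK <- sradK + stats::rnorm(nr * nc, 0, noiseSd$srad)
    }
    tem[, , k] <- temK
    pre[, , k] <- pmax(preK, 0)
    srad[, , k] <- pmax(sradK, 1)
  }
  tr <- gridTransform(elevation); crs <- gridCrs(elevation)
  yv <- rep(as.integer(years), each = 12)
  list(
    pre = monthlyCube(pre, yv, months, tr, crs),
    tem = monthlyCube(tem, yv, months, tr, crs),
    srad = monthlyCube(srad, yv, months, tr, crs)
  )
}

#' Generate synthetic annual land cover with known SF/CF truth
#'
#' A fraction \code{1 - changeFraction} of forest pixels keeps one forest
#' subclass (IGBP 1-5) through all years; an exactly-counted
#' \code{round(changeFraction * n_forest)} subset changes at a seeded random
#' year: 70\% switch forest subclass, 15\% convert to non-forest and 15\%
#' start as non-forest and become forest. The remaining pixels are never
#' forest (grassland/cropland). The generator's own bookkeeping masks are
#' returned as ground truth for \code{\link{classifyForestDynamics}}.
#'
#' @param nrow,ncol grid dimensions.
#' @param years integer vector of calendar years (>= 3).
#' @param changeFraction fraction of forest pixels that change, in [0, 1).
#' @param forestFraction fraction of all pixels that are (ever) forest.
#' @param seed integer seed.
#' @param cellsize pixel size (m).
#' @return List: \code{landcover} (categorical \linkS4class{AnnualCube} of
#'   IGBP codes), \code{sfTruth}, \code{cfTruth} (logical matrices),
#'   \code{changeYear} (integer matrix, NA for unchanged).
#' @export
generateLandcover <- function(nrow = 64, ncol = 64, years, changeFraction,
                              forestFraction = 0.85, seed = 1,
                              cellsize = 500) {
  if (changeFraction < 0 || changeFraction >= 1) {
    stop("changeFraction must lie in [0, 1)")
  }
  ny <- length(years)
  if (ny < 3L) stop("need at least 3 years")
  set.seed(seed + 2L)
  npix <- nrow * ncol
  # spatially clustered forest subclasses from a smooth field
  f <- smoothField(nrow, ncol, scale = 6)
  subclass <- as.integer(cut(f, stats::quantile(f, probs = seq(0, 1, 0.2)),
                             include.lowest = TRUE))  # 1..5
  forest <- matrix(FALSE, nrow, ncol)
  forest[order(smoothField(nrow, ncol, scale = 10) + stats::rnorm(npix, 0, 0.3),
               decreasing = TRUE)[seq_len(round(forestFraction * npix))]] <-
    TRUE
  fIdx <- which(forest)
  nCf <- round(changeFraction * length(fIdx))
  cfIdx <- if (nCf > 0) sample(fIdx, nCf) else integer()
  kind <- if (nCf > 0) {
    sample(c("subclass", "to_nonforest", "from_nonforest"), nCf,
           replace = TRUE, prob = c(0.70, 0.15, 0.15))
  } else character()
  chYear <- if (nCf > 0) sample(2:(ny - 1), nCf, replace = TRUE) else integer()
  nonForestCode <- matrix(sample(c(10L, 12L), npix, replace = TRUE),
                          nrow, ncol)  # grassland / cropland
  lc <- array(NA_integer_, c(nrow, ncol, ny))
  base <- matrix(subclass, nrow, ncol)
  for (t in seq_len(ny)) {
    layer <- ifelse(forest, base, nonForestCode)
    lc[, , t] <- layer
  }
  if (nCf > 0) {
    newClass <- vapply(seq_len(nCf), function(i) {
      old <- base[cfIdx[i]]
      sample(setdiff(1:5, old), 1L)
    }, integer(1))
    for (i in seq_len(nCf)) {
      px <- cfIdx[i]
      rc <- arrayInd(px, c(nrow, ncol))
      after <- chYear[i]:ny
      if (kind[i] == "subclass") {
        lc[rc[1], rc[2], after] <- newClass[i]
      } else if (kind[i] == "to_nonforest") {
        lc[rc[1], rc[2], after] <- nonForestCode[px]
      } else {
        lc[rc[1], rc[2], seq_len(chYear[i] - 1L)] <- nonForestCode[px]
      }
    }
  }
  cfTruth <- matrix(FALSE, nrow, ncol)
  cfTruth[cfIdx] <- TRUE
  sfTruth <- forest & !cfTruth
  changeYear <- matrix(NA_integer_, nrow, ncol)
  changeYear[cfIdx] <- as.integer(years[chYear])
  tr <- c(0, cellsize, 0, nrow * cellsize, 0, -cellsize)
  list(
    landcover = annualCube(lc, years, tr, "local", categorical = TRUE),
    sfTruth = sfTruth, cfTruth = cfTruth, changeYear = changeYear
  )
}

#' Generate auxiliary anthropogenic / forest-attribute grids
#'
#' Human-activity intensity (index in [0, 1], concentrated at low
#' elevations), forest age (years, smooth in [10, 120]) and forest type
#' (planted = 1 / natural = 0, clustered, more plantations where human
#' activity is high).
#'
#' @param elevation \linkS4class{RasterGrid}.
#' @param seed integer seed.
#' @return List of \linkS4class{RasterGrid}s: \code{ha}, \code{age},
#'   \code{ftype}.
#' @export
generateAnthropogenic <- function(elevation, seed = 1) {
  set.seed(seed + 3L)
  z <- gridValues(elevation)
  nr <- nrow(z); nc <- ncol(z)
  lowland <- 1 - (z - min(z)) / diff(range(z))
  ha <- rescaleTo(0.6 * lowland + 0.4 * smoothField(nr, nc, scale = 5), 0, 1)
  age <- rescaleTo(smoothField(nr, nc, scale = 7), 10, 120)
  ftype <- (0.5 * smoothField(nr, nc, scale = 6) + 0.5 * (ha - 0.5)) > 0.15
  tr <- gridTransform(elevation); crs <- gridCrs(elevation)
  list(
    ha = RasterGrid(ha, tr, crs),
    age = RasterGrid(age, tr, crs),
    ftype = RasterGrid(ftype + 0, tr, crs, categorical = TRUE)
  )
}

#' Default response-surface parameters of the synthetic NPP truth
#'
#' The closed-form response of multi-year mean NPP to the drivers: a
#' saturating precipitation ramp over [100, 125] mm (the dominant term), a
#' unimodal temperature response with optimum 17 deg C (rising over
#' 14-20 deg C and declining above), a flat-then-declining elevation term
#' breaking at 2000 m, a forest-age peak across 50-70 years, a linear
#' human-activity penalty, and a temperature x elevation interaction (the
#' dominant pairwise interaction). Temporal structure: a per-pixel linear
#' trend plus fractional-Gaussian-noise residuals with target Hurst
#' exponent.
#'
#' @param ... overrides of the defaults.
#' @return Named list of truth parameters.
#' @export
syntheticTruth <- function(...) {
  truth <- list(
    mu = 900,              # baseline NPP, gC m-2 a-1
    # effect amplitudes encode the designed driver ordering: the
    # precipitation ramp is the clearly dominant driver
    preLo = 100, preHi = 125, preAmp = 700,   # saturating ramp (mm -> gC)
    temOpt = 17, temSd = 4.5, temAmp = 120,   # unimodal, peak inside 14-20
    eleBreak = 2000, eleSlope = -80,          # gC per km above the break
    agePeak = 60, ageSd = 15, ageAmp = 100,   # peak inside 50-70 yr
    haBeta = -80,                             # per unit Ha index
    # Tem x Ele product term on standardized factors; NA references/scales
    # are replaced by the realized field means/SDs at generation time, so
    # the product is a pure interaction (no marginal component) whose
    # magnitude in gC m-2 a-1 per unit product is stable across
    # realizations and comparable to the main effects
    interAmp = 180, interTemRef = NA, interEleRef = NA,
    interTemScale = NA, interEleScale = NA,
    trendSlope = 3,       # gC m-2 a-2, spatially modulated
    hurstH = 0.8, fgnSd = 30, whiteSd = 10,
    ndviRange = c(0.1, 0.85)
  )
  truth[names(list(...))] <- list(...)
  truth
}

# closed-form spatial response at given multi-year mean driver values
nppResponse <- function(truth, pre, tem, ele, age, ha, ftype) {
  fPre <- truth$preAmp *
    pmin(pmax((pre - truth$preLo) / (truth$preHi - truth$preLo), 0), 1)
  fTem <- truth$temAmp * exp(-((tem - truth$temOpt)^2) / (2 * truth$temSd^2))
  fEle <- truth$eleSlope * pmax(ele - truth$eleBreak, 0) / 1000
  fAge <- truth$ageAmp * exp(-((age - truth$agePeak)^2) / (2 * truth$ageSd^2))
  fHa <- truth$haBeta * ha
  inter <- truth$interAmp *
    ((tem - truth$interTemRef) / truth$interTemScale) *
    ((ele - truth$interEleRef) / truth$interEleScale)
  truth$mu + fPre + fTem + fEle + fAge + fHa + inter + 0 * ftype
}

#' Generate synthetic NPP and NDVI with known ground truth
#'
#' Annual NPP is the closed-form driver response (see
#' \code{\link{syntheticTruth}}) evaluated at each pixel's multi-year mean
#' drivers, plus a per-pixel linear trend and a temporal residual of
#' fractional Gaussian noise (target Hurst exponent \code{truth$hurstH})
#' and white noise. Monthly NDVI is a strictly monotone bounded transform
#' of the pixel's true mean productivity modulated by a seasonal cycle, so
#' light-use-efficiency inversion tests are well-posed.
#'
#' @param drivers list with \code{pre}, \code{tem}, \code{srad}
#'   (\linkS4class{MonthlyCube}s), \code{elevation}, \code{ha}, \code{age},
#'   \code{ftype} (\linkS4class{RasterGrid}s).
#' @param truth parameter list from \code{\link{syntheticTruth}}.
#' @param years integer vector of calendar years.
#' @param seed integer seed.
#' @return List: \code{npp} (\linkS4class{AnnualCube}), \code{ndvi}
#'   (\linkS4class{MonthlyCube}), \code{meanResponse} (matrix of the
#'   noise-free spatial response), \code{trendField} (matrix of true slopes,
#'   gC m-2 a-2), \code{truth}.
#' @export
generateNpp <- function(drivers, truth = syntheticTruth(), years, seed = 1) {
  stopIfMisaligned(drivers$pre, drivers$tem, drivers$srad,
                   drivers$elevation, what = "driver cubes")
  set.seed(seed + 4L)
  preM <- apply(gridValues(drivers$pre), c(1, 2), mean)
  temM <- apply(gridValues(drivers$tem), c(1, 2), mean)
  ele <- gridValues(drivers$elevation)
  age <- gridValues(drivers$age)
  ha <- gridValues(drivers$ha)
  ftype <- gridValues(drivers$ftype)
  if (is.na(truth$interTemRef)) truth$interTemRef <- mean(temM)
  if (is.na(truth$interEleRef)) truth$interEleRef <- mean(ele)
  if (is.na(truth$interTemScale)) truth$interTemScale <- stats::sd(temM)
  if (is.na(truth$interEleScale)) truth$interEleScale <- stats::sd(ele)
  base <- nppResponse(truth, preM, temM, ele, age, ha, ftype)
  nr <- nrow(base); nc <- ncol(base); ny <- length(years)
  trendField <- truth$trendSlope *
    (0.5 + 0.5 * rescaleTo(smoothField(nr, nc, scale = 8), 0, 1))
  tCent <- seq_len(ny) - (ny + 1) / 2
  npp <- array(NA_real_, c(nr, nc, ny))
  resid <- matrix(0, nr * nc, ny)
  if (truth$fgnSd > 0) {
    for (i in seq_len(nr * nc)) {
      resid[i, ] <- truth$fgnSd * rfgn(ny, truth$hurstH)
    }
  }
  if (truth$whiteSd > 0) {
    resid <- resid + matrix(stats::rnorm(nr * nc * ny, 0, truth$whiteSd),
                            nr * nc, ny)
  }
  for (t in seq_len(ny)) {
    npp[, , t] <- pmax(base + trendField * tCent[t] +
                         matrix(resid[, t], nr, nc), 0)
  }
  # strictly monotone NDVI transform of true mean productivity
  u <- (base - min(base)) / max(diff(range(base)), 1e-12)
  lo <- truth$ndviRange[1]; hi <- truth$ndviRange[2]
  nt <- ny * 12
  ndvi <- array(NA_real_, c(nr, nc, nt))
  months <- rep(1:12, ny)
  for (k in seq_len(nt)) {
    seas <- 0.75 + 0.25 * cos(2 * pi * (months[k] - 8) / 12)
    ndvi[, , k] <- lo + (hi - lo) * u * seas
  }
  tr <- gridTransform(drivers$elevation); crs <- gridCrs(drivers$elevation)
  list(
    npp = annualCube(npp, years, tr, crs),
    ndvi = monthlyCube(ndvi, rep(as.integer(years), each = 12), months,
                       tr, crs),
    meanResponse = base,
    trendField = trendField,
    truth = truth
  )
}

#' Generate the full synthetic study system
#'
#' One call that produces terrain, climate, land cover with SF/CF truth,
#' anthropogenic grids, true NPP and NDVI, all mutually aligned and fully
#' determined by \code{seed}.
#'
#' @param nrow,ncol grid dimensions (default 64 x 64).
#' @param years calendar years (default 2001:2022).
#' @param changeFraction fraction of forest pixels that change subclass or
#'   forest status.
#' @param truth response-surface truth from \code{\link{syntheticTruth}}.
#' @param seed integer seed.
#' @param preTrend precipitation trend passed to
#'   \code{\link{generateClimate}} (mm per year).
#' @param noiseSd climate noise levels, see \code{\link{generateClimate}}.
#' @return List with all generated layers plus the \code{truth} bookkeeping.
#' @export
generateStudySystem <- function(nrow = 64, ncol = 64, years = 2001:2022,
                                changeFraction = 0.3,
                                truth = syntheticTruth(), seed = 1,
                                preTrend = 0,
                                noiseSd = list(tem = 0.5, pre = 6,
                                               srad = 8)) {
  terrain <- generateTerrain(nrow, ncol, seed)
  climate <- generateClimate(terrain$elevation, years, seed,
                             preTrend = preTrend, noiseSd = noiseSd)
  lcov <- generateLandcover(nrow, ncol, years, changeFraction, seed = seed)
  anthro <- generateAnthropogenic(terrain$elevation, seed)
  drivers <- c(terrain, climate, anthro)
  nppGen <- generateNpp(drivers, truth, years, seed)
  c(terrain, climate, anthro, lcov, nppGen, list(years = years, seed = seed))
}
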