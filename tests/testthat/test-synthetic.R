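test_that("terrain generation is seeded, bounded and differentiable", {
  t1 <- generateTerrain(24, 24, seed = 5)
  t2 <- generateTerrain(24, 24, seed = 5)
  expect_identical(gridValues(t1$elevation), gridValues(t2$elevation))
  z <- gridValues(t1$elevation)
  expect_true(all(z >= 500 & z <= 4500))
  a <- gridValues(t1$aspect)
  expect_true(all(a >= 0 & a < 360))
  expect_error(generateTerrain(8, 8), "16")
})

test_that("a flat elevation field has zero slope everywhere", {
  flat <- RasterGrid(matrix(1500, 20, 20),
                     transform = c(0, 500, 0, 10000, 0, -500))
  d <- terrainDerivatives(flat)
  expect_true(all(gridValues(d$slope) == 0))
})

test_that("a plane dipping due south has uniform aspect 180", {
  # elevation decreases southward (with increasing row index)
  z <- matrix(rep(seq(2000, 1000, length.out = 20), each = 20), 20, 20,
              byrow = TRUE)
  g <- RasterGrid(z, transform = c(0, 500, 0, 10000, 0, -500))
  d <- terrainDerivatives(g)
  expect_true(all(abs(gridValues(d$aspect) - 180) < 1e-9))
  # analytic slope of the plane: atan(drop / run)
  drop <- (2000 - 1000) / 19 / 500
  expect_equal(max(abs(gridValues(d$slope) - atan(drop) * 180 / pi)), 0,
               tolerance = 1e-9)
})

test_that("temperature follows the configured lapse rate exactly", {
  tr <- c(0, 500, 0, 8000, 0, -500)
  eleLo <- RasterGrid(matrix(1000, 16, 16), tr)
  eleHi <- RasterGrid(matrix(2000, 16, 16), tr)
  noNoise <- list(tem = 0, pre = 0, srad = 0)
  clLo <- generateClimate(eleLo, 2001:2003, seed = 2, lapseRate = 6.5,
                          noiseSd = noNoise)
  clHi <- generateClimate(eleHi, 2001:2003, seed = 2, lapseRate = 6.5,
                          noiseSd = noNoise)
  # same seed, elevations 1000 m apart: every month differs by 6.5 degC
  expect_equal(gridValues(clLo$tem) - gridValues(clHi$tem),
               array(6.5, dim(gridValues(clLo$tem))), tolerance = 1e-12)
  expect_true(all(gridValues(clLo$srad) > 0))
})

test_that("a configured precipitation trend is recovered exactly by Theil-Sen", {
  ele <- generateTerrain(16, 16, seed = 3)$elevation
  cl <- generateClimate(ele, 2001:2012, seed = 3, preTrend = 2,
                        noiseSd = list(tem = 0, pre = 0, srad = 0))
  pv <- gridValues(cl$pre)
  yrs <- cubeYears(cl$pre)
  annualMean <- vapply(sort(unique(yrs)), function(y) {
    mean(pv[4, 7, yrs == y])
  }, numeric(1))
  expect_equal(theilSenSlope(annualMean), 2, tolerance = 1e-10)
})

test_that("land-cover change counts and truth masks are exact", {
  g0 <- generateLandcover(20, 20, 2001:2010, changeFraction = 0, seed = 7)
  expect_true(all(!g0$cfTruth))
  expect_true(any(g0$sfTruth))
  g3 <- generateLandcover(20, 20, 2001:2010, changeFraction = 0.3, seed = 7)
  nForest <- sum(g3$sfTruth | g3$cfTruth)
  expect_identical(sum(g3$cfTruth), as.integer(round(0.3 * nForest)))
  # deterministic under the seed
  g3b <- generateLandcover(20, 20, 2001:2010, changeFraction = 0.3, seed = 7)
  expect_identical(gridValues(g3$landcover), gridValues(g3b$landcover))
  expect_error(generateLandcover(20, 20, 2001:2010, 1.0), "changeFraction")
})

test_that("noise-free NPP equals the documented closed form pointwise", {
  sys <- cleanSystem()
  tr <- sys$truth
  pre <- apply(gridValues(sys$pre), c(1, 2), mean)
  tem <- apply(gridValues(sys$tem), c(1, 2), mean)
  ele <- gridValues(sys$elevation)
  age <- gridValues(sys$age)
  ha <- gridValues(sys$ha)
  # independent re-evaluation of the response surface
  expected <- tr$mu +
    tr$preAmp * pmin(pmax((pre - tr$preLo) / (tr$preHi - tr$preLo), 0), 1) +
    tr$temAmp * exp(-((tem - tr$temOpt)^2) / (2 * tr$temSd^2)) +
    tr$eleSlope * pmax(ele - tr$eleBreak, 0) / 1000 +
    tr$ageAmp * exp(-((age - tr$agePeak)^2) / (2 * tr$ageSd^2)) +
    tr$haBeta * ha +
    tr$interAmp * ((tem - tr$interTemRef) / tr$interTemScale) *
      ((ele - tr$interEleRef) / tr$interEleScale)
  for (k in c(1, 11, 22)) {
    expect_equal(gridValues(sys$npp)[, , k], pmax(expected, 0),
                 tolerance = 1e-12)
  }
})

test_that("the temperature response peaks at the configured optimum", {
  tr <- syntheticTruth(interTemRef = 15, interEleRef = 2300,
                       interTemScale = 5, interEleScale = 900)
  sweep <- seq(5, 30, by = 0.1)
  # at ele = interEleRef the interaction term vanishes for every tem
  resp <- forestNPP:::nppResponse(tr, pre = 110, tem = sweep,
                                  ele = tr$interEleRef,
                                  age = 60, ha = 0.2, ftype = 0)
  expect_equal(sweep[which.max(resp)], tr$temOpt, tolerance = 0.051)
})

test_that("fGn residuals match the theoretical lag-1 autocorrelation", {
  set.seed(11)
  for (H in c(0.3, 0.5, 0.8)) {
    # the process has known mean 0, so use the uncentered estimator
    # (centering biases autocovariances downward under long memory)
    ac1 <- mean(replicate(60, {
      x <- rfgn(2048, H)
      mean(x[-1] * x[-length(x)])
    }))
    expect_lt(abs(ac1 - fgnAutocov(1, H)), 0.04)
  }
})

test_that("regeneration from the same seed is bit-identical", {
  a <- generateStudySystem(nrow = 16, ncol = 16, years = 2001:2005,
                           changeFraction = 0.2, seed = 42)
  b <- generateStudySystem(nrow = 16, ncol = 16, years = 2001:2005,
                           changeFraction = 0.2, seed = 42)
  expect_identical(gridValues(a$npp), gridValues(b$npp))
  expect_identical(gridValues(a$ndvi), gridValues(b$ndvi))
  expect_identical(gridValues(a$pre), gridValues(b$pre))
})
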