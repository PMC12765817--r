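toyParams <- data.frame(class_code = 1:9, NDVImin = 0.1, NDVImax = 0.9,
                        epsilon_star = 0.5)

test_that("FPAR clips at the class NDVI bounds", {
  lc <- constantAnnual(2, categorical = TRUE)       # EBF everywhere
  atMax <- computeFpar(constantMonthly(0.9), lc, toyParams)
  expect_true(all(gridValues(atMax) == 0.95))
  atMin <- computeFpar(constantMonthly(0.1), lc, toyParams)
  expect_true(all(gridValues(atMin) == 0.001))
  over <- computeFpar(constantMonthly(0.95), lc, toyParams)
  expect_true(all(gridValues(over) == 0.95))
})

test_that("FPAR midway equals the mean of the NDVI and SR estimates", {
  lc <- constantAnnual(1, categorical = TRUE)
  f <- computeFpar(constantMonthly(0.5), lc, toyParams)
  # hand evaluation: NDVI estimate = (0.5-0.1)/(0.9-0.1)*0.949 + 0.001
  fN <- (0.5 - 0.1) / 0.8 * (0.95 - 0.001) + 0.001
  sr <- (1 + 0.5) / (1 - 0.5)            # 3
  srMin <- (1 + 0.1) / (1 - 0.1)         # 1.2222
  srMax <- (1 + 0.9) / (1 - 0.9)         # 19
  fS <- (sr - srMin) / (srMax - srMin) * (0.95 - 0.001) + 0.001
  expect_equal(gridValues(f)[1, 1, 1], (fN + fS) / 2, tolerance = 1e-12)
})

test_that("FPAR rejects class codes missing from the parameter table", {
  lc <- constantAnnual(4, categorical = TRUE)
  p <- toyParams[toyParams$class_code != 4, ]
  expect_error(computeFpar(constantMonthly(0.5), lc, p), "class code")
})

test_that("APAR unit conversion matches hand arithmetic", {
  # srad = 231.48 W/m2 over a 30-day month -> SOL = 600.0 MJ/m2;
  # with FPAR = 1, APAR = 300.0
  fpar <- monthlyCube(array(1, c(2, 2, 12)), rep(2001, 12), 1:12,
                      transform = c(0, 1, 0, 2, 0, -1))
  srad <- monthlyCube(array(231.48, c(2, 2, 12)), rep(2001, 12), 1:12,
                      transform = c(0, 1, 0, 2, 0, -1))
  apar <- computeApar(fpar, srad)
  april <- gridValues(apar)[1, 1, 4]        # 30-day month
  expect_equal(april, 300.0, tolerance = 1e-4)
  # zero FPAR kills APAR; doubling srad doubles it
  apar0 <- computeApar(constantMonthly(0, 2, 2), srad)
  expect_true(all(gridValues(apar0) == 0))
  apar2 <- computeApar(fpar, monthlyCube(array(2 * 231.48, c(2, 2, 12)),
                                         rep(2001, 12), 1:12,
                                         transform = c(0, 1, 0, 2, 0, -1)))
  expect_equal(gridValues(apar2), 2 * gridValues(apar))
  bad <- monthlyCube(array(-1, c(2, 2, 12)), rep(2001, 12), 1:12,
                     transform = c(0, 1, 0, 2, 0, -1))
  expect_error(computeApar(fpar, bad), "negative")
})

test_that("temperature stress scalars follow their closed forms", {
  # Topt = 20: Te1 = 0.8 + 0.4 - 0.2 = 1.0 exactly
  tem <- constantMonthly(20)
  ndvi <- constantMonthly(0.5)
  ts <- temperatureStress(tem, ndvi)
  expect_equal(gridValues(ts$topt)[1, 1, 1], 20)
  expect_true(all(abs(gridValues(ts$te1) - 1.0) < 1e-12))
  # T = Topt: Te2 = 1.184 / (1 + e^-2) / (1 + e^-3) ~ 0.9993... by hand
  te2Expect <- 1.184 / (1 + exp(-2)) / (1 + exp(-3))
  expect_equal(gridValues(ts$te2)[1, 1, 1], te2Expect, tolerance = 1e-12)
  expect_lt(abs(te2Expect - 0.993), 0.001)
  # a Topt where the quadratic goes negative clips to 0
  cold <- temperatureStress(constantMonthly(-60), ndvi)
  expect_true(all(gridValues(cold$te1) == 0))
})

test_that("stress scalars stay inside their bounds for arbitrary inputs", {
  set.seed(3)
  for (rep in 1:5) {
    tem <- monthlyCube(array(runif(4 * 4 * 12, -80, 60), c(4, 4, 12)),
                       rep(2001, 12), 1:12, transform = c(0, 1, 0, 4, 0, -1))
    ndvi <- monthlyCube(array(runif(4 * 4 * 12, -1, 1), c(4, 4, 12)),
                        rep(2001, 12), 1:12,
                        transform = c(0, 1, 0, 4, 0, -1))
    pre <- monthlyCube(array(rexp(4 * 4 * 12, 1 / 80), c(4, 4, 12)),
                       rep(2001, 12), 1:12, transform = c(0, 1, 0, 4, 0, -1))
    ts <- temperatureStress(tem, ndvi)
    expect_true(all(gridValues(ts$te1) >= 0 & gridValues(ts$te1) <= 1))
    expect_true(all(gridValues(ts$te2) >= 0 &
                      gridValues(ts$te2) <= 1.184 + 1e-12))
    we <- waterStress(pre, tem)
    expect_true(all(gridValues(we) >= 0.5 & gridValues(we) <= 1))
  }
})

test_that("moisture scalar hits its documented anchor points", {
  # water-saturated month: EET caps at PET, so We = 0.5 + 0.5 * 1 = 1
  weWet <- waterStress(constantMonthly(5000), constantMonthly(20))
  expect_true(all(gridValues(weWet) == 1))
  # freezing month: PET = 0 falls back to 0.5
  we <- waterStress(constantMonthly(50), constantMonthly(-10))
  expect_true(all(gridValues(we) == 0.5))
  # no precipitation: EET = 0 -> 0.5
  weDry <- waterStress(constantMonthly(0), constantMonthly(15))
  expect_true(all(gridValues(weDry) == 0.5))
  expect_error(waterStress(constantMonthly(-5), constantMonthly(15)),
               "negative")
})

test_that("NPP is the exact product of APAR, stress scalars and epsilon*", {
  tr <- c(0, 1, 0, 2, 0, -1)
  mk <- function(v) monthlyCube(array(v, c(2, 2, 12)), rep(2001, 12), 1:12,
                                transform = tr)
  apar <- mk(100)
  stress <- list(te1 = mk(1), te2 = mk(1), we = mk(1))
  lc <- constantAnnual(1, nr = 2, nc = 2, categorical = TRUE)
  est <- computeNpp(apar, stress, toyParams, lc)
  expect_true(all(gridValues(est$monthly) == 50))        # 100 * 0.5
  expect_true(all(gridValues(est$annual) == 600))        # 12 * 50
  # any zero stress scalar zeroes NPP
  est0 <- computeNpp(apar, list(te1 = mk(0), te2 = mk(1), we = mk(1)),
                     toyParams, lc)
  expect_true(all(gridValues(est0$monthly) == 0))
  # halving epsilon* halves NPP everywhere
  half <- toyParams
  half$epsilon_star <- half$epsilon_star / 2
  estH <- computeNpp(apar, stress, half, lc)
  expect_equal(gridValues(estH$annual), gridValues(est$annual) / 2)
})

test_that("validation metrics behave under affine maps and independence", {
  set.seed(8)
  v <- array(runif(100 * 4, 200, 1500), c(10, 10, 4))
  tr <- c(0, 1, 0, 10, 0, -1)
  est <- annualCube(v, 2001:2004, tr)
  # lm warns about the perfect fit; that is the point of these two cases
  same <- suppressWarnings(validateAgainstReference(est, est))
  expect_equal(same$r2, 1)
  expect_equal(same$rmse, 0)
  aff <- suppressWarnings(validateAgainstReference(
    annualCube(2 * v + 5, 2001:2004, tr), est))
  expect_equal(aff$r2, 1)
  noise <- annualCube(array(rnorm(length(v)), dim(v)), 2001:2004, tr)
  ind <- validateAgainstReference(est, noise)
  expect_lt(ind$r2, 0.05)
  tiny <- annualCube(array(c(1, NA, NA, NA), c(2, 2, 1)), 2001, c(0, 1, 0,
                                                                  2, 0, -1))
  expect_error(validateAgainstReference(tiny, tiny), "fewer than 3")
})

test_that("CASA NPP ranks pixels like the true productivity at zero noise", {
  sys <- cleanSystem()
  est <- casaNpp(sys$ndvi, sys$landcover, sys$pre, sys$tem, sys$srad)
  m <- apply(gridValues(est$annual), c(1, 2), mean)
  rho <- stats::cor(as.vector(m), as.vector(sys$meanResponse),
                    method = "spearman")
  expect_gt(rho, 0.8)
  expect_true(all(gridValues(est$monthly) >= 0))
  expect_equal(gridValues(est$annual)[, , 1],
               apply(gridValues(est$monthly)[, , 1:12], c(1, 2), sum))
})
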