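test_that("partial dependence on an unused feature is exactly flat", {
  sys <- cleanSystem()
  dl <- driverLists(sys)
  mask <- sys$sfTruth | sys$cfTruth
  tab <- buildDriverTable(sys$npp, dl$climate, dl$terrain, dl$anthro, mask,
                          sampleCap = 600, seed = 51)
  m <- fitRf(tab, budget = 0, seed = 51,
             features = setdiff(forestNPP:::driverFeatures, "Tem"),
             params = list(num.trees = 80, max.depth = 5))
  cu <- partialDependence(m, "Tem", nGrid = 15)
  scale <- diff(range(tab$npp))
  expect_lt(diff(range(cu$pd)), 1e-6 * scale)
})

test_that("a linear truth is recovered with the right PDP slope", {
  sys <- cleanSystem()
  dl <- driverLists(sys)
  tab <- buildDriverTable(sys$npp, dl$climate, dl$terrain, dl$anthro,
                          matrix(TRUE, 32, 32), sampleCap = 900, seed = 52)
  set.seed(52)
  tab$npp <- 3 * tab$Ele + rnorm(nrow(tab), 0, 20)
  m <- fitRf(tab, budget = 0, seed = 52,
             params = list(num.trees = 150, max.depth = 8, mtry = 6))
  cu <- partialDependence(m, "Ele", nGrid = 25)
  # interior slope (forests attenuate at the support edges)
  keep <- cu$grid >= quantile(tab$Ele, 0.15) &
    cu$grid <= quantile(tab$Ele, 0.85)
  fit <- lm(cu$pd[keep] ~ cu$grid[keep])
  expect_equal(unname(coef(fit)[2]), 3, tolerance = 0.25)
})

test_that("duplicating rows leaves the curve unchanged", {
  m <- cleanModel()
  cu1 <- partialDependence(m, "Pre", nGrid = 12)
  m2 <- m
  m2@table <- rbind(m@table, m@table)
  cu2 <- partialDependence(m2, "Pre", nGrid = 12)
  expect_equal(cu1$pd, cu2$pd)
  expect_error(partialDependence(m, "NotAFeature"), "unknown feature")
})

test_that("grids are strictly increasing with density flags", {
  m <- cleanModel()
  cu <- partialDependence(m, "Ele", nGrid = 20)
  expect_true(all(diff(cu$grid) > 0))
  expect_equal(sum(cu$density), 1, tolerance = 1e-12)
  expect_identical(cu$sparse, cu$density < 0.01)
})

test_that("threshold extraction needs enough dense points and handles flats", {
  flat <- structure(list(feature = "x", grid = seq_len(20),
                         pd = rep(5, 20), density = rep(0.05, 20),
                         sparse = rep(FALSE, 20)), class = "PDPCurve")
  th <- extractThresholds(flat)
  expect_equal(nrow(th$breakpoints), 0)
  expect_null(th$optimum)
  expect_identical(th$directions$direction, "flat")
  few <- flat
  few$sparse <- c(rep(FALSE, 8), rep(TRUE, 12))
  expect_error(extractThresholds(few), "10 unflagged")
})

test_that("a unimodal curve yields an optimum around its peak", {
  g <- seq(0, 30, length.out = 40)
  pd <- 1000 + 200 * exp(-((g - 17)^2) / (2 * 3^2))
  cu <- structure(list(feature = "Tem", grid = g, pd = pd,
                       density = rep(1 / 40, 40),
                       sparse = rep(FALSE, 40)), class = "PDPCurve")
  th <- extractThresholds(cu)
  expect_true(th$optimum[1] <= 17 && th$optimum[2] >= 17)
  expect_true(th$optimum[1] > 10 && th$optimum[2] < 24)
  dirs <- th$directions$direction
  expect_true("increasing" %in% dirs && "decreasing" %in% dirs)
})

test_that("a piecewise flat-then-declining curve breaks near the knee", {
  g <- seq(500, 4500, length.out = 50)
  pd <- 1200 - 0.3 * pmax(g - 2000, 0)
  cu <- structure(list(feature = "Ele", grid = g, pd = pd,
                       density = rep(1 / 50, 50),
                       sparse = rep(FALSE, 50)), class = "PDPCurve")
  th <- extractThresholds(cu, smoothWindow = 3)
  dec <- th$breakpoints[th$breakpoints$to == "decreasing", ]
  expect_equal(nrow(dec), 1)
  step <- diff(g)[1]
  expect_lt(abs(dec$value - 2000), 2 * step + 1e-9)
  # the decline persists to the end of the grid
  last <- th$directions[nrow(th$directions), ]
  expect_identical(last$direction, "decreasing")
  expect_equal(last$end, max(g))
})
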