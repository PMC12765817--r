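test_that("the change code is 10A + B with a decodable round-trip", {
  expect_identical(encodeChange(1, 2), 12L)   # ENF -> EBF
  expect_identical(encodeChange(5, 5), 55L)   # no-change code
  expect_error(encodeChange(4, 13), "1..9")
  expect_error(encodeChange(0, 3), "1..9")
  # round-trip identity over the whole remapped domain
  grid <- expand.grid(a = 1:9, b = 1:9)
  C <- encodeChange(grid$a, grid$b)
  expect_false(anyDuplicated(C) > 0)
  dec <- decodeChange(C)
  expect_identical(dec$from, grid$a)
  expect_identical(dec$to, grid$b)
})

test_that("IGBP remapping keeps forest subclasses and aggregates the rest", {
  expect_identical(remapIgbp(1:5), c(1, 2, 3, 4, 5))
  expect_identical(remapIgbp(c(8, 10)), c(6, 6))      # savanna, grassland
  expect_identical(remapIgbp(c(12, 14)), c(7, 7))     # cropland, mosaic
  expect_identical(remapIgbp(13), 8)                  # built
  expect_identical(remapIgbp(c(11, 17)), c(9, 9))     # wetland, water
  expect_error(remapIgbp(18), "1..17")
})

test_that("per-pixel sequences classify as SF, CF or unlabeled", {
  tr <- c(0, 1, 0, 2, 0, -1)
  seqCube <- function(a, b, c, d) {
    arr <- array(NA_real_, c(2, 2, 22))
    arr[1, 1, ] <- a; arr[1, 2, ] <- b; arr[2, 1, ] <- c; arr[2, 2, ] <- d
    annualCube(arr, 2001:2022, tr, categorical = TRUE)
  }
  cm <- classifyForestDynamics(seqCube(
    rep(2, 22),                      # all-EBF -> SF
    c(rep(1, 10), rep(2, 12)),       # ENF then EBF -> CF coded 12
    rep(12, 22),                     # cropland forever -> unlabeled
    c(rep(2, 21), 10)                # forest converted out -> CF
  ))
  expect_true(sfMask(cm)[1, 1])
  expect_true(cfMask(cm)[1, 2])
  expect_identical(changeCode(cm)[1, 2], 12L)
  expect_false(sfMask(cm)[2, 1] || cfMask(cm)[2, 1])
  expect_true(is.na(changeCode(cm)[2, 1]))
  expect_true(cfMask(cm)[2, 2])
  # legend decodes the codes present
  expect_true(all(c(22, 12) %in% changeLegend(cm)$code))
  expect_identical(
    changeLegend(cm)$from[changeLegend(cm)$code == 12], "ENF")
  expect_identical(changeLegend(cm)$to[changeLegend(cm)$code == 12], "EBF")
})

test_that("a transient one-year excursion counts as change unless endpoint-only", {
  arr <- array(2, c(2, 2, 10))
  arr[1, 1, 5] <- 4                  # one-year DBF excursion, endpoints EBF
  cube <- annualCube(arr, 2001:2010, c(0, 1, 0, 2, 0, -1),
                     categorical = TRUE)
  full <- classifyForestDynamics(cube)
  expect_true(cfMask(full)[1, 1])
  expect_identical(changeCode(full)[1, 1], 22L)  # endpoints still EBF
  ep <- classifyForestDynamics(cube, endpointOnly = TRUE)
  expect_true(sfMask(ep)[1, 1])
})

test_that("classification recovers the generator truth masks exactly", {
  for (cf in c(0, 0.3, 0.7)) {
    g <- generateLandcover(24, 24, 2001:2022, changeFraction = cf,
                           seed = 13)
    cm <- classifyForestDynamics(g$landcover)
    expect_identical(sfMask(cm), g$sfTruth)
    expect_identical(cfMask(cm), g$cfTruth)
  }
})

test_that("change summaries count areas and normalize per subregion", {
  g <- generateLandcover(20, 20, 2001:2010, changeFraction = 0.4, seed = 2)
  cm <- classifyForestDynamics(g$landcover)
  subr <- matrix(rep(c("W", "E"), each = 200), 20, 20)
  cs <- changeSummary(cm, subregions = subr, pixelArea = 0.25)
  dyn <- cs$dynamics
  all <- dyn[dyn$subregion == "all", ]
  expect_equal(sum(all$proportion), 1)
  expect_equal(all$area, all$count * 0.25)
  expect_identical(sum(all$count[all$class == "CF"]), sum(g$cfTruth))
  for (s in c("W", "E")) {
    expect_equal(sum(dyn$proportion[dyn$subregion == s]), 1)
  }
  # partition additivity: subregion counts sum to the overall counts
  cfCounts <- dyn[dyn$class == "CF", ]
  expect_identical(sum(cfCounts$count[cfCounts$subregion != "all"]),
                   cfCounts$count[cfCounts$subregion == "all"])
  # an all-SF map has CF proportion zero
  g0 <- generateLandcover(16, 16, 2001:2005, changeFraction = 0, seed = 3)
  cs0 <- changeSummary(classifyForestDynamics(g0$landcover))
  expect_false("CF" %in% cs0$dynamics$class)
})
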