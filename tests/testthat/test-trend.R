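test_that("Theil-Sen matches hand-enumerated pairwise medians", {
  expect_equal(theilSenSlope(c(1, 2, 3, 4)), 1.0)
  expect_equal(theilSenSlope(c(5, 5, 5, 5)), 0.0)
  # six pairwise slopes of (1,2,4,3): {1, 1.5, 2/3, 2, 0.5, -1}; median
  expect_equal(theilSenSlope(c(1, 2, 4, 3)), (2 / 3 + 1) / 2)
  expect_error(theilSenSlope(c(1, 2, 3)), "at least 4")
})

test_that("Theil-Sen and MK S match brute-force enumeration exactly", {
  set.seed(20)
  for (r in 1:1000) {
    n <- sample(4:30, 1)
    x <- if (r %% 3 == 0) {
      sample(1:5, n, replace = TRUE)           # heavy ties
    } else {
      rnorm(n)
    }
    expect_identical(theilSenSlope(x), bruteTheilSen(x))
    expect_identical(mannKendall(x)$S, bruteMkS(x))
  }
})

test_that("Theil-Sen is shift-invariant and scale-equivariant", {
  set.seed(4)
  for (r in 1:50) {
    x <- rnorm(15)
    expect_equal(theilSenSlope(x + 100), theilSenSlope(x))
    expect_equal(theilSenSlope(3 * x), 3 * theilSenSlope(x))
  }
})

test_that("MK score, deviate and ties behave per the test's definition", {
  up <- mannKendall(1:5)
  expect_identical(up$S, 10L)                  # all C(5,2) pairs increase
  down <- mannKendall(5:1)
  expect_identical(down$S, -10L)               # antisymmetry
  expect_equal(up$Z, -down$Z)
  tied <- mannKendall(rep(3, 6))
  expect_identical(tied$S, 0L)
  expect_equal(tied$Z, 0)
  expect_equal(tied$p, 1)
  # sign consistency and continuity correction
  x <- c(1, 3, 2, 5, 4, 7)
  mk <- mannKendall(x)
  expect_identical(sign(mk$Z), sign(as.numeric(mk$S)))
  expect_true(mk$p >= 0 && mk$p <= 1)
})

test_that("trend classes follow the slope/significance rule", {
  expect_identical(as.character(classifyTrend(2, 3)),
                   "significant increase")
  expect_identical(as.character(classifyTrend(-0.1, -0.5)),
                   "slight decrease")
  expect_identical(as.character(classifyTrend(0, 0)), "no change")
  expect_identical(as.character(classifyTrend(1, 1.95)), "slight increase")
  expect_identical(as.character(classifyTrend(-1, -2)),
                   "significant decrease")
  # alpha moves the significant/slight boundary
  expect_identical(as.character(classifyTrend(1, 1.7, alpha = 0.1)),
                   "significant increase")
})

test_that("exact linear cubes yield the configured slope at every pixel", {
  nr <- 8; nc <- 8; ny <- 12
  slopes <- matrix(runif(nr * nc, -5, 5), nr, nc)
  arr <- array(0, c(nr, nc, ny))
  for (t in seq_len(ny)) arr[, , t] <- 600 + slopes * t
  cube <- annualCube(arr, 2000 + seq_len(ny), c(0, 1, 0, nr, 0, -1))
  tt <- trendAnalysis(cube)
  expect_equal(nrow(tt), nr * nc)
  got <- matrix(NA_real_, nr, nc)
  got[cbind(tt$row, tt$col)] <- tt$rho
  expect_equal(got, slopes, tolerance = 1e-10)
  dir <- ifelse(slopes > 0, 1, -1)
  gotDir <- matrix(NA_real_, nr, nc)
  gotDir[cbind(tt$row, tt$col)] <- ifelse(grepl("increase", tt$trend_class),
                                          1, -1)
  expect_equal(gotDir, dir)
})

test_that("area proportions match direct counts and partition the map", {
  cl <- matrix(NA_character_, 10, 10)
  cl[1:4, 1] <- "a"; cl[5:10, 1] <- "b"; cl[, 2] <- "c"
  ap <- areaProportions(cl)
  expect_equal(ap$proportion[ap$class == "a"], 4 / 20)
  expect_equal(ap$proportion[ap$class == "c"], 10 / 20)
  expect_equal(sum(ap$proportion), 1)
  # single-class map
  one <- areaProportions(matrix("x", 3, 3))
  expect_equal(one$proportion, 1)
  expect_error(areaProportions(matrix(NA_character_, 2, 2)), "no labeled")
})
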