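test_that("driver tables carry hand-checked multi-year means", {
  sys <- cleanSystem()
  dl <- driverLists(sys)
  mask <- matrix(FALSE, 32, 32)
  mask[cbind(c(3, 10, 20), c(5, 15, 30))] <- TRUE
  tab <- buildDriverTable(sys$npp, dl$climate, dl$terrain, dl$anthro, mask,
                          stratum = "toy", seed = 1)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$Pre[1], mean(gridValues(sys$pre)[3, 5, ]))
  expect_equal(tab$Tem[2], mean(gridValues(sys$tem)[10, 15, ]))
  expect_equal(tab$npp[3], mean(gridValues(sys$npp)[20, 30, ]))
  expect_equal(tab$Ele[1], gridValues(sys$elevation)[3, 5])
  expect_true(all(tab$stratum == "toy"))
  # a pixel outside the mask is absent
  expect_false(any(tab$row == 1 & tab$col == 1))
  expect_error(buildDriverTable(sys$npp, dl$climate, dl$terrain, dl$anthro,
                                matrix(FALSE, 32, 32)), "no pixels")
})

test_that("spatial subsampling under a cap is deterministic in the seed", {
  sys <- cleanSystem()
  dl <- driverLists(sys)
  mask <- matrix(TRUE, 32, 32)
  t1 <- buildDriverTable(sys$npp, dl$climate, dl$terrain, dl$anthro, mask,
                         sampleCap = 100, seed = 9)
  t2 <- buildDriverTable(sys$npp, dl$climate, dl$terrain, dl$anthro, mask,
                         sampleCap = 100, seed = 9)
  expect_identical(t1, t2)
  expect_equal(nrow(t1), 100)
})

test_that("the 70/30 split and holdout metrics are reported", {
  m <- cleanModel()
  n <- nrow(m@table)
  expect_equal(length(m@trainIdx), round(0.7 * n), tolerance = 2)
  expect_equal(length(m@trainIdx) + length(m@testIdx), n)
  expect_gt(m@metrics[["r2"]], 0.9)    # noise-free closed-form response
  expect_true(m@metrics[["rmse"]] > 0)
})

test_that("a permuted response cannot be fitted (negative control)", {
  m <- cleanModel()
  tab <- m@table
  set.seed(31)
  tab$npp <- sample(tab$npp)
  mPerm <- fitRf(tab, budget = 0, seed = 31)
  expect_lt(mPerm@metrics[["r2"]], 0.1)
})

test_that("the Bayesian tuner improves or matches the default CV score", {
  sys <- cleanSystem()
  dl <- driverLists(sys)
  mask <- sys$sfTruth | sys$cfTruth
  tab <- buildDriverTable(sys$npp, dl$climate, dl$terrain, dl$anthro, mask,
                          sampleCap = 500, seed = 21)
  mT <- fitRf(tab, budget = 8, folds = 3, seed = 21)
  expect_equal(nrow(mT@tuning), 8)
  expect_true(all(c("num.trees", "max.depth", "mtry", "min.node.size",
                    "cv_r2") %in% names(mT@tuning)))
  best <- which.max(mT@tuning$cv_r2)
  expect_identical(mT@hyperparams$max.depth,
                   as.integer(mT@tuning$max.depth[best]))
  expect_gt(mT@metrics[["r2"]], 0.7)
})

test_that("SHAP values satisfy additivity and the interaction identities", {
  m <- cleanModel()
  sh <- shapEffects(m, evalCap = 40, seed = 2)
  scale <- mean(abs(sh@predictions))
  addErr <- abs(sh@baseValue + rowSums(shapValues(sh)) - sh@predictions)
  expect_lt(max(addErr) / scale, 1e-6)
  # per-sample phi_i = phi_ii + sum_j phi_ij
  M <- length(m@features)
  for (i in seq_len(M)) {
    rowSum <- apply(sh@interactions[, i, ], 1, sum)
    expect_lt(max(abs(shapValues(sh)[, i] - rowSum)) / scale, 1e-6)
  }
  # symmetry of interactions and of the summary matrix
  for (k in seq_len(nrow(shapValues(sh)))) {
    expect_equal(sh@interactions[k, , ], t(sh@interactions[k, , ]))
  }
  expect_equal(interactionMatrix(sh), t(interactionMatrix(sh)))
  # normalized importances sum to one
  expect_equal(sum(totalImportance(sh)), 1)
  expect_equal(sum(mainImportance(sh)), 1)
  # subset values reproduce the forest prediction exactly
  X <- forestNPP:::encodeFeatures(m@table, m@features)[sh@evalIdx, ]
  pr <- predict(m@forest, data = X, num.threads = 1)$predictions
  expect_equal(sh@predictions, pr, tolerance = 1e-10)
})

test_that("SHAP determinism: same seed, same result", {
  m <- cleanModel()
  a <- shapEffects(m, evalCap = 20, seed = 5)
  b <- shapEffects(m, evalCap = 20, seed = 5)
  expect_identical(shapValues(a), shapValues(b))
  expect_identical(interactionMatrix(a), interactionMatrix(b))
})

test_that("an inert driver gets near-zero importance (negative control)", {
  # aspect does not enter the synthetic response surface
  m <- cleanModel()
  sh <- shapEffects(m, evalCap = 150, seed = 3)
  expect_lt(totalImportance(sh)[["Asp"]], 0.02)
})

test_that("an additive truth yields off-diagonals far below diagonals", {
  sys <- generateStudySystem(
    nrow = 32, ncol = 32, years = 2001:2010, changeFraction = 0,
    truth = syntheticTruth(interAmp = 0, fgnSd = 0, whiteSd = 0,
                           trendSlope = 0),
    seed = 77, noiseSd = list(tem = 0, pre = 0, srad = 0))
  dl <- driverLists(sys)
  tab <- buildDriverTable(sys$npp, dl$climate, dl$terrain, dl$anthro,
                          sys$sfTruth, stratum = "SF", seed = 77)
  m <- fitRf(tab, budget = 0, seed = 77,
             params = list(num.trees = 120, max.depth = 6))
  sh <- shapEffects(m, evalCap = 120, seed = 77)
  im <- interactionMatrix(sh)
  offMax <- max(im[upper.tri(im)])
  diagMax <- max(diag(im))
  expect_lt(offMax, diagMax / 4)
})

test_that("driver ranking is ordered, tie-flagged and order-invariant", {
  m <- cleanModel()
  sh <- shapEffects(m, evalCap = 60, seed = 4)
  rk <- rankDrivers(sh)
  expect_identical(rk$importance, sort(rk$importance, decreasing = TRUE))
  expect_equal(nrow(rk), length(m@features))
  # permuting the table's column order does not change the ranking
  tab2 <- m@table[, rev(names(m@table))]
  m2 <- m
  m2@table <- tab2
  sh2 <- shapEffects(m2, evalCap = 60, seed = 4)
  expect_identical(rankDrivers(sh2)$feature, rk$feature)
  # exact ties are flagged and broken alphabetically
  fake <- sh
  imp <- totalImportance(sh)
  imp[] <- 1 / length(imp)
  fake@totalImportance <- imp
  rkTie <- rankDrivers(fake)
  expect_true(all(rkTie$tied))
  expect_identical(rkTie$feature, sort(names(imp)))
})
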