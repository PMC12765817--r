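# Shared fixtures, built once per test run.

fixtureCache <- new.env(parent = emptyenv())

# small noise-free study system: every response is the exact closed form
cleanSystem <- function() {
  if (is.null(fixtureCache$clean)) {
    fixtureCache$clean <- generateStudySystem(
      nrow = 32, ncol = 32, years = 2001:2022, changeFraction = 0.3,
      truth = syntheticTruth(fgnSd = 0, whiteSd = 0, trendSlope = 0),
      seed = 101, noiseSd = list(tem = 0, pre = 0, srad = 0)
    )
  }
  fixtureCache$clean
}

driverLists <- function(sys) {
  list(
    climate = list(pre = sys$pre, tem = sys$tem, srad = sys$srad),
    terrain = list(elevation = sys$elevation, slope = sys$slope,
                   aspect = sys$aspect),
    anthro = list(ha = sys$ha, age = sys$age, ftype = sys$ftype)
  )
}

# deterministic noise-free driver table + untuned forest on the true NPP
cleanModel <- function() {
  if (is.null(fixtureCache$model)) {
    sys <- cleanSystem()
    dl <- driverLists(sys)
    mask <- sys$sfTruth | sys$cfTruth
    tab <- buildDriverTable(sys$npp, dl$climate, dl$terrain, dl$anthro,
                            mask, stratum = "all", seed = 101)
    fixtureCache$model <- fitRf(tab, budget = 0, seed = 101)
  }
  fixtureCache$model
}

# tiny monthly cube with constant geometry, one year
constantMonthly <- function(value, nr = 4, nc = 4, year = 2001) {
  monthlyCube(array(value, c(nr, nc, 12)), rep(year, 12), 1:12,
              transform = c(0, 1, 0, nr, 0, -1), crs = "local")
}

constantAnnual <- function(value, nr = 4, nc = 4, years = 2001,
                           categorical = FALSE) {
  annualCube(array(value, c(nr, nc, length(years))), years,
             transform = c(0, 1, 0, nr, 0, -1), crs = "local",
             categorical = categorical)
}
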