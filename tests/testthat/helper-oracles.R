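# Independent brute-force oracles used by the trend and acceptance suites.

bruteTheilSen <- function(x) {
  n <- length(x)
  slopes <- c()
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      slopes <- c(slopes, (x[j] - x[i]) / (j - i))
    }
  }
  median(slopes)
}

bruteMkS <- function(x) {
  n <- length(x)
  S <- 0L
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      S <- S + sign(x[j] - x[i])
    }
  }
  as.integer(S)
}
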