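#' Theoretical fractional-Gaussian-noise autocovariance
#'
#' \eqn{\gamma(k) = \sigma^2/2 (|k+1|^{2H} - 2|k|^{2H} + |k-1|^{2H})}.
#'
#' @param k integer lag(s), \eqn{k \ge 0}.
#' @param H Hurst exponent in (0, 1).
#' @param sigma marginal standard deviation.
#' @return Autocovariance at each lag.
#' @export
fgnAutocov <- function(k, H, sigma = 1) {
  k <- abs(k)
  0.5 * sigma^2 * (abs(k + 1)^(2 * H) - 2 * k^(2 * H) + abs(k - 1)^(2 * H))
}

#' Simulate fractional Gaussian noise by circulant embedding
#'
#' Exact simulation via the Davies-Harte construction: the target
#' autocovariance is embedded in a circulant matrix of order \eqn{2n},
#' diagonalized by the FFT, and a complex Gaussian vector is coloured by the
#' square-root eigenvalues. The sample has exactly the fGn covariance for any
#' admissible H (the embedding is nonnegative-definite for H in (0, 1)).
#'
#' @param n series length.
#' @param H Hurst exponent in (0, 1); \code{H = 0.5} gives white noise.
#' @param sigma marginal standard deviation.
#' @return Numeric vector of length \code{n}.
#' @examples
#' x <- rfgn(1024, H = 0.8)
#' @export
rfgn <- function(n, H, sigma = 1) {
  stopifnot(n >= 1, H > 0, H < 1, sigma > 0)
  if (n == 1L) return(stats::rnorm(1, sd = sigma))
  m <- 2L * (n - 1L)
  # first row of the circulant embedding of the Toeplitz covariance
  gamma <- fgnAutocov(0:(n - 1L), H, sigma)
  row1 <- c(gamma, gamma[(n - 1L):2L])
  lambda <- Re(stats::fft(row1))
  lambda[lambda < 0 & lambda > -1e-10] <- 0  # numerical dust
  if (any(lambda < 0)) stop("circulant embedding failed (negative spectrum)")
  z <- complex(
    real = stats::rnorm(m),
    imaginary = stats::rnorm(m)
  )
  # enforce the Hermitian structure that makes the transform real
  z[1] <- complex(real = sqrt(2) * Re(z[1]), imaginary = 0)
  half <- n
  z[half] <- complex(real = sqrt(2) * Re(z[half]), imaginary = 0)
  if (n > 2L) {
    idx <- 2L:(half - 1L)
    z[m + 2L - idx] <- Conj(z[idx])
  }
  w <- sqrt(lambda / (2 * m)) * z
  x <- Re(stats::fft(w))
  x[seq_len(n)]
}
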