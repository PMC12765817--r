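#' @include trend.R
NULL

persistenceLevels <- c("anti-persistent", "random", "persistent")
futureLevels <- c("persistent significant decrease",
                  "persistent slight decrease", "stable",
                  "persistent slight increase",
                  "persistent significant increase",
                  "uncertain", "stochastic")

#' Small-sample expected rescaled range of white noise
#'
#' Anis-Lloyd expectation with the Peters finite-sample factor:
#' \deqn{E[R/S]_m = \frac{m - 1/2}{m}
#'   \frac{\Gamma((m-1)/2)}{\sqrt{\pi}\,\Gamma(m/2)}
#'   \sum_{i=1}^{m-1} \sqrt{(m - i)/i},}
#' with the gamma ratio replaced by its asymptotic form
#' \eqn{(m\pi/2)^{-1/2}} for m > 340 (where the exact ratio overflows).
#' Subtracting its log from the observed log R/S before fitting removes the
#' well-known upward small-sample bias of the classic estimator.
#'
#' @param m window length(s), \code{m >= 2}.
#' @return Expected R/S for an uncorrelated Gaussian series of length m
#'   (R/S computed with the sample standard deviation).
#' @export
expectedRS <- function(m) {
  vapply(m, function(mm) {
    i <- seq_len(mm - 1L)
    front <- if (mm <= 340) {
      exp(lgamma((mm - 1) / 2) - lgamma(mm / 2)) / sqrt(pi)
    } else {
      1 / sqrt(mm * pi / 2)
    }
    (mm - 0.5) / mm * front * sum(sqrt((mm - i) / i))
  }, numeric(1))
}

#' Rescaled-range Hurst exponent
#'
#' Classic R/S analysis: for each window length m in a log-spaced set the
#' series is cut into \code{floor(n/m)} non-overlapping blocks; each block
#' contributes the range of its cumulative mean-deviations divided by its
#' standard deviation, and the block-average R/S is regressed on m in
#' log-log space. With \code{correction = "expected-RS"} (default) the
#' Anis-Lloyd expected statistic is subtracted before fitting and H is the
#' corrected slope offset from 1/2, removing small-sample bias. H is clipped
#' to [0, 1].
#'
#' H < 0.5 marks anti-persistence (future tendency opposite to the past),
#' H = 0.5 an uncorrelated stochastic series, H > 0.5 persistence.
#'
#' @param x numeric series, length >= 8.
#' @param windows integer vector of window lengths; default 4..floor(n/2)
#'   for short series (n < 64) and ~12 log-spaced lengths in [8, n/4]
#'   otherwise.
#' @param correction \code{"expected-RS"} or \code{"none"}.
#' @return List with \code{H}, \code{fit_r2} (R2 of the log-log fit),
#'   \code{small_sample} (TRUE when n < 32, where per-pixel estimates are
#'   intrinsically noisy), \code{windows}. A constant series has an
#'   undefined rescaled range and returns \code{H = NA}.
#' @examples
#' set.seed(1)
#' rsHurst(rnorm(1024))$H  # near 0.5
#' @export
rsHurst <- function(x, windows = NULL,
                    correction = c("expected-RS", "none")) {
  correction <- match.arg(correction)
  n <- length(x)
  if (n < 8L) stop("need at least 8 observations")
  if (anyNA(x)) stop("missing values not allowed; mask upstream")
  if (stats::sd(x) == 0) {
    return(list(H = NA_real_, fit_r2 = NA_real_, small_sample = n < 32L,
                windows = integer()))
  }
  if (is.null(windows)) {
    windows <- if (n < 64L) {
      4:max(4L, n %/% 2L)
    } else {
      unique(round(exp(seq(log(8), log(n / 4), length.out = 12L))))
    }
  }
  windows <- sort(unique(as.integer(windows)))
  windows <- windows[windows >= 2L & windows <= n]
  rs <- vapply(windows, function(m) {
    nb <- n %/% m
    vals <- vapply(seq_len(nb), function(b) {
      seg <- x[((b - 1L) * m + 1L):(b * m)]
      s <- stats::sd(seg)  # sample sd, matching the expectedRS() convention
      if (s == 0) return(NA_real_)
      cum <- cumsum(seg - mean(seg))
      (max(cum) - min(cum)) / s
    }, numeric(1))
    mean(vals, na.rm = TRUE)
  }, numeric(1))
  ok <- is.finite(rs) & rs > 0
  if (sum(ok) < 3L) {
    return(list(H = NA_real_, fit_r2 = NA_real_, small_sample = n < 32L,
                windows = windows))
  }
  lm0 <- stats::lm(log(rs[ok]) ~ log(windows[ok]))
  fitR2 <- summary(lm0)$r.squared
  H <- if (correction == "expected-RS") {
    dev <- log(rs[ok]) - log(expectedRS(windows[ok]))
    0.5 + unname(stats::coef(stats::lm(dev ~ log(windows[ok])))[2])
  } else {
    unname(stats::coef(lm0)[2])
  }
  list(H = min(max(H, 0), 1), fit_r2 = fitR2, small_sample = n < 32L,
       windows = windows)
}

#' Persistence class from a Hurst exponent
#'
#' \eqn{H \in [0, 0.5)} anti-persistent (future trend opposite to the
#' current), \eqn{H = 0.5} random (unsustainable stochastic fluctuation),
#' \eqn{H \in (0.5, 1]} persistent (future consistent with the current).
#'
#' @param H Hurst exponent(s) in [0, 1]; NA propagates.
#' @return Factor with levels anti-persistent, random, persistent.
#' @export
classifyPersistence <- function(H) {
  out <- ifelse(is.na(H), NA_character_,
                ifelse(H < 0.5, "anti-persistent",
                       ifelse(H > 0.5, "persistent", "random")))
  factor(out, levels = persistenceLevels)
}

#' Superpose trend and persistence into a future-trend class
#'
#' Persistent pixels keep their current direction (significant/slight
#' preserved; a persistent "no change" is "stable"); anti-persistent pixels
#' are labeled "uncertain" (likely reversal, direction unknown); random
#' pixels are "stochastic".
#'
#' @param trendClass factor/character from \code{\link{classifyTrend}}.
#' @param persistenceClass factor/character from
#'   \code{\link{classifyPersistence}}; recycled against \code{trendClass}.
#' @return Factor over the 7 future classes.
#' @export
superposeFuture <- function(trendClass, persistenceClass) {
  tc <- as.character(trendClass)
  pc <- as.character(persistenceClass)
  n <- max(length(tc), length(pc))
  tc <- rep_len(tc, n); pc <- rep_len(pc, n)
  out <- rep(NA_character_, n)
  out[pc == "random"] <- "stochastic"
  out[pc == "anti-persistent"] <- "uncertain"
  per <- which(pc == "persistent")
  out[per] <- ifelse(tc[per] == "no change", "stable",
                     paste("persistent", tc[per]))
  factor(out, levels = futureLevels)
}

#' Per-pixel Hurst / persistence analysis of an annual cube
#'
#' @param cube an \linkS4class{AnnualCube}.
#' @param mask optional logical matrix restricting the analysed pixels.
#' @param windows,correction passed to \code{\link{rsHurst}}.
#' @return data.frame with \code{row}, \code{col}, \code{H}, \code{fit_r2},
#'   \code{persistence_class}. Per-pixel series of ~22 points sit in the
#'   small-sample regime; \code{fit_r2} lets users mask unreliable pixels.
#' @export
hurstAnalysis <- function(cube, mask = NULL, windows = NULL,
                          correction = "expected-RS") {
  d <- dim(cube)
  idx <- which(if (is.null(mask)) matrix(TRUE, d[1], d[2]) else mask)
  flat <- matrix(gridValues(cube), d[1] * d[2], d[3])
  keep <- idx[rowSums(is.na(flat[idx, , drop = FALSE])) == 0L]
  res <- vapply(keep, function(i) {
    h <- rsHurst(flat[i, ], windows = windows, correction = correction)
    c(h$H, h$fit_r2)
  }, numeric(2))
  rc <- arrayInd(keep, d[1:2])
  data.frame(
    row = rc[, 1], col = rc[, 2],
    H = res[1, ], fit_r2 = res[2, ],
    persistence_class = classifyPersistence(res[1, ])
  )
}

#' Combine per-pixel trend and Hurst tables into future-trend classes
#'
#' @param trendTable output of \code{\link{trendAnalysis}}.
#' @param hurstTable output of \code{\link{hurstAnalysis}}.
#' @return The merged table with a \code{future_class} column.
#' @export
futureTrend <- function(trendTable, hurstTable) {
  m <- merge(trendTable, hurstTable, by = c("row", "col"))
  m$future_class <- superposeFuture(m$trend_class, m$persistence_class)
  m
}
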