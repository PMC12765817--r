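#' @include methods.R
NULL

trendLevels <- c("significant decrease", "slight decrease", "no change",
                 "slight increase", "significant increase")

#' Theil-Sen slope of a time series
#'
#' Median of all \eqn{n(n-1)/2} pairwise slopes
#' \eqn{(x_j - x_i)/(j - i)}, \eqn{i < j}, a trend-magnitude estimator robust
#' to outliers. Even pair counts take the midpoint of the two central values
#' (the usual sample median).
#'
#' @param x numeric series in time order (indices are the time axis; for
#'   annual NPP the slope is in gC m-2 a-2).
#' @param t optional numeric time points; defaults to \code{1:length(x)}.
#' @return The median pairwise slope.
#' @examples
#' theilSenSlope(c(1, 2, 4, 3))  # median of the 6 pairwise slopes
#' @export
theilSenSlope <- function(x, t = seq_along(x)) {
  if (length(x) < 4L) stop("need at least 4 observations")
  if (anyNA(x)) stop("missing values not allowed; mask upstream")
  dx <- outer(x, x, "-")
  dt <- outer(t, t, "-")
  lower <- lower.tri(dx)
  stats::median(dx[lower] / dt[lower])
}

#' Mann-Kendall trend test
#'
#' Nonparametric rank-based test for monotone trend: score
#' \eqn{S = \sum_{i<j} \mathrm{sign}(x_j - x_i)}, tie-corrected variance
#' \eqn{\mathrm{Var}(S) = [n(n-1)(2n+5) - \sum_t t(t-1)(2t+5)]/18}, and the
#' continuity-corrected deviate \eqn{Z = (S \mp 1)/\sqrt{\mathrm{Var}(S)}}
#' (\eqn{Z = 0} when \eqn{S = 0}) with a two-sided normal p-value. A fully
#' tied series yields \eqn{S = 0}, \eqn{Z = 0}, \eqn{p = 1}.
#'
#' @param x numeric series in time order, length >= 4.
#' @return List with \code{S}, \code{Z}, \code{p}.
#' @examples
#' mannKendall(1:5)$S  # 10: all C(5,2) pairs increase
#' @export
mannKendall <- function(x) {
  n <- length(x)
  if (n < 4L) stop("need at least 4 observations")
  if (anyNA(x)) stop("missing values not allowed; mask upstream")
  d <- sign(outer(x, x, "-"))
  S <- sum(d[lower.tri(d)])  # entries (r, c), r > c: sign(x_r - x_c)
  ties <- table(x)
  ties <- ties[ties > 1L]
  varS <- (n * (n - 1) * (2 * n + 5) -
             sum(ties * (ties - 1) * (2 * ties + 5))) / 18
  if (varS <= 0 || S == 0L) {
    Z <- 0
  } else {
    Z <- (S - sign(S)) / sqrt(varS)
  }
  p <- if (Z == 0 && S == 0 && varS <= 0) 1 else 2 * stats::pnorm(-abs(Z))
  list(S = as.integer(S), Z = Z, p = p)
}

#' Classify a trend from its Theil-Sen slope and Mann-Kendall deviate
#'
#' Five classes: increasing/decreasing split into significant
#' (\eqn{|Z| \ge z_{1-\alpha/2}}) and slight, plus "no change" for an exactly
#' zero slope.
#'
#' @param rho Theil-Sen slope(s).
#' @param Z Mann-Kendall deviate(s), recycled against \code{rho}.
#' @param alpha two-sided significance level (default 0.05, i.e.
#'   \eqn{|Z| \ge 1.96}).
#' @return Factor with levels significant decrease < slight decrease <
#'   no change < slight increase < significant increase.
#' @export
classifyTrend <- function(rho, Z, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  zcrit <- stats::qnorm(1 - alpha / 2)
  sig <- abs(Z) >= zcrit
  out <- ifelse(rho > 0, ifelse(sig, "significant increase",
                                "slight increase"),
                ifelse(rho < 0, ifelse(sig, "significant decrease",
                                       "slight decrease"),
                       "no change"))
  factor(out, levels = trendLevels)
}

#' Per-pixel trend analysis of an annual cube
#'
#' Applies \code{\link{theilSenSlope}}, \code{\link{mannKendall}} and
#' \code{\link{classifyTrend}} to every pixel with a complete series.
#'
#' @param cube an \linkS4class{AnnualCube} (e.g. annual NPP).
#' @param alpha significance level for the significant/slight split.
#' @param mask optional logical matrix restricting the analysed pixels.
#' @return data.frame with columns \code{row}, \code{col}, \code{rho},
#'   \code{S}, \code{Z}, \code{p}, \code{trend_class}.
#' @export
trendAnalysis <- function(cube, alpha = 0.05, mask = NULL) {
  d <- dim(cube)
  idx <- which(if (is.null(mask)) matrix(TRUE, d[1], d[2]) else mask)
  arr <- gridValues(cube)
  flat <- matrix(arr, d[1] * d[2], d[3])
  keep <- idx[rowSums(is.na(flat[idx, , drop = FALSE])) == 0L]
  res <- vapply(keep, function(i) {
    x <- flat[i, ]
    mk <- mannKendall(x)
    c(theilSenSlope(x), mk$S, mk$Z, mk$p)
  }, numeric(4))
  rc <- arrayInd(keep, d[1:2])
  data.frame(
    row = rc[, 1], col = rc[, 2],
    rho = res[1, ], S = as.integer(res[2, ]), Z = res[3, ], p = res[4, ],
    trend_class = classifyTrend(res[1, ], res[3, ], alpha)
  )
}

#' Area shares of a class map
#'
#' Pixel-count shares of each class over the masked area, overall
#' (\code{subregion = "all"}) and per subregion label when one is supplied.
#' Shares sum to 1 within each subregion.
#'
#' @param classes factor/character/integer matrix of per-pixel class labels
#'   (\code{NA} = unlabeled), or a data.frame with \code{row}, \code{col} and
#'   a class column named by \code{classCol}.
#' @param mask optional logical matrix restricting the tally.
#' @param subregions optional \linkS4class{RasterGrid} or matrix of subregion
#'   labels.
#' @param pixelArea area of one pixel (any unit); areas are
#'   \code{count * pixelArea}.
#' @param classCol class column name when \code{classes} is a data.frame.
#' @param dims matrix dimensions when \code{classes} is a data.frame.
#' @return data.frame with \code{subregion}, \code{class}, \code{count},
#'   \code{area}, \code{proportion}.
#' @export
areaProportions <- function(classes, mask = NULL, subregions = NULL,
                            pixelArea = 1, classCol = "trend_class",
                            dims = NULL) {
  if (is.data.frame(classes)) {
    if (is.null(dims)) stop("'dims' required with a data.frame input")
    m <- matrix(NA_character_, dims[1], dims[2])
    m[cbind(classes$row, classes$col)] <- as.character(classes[[classCol]])
    classes <- m
  }
  cl <- as.character(classes)
  dim(cl) <- dim(classes)
  if (!is.null(mask)) cl[!mask] <- NA_character_
  if (is(subregions, "RasterGrid")) subregions <- gridValues(subregions)
  ok <- !is.na(cl)
  if (!any(ok)) stop("no labeled pixels under the mask")
  tallyOne <- function(sel, name) {
    tab <- table(cl[sel])
    data.frame(subregion = name, class = names(tab),
               count = as.integer(tab),
               area = as.integer(tab) * pixelArea,
               proportion = as.integer(tab) / sum(tab))
  }
  out <- tallyOne(ok, "all")
  if (!is.null(subregions)) {
    for (s in sort(unique(subregions[ok]))) {
      out <- rbind(out, tallyOne(ok & subregions == s, as.character(s)))
    }
  }
  rownames(out) <- NULL
  out
}
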