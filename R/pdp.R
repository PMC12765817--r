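#' @include attribution.R
NULL

#' Partial dependence of the fitted model on one feature
#'
#' Mean model prediction as the feature is swept across a quantile-spaced
#' grid between its 1st and 99th percentile, every other column held at its
#' observed values. Each grid point carries a data-density weight (fraction
#' of observations nearest to it); points below \code{densityFloor} are
#' flagged sparse and excluded from threshold detection, since trend lines
#' in sparse regions are unreliable.
#'
#' @param model an \linkS4class{AttributionModel}.
#' @param feature feature name (one of the driver columns).
#' @param nGrid number of grid points (default 30).
#' @param densityFloor sparse-flag threshold on the density weight
#'   (default 0.01).
#' @return List of class \code{"PDPCurve"}: \code{feature}, \code{grid}
#'   (strictly increasing), \code{pd} (gC m-2 a-1), \code{density},
#'   \code{sparse}.
#' @export
partialDependence <- function(model, feature, nGrid = 30,
                              densityFloor = 0.01) {
  X <- encodeFeatures(model@table, model@features)
  if (feature %in% colnames(X)) {
    x <- X[[feature]]
  } else if (feature %in% names(model@table)) {
    # a table column the model was fitted without: the curve is exactly flat
    x <- encodeFeatures(model@table, feature)[[1]]
  } else {
    stop("unknown feature: ", feature)
  }
  if (stats::sd(x) == 0) stop("feature '", feature, "' is constant")
  # type-1 quantiles are a function of the empirical CDF alone, so the grid
  # is invariant under row duplication
  qs <- stats::quantile(x, probs = seq(0.01, 0.99, length.out = nGrid),
                        names = FALSE, type = 1)
  grid <- sort(unique(qs))
  pd <- vapply(grid, function(g) {
    Xg <- X
    Xg[[feature]] <- g
    mean(stats::predict(model@forest, data = Xg,
                        num.threads = 1)$predictions)
  }, numeric(1))
  nearest <- vapply(x, function(v) which.min(abs(grid - v)), integer(1))
  density <- tabulate(nearest, nbins = length(grid)) / length(x)
  structure(
    list(feature = feature, grid = grid, pd = pd, density = density,
         sparse = density < densityFloor),
    class = "PDPCurve"
  )
}

#' @export
print.PDPCurve <- function(x, ...) {
  cat("PDPCurve for ", x$feature, ": ", length(x$grid), " grid points in [",
      signif(min(x$grid), 4), ", ", signif(max(x$grid), 4), "], ",
      sum(x$sparse), " sparse\n", sep = "")
  invisible(x)
}

movingAverage <- function(y, window) {
  n <- length(y)
  half <- window %/% 2
  vapply(seq_len(n), function(i) {
    mean(y[max(1, i - half):min(n, i + half)])
  }, numeric(1))
}

#' Extract response thresholds from a partial-dependence curve
#'
#' Works on the unflagged (dense) grid points only: the PD values are
#' smoothed with a fixed-window moving average; consecutive grid segments
#' are classified as increasing / flat / decreasing by comparing the
#' smoothed slope with a flatness band (\code{flatFrac} of the response
#' range per unit of the feature range); boundaries between differing
#' direction regimes are reported as breakpoints, and the optimum interval
#' is the contiguous grid region within \code{delta} of the smoothed
#' maximum (range-relative). A flat curve yields no breakpoints and no
#' optimum.
#'
#' @param curve a \code{PDPCurve} from \code{\link{partialDependence}}.
#' @param smoothWindow moving-average window in grid points (default 5).
#' @param delta optimum-interval tolerance as a fraction of the smoothed
#'   response range (default 0.05).
#' @param flatFrac flatness band as a fraction of response range per
#'   feature range (default 0.05).
#' @return List: \code{optimum} (c(lo, hi) or NULL), \code{breakpoints}
#'   (data.frame value/from/to), \code{directions} (data.frame
#'   start/end/direction), \code{smoothed}, \code{grid}.
#' @export
extractThresholds <- function(curve, smoothWindow = 5, delta = 0.05,
                              flatFrac = 0.05) {
  keep <- !curve$sparse
  if (sum(keep) < 10) stop("need at least 10 unflagged grid points")
  g <- curve$grid[keep]
  sm <- movingAverage(curve$pd[keep], smoothWindow)
  rng <- max(sm) - min(sm)
  if (rng <= .Machine$double.eps * max(1, abs(max(sm)))) {
    return(list(optimum = NULL,
                breakpoints = data.frame(value = numeric(),
                                         from = character(),
                                         to = character()),
                directions = data.frame(start = min(g), end = max(g),
                                        direction = "flat"),
                smoothed = sm, grid = g))
  }
  slope <- diff(sm) / diff(g)
  eps <- flatFrac * rng / (max(g) - min(g))
  dir <- ifelse(slope > eps, "increasing",
                ifelse(slope < -eps, "decreasing", "flat"))
  runs <- rle(dir)
  ends <- cumsum(runs$lengths)
  starts <- c(1, utils::head(ends, -1) + 1)
  directions <- data.frame(
    start = g[starts], end = g[ends + 1],
    direction = runs$values, stringsAsFactors = FALSE
  )
  breakpoints <- if (length(runs$values) > 1) {
    data.frame(
      value = g[ends[-length(ends)] + 1],
      from = runs$values[-length(runs$values)],
      to = runs$values[-1],
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(value = numeric(), from = character(), to = character())
  }
  inOpt <- sm >= max(sm) - delta * rng
  # contiguous region containing the argmax
  k <- which.max(sm)
  lo <- k; while (lo > 1 && inOpt[lo - 1]) lo <- lo - 1
  hi <- k; while (hi < length(sm) && inOpt[hi + 1]) hi <- hi + 1
  list(optimum = c(g[lo], g[hi]), breakpoints = breakpoints,
       directions = directions, smoothed = sm, grid = g)
}
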