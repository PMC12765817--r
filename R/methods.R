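#' @include AllGenerics.R
NULL

#' @rdname raster-accessors
setMethod("gridValues", "RasterGrid", function(x) x@values)
#' @rdname raster-accessors
setMethod("gridValues", "AnnualCube", function(x) x@data)
#' @rdname raster-accessors
setMethod("gridValues", "MonthlyCube", function(x) x@data)

#' @rdname raster-accessors
setMethod("nodataMask", "RasterGrid", function(x) is.na(x@values))

#' @rdname raster-accessors
setMethod("gridTransform", "RasterGrid", function(x) x@transform)
#' @rdname raster-accessors
setMethod("gridTransform", "AnnualCube", function(x) x@transform)
#' @rdname raster-accessors
setMethod("gridTransform", "MonthlyCube", function(x) x@transform)

#' @rdname raster-accessors
setMethod("gridCrs", "RasterGrid", function(x) x@crs)
#' @rdname raster-accessors
setMethod("gridCrs", "AnnualCube", function(x) x@crs)
#' @rdname raster-accessors
setMethod("gridCrs", "MonthlyCube", function(x) x@crs)

#' @rdname raster-accessors
setMethod("isCategorical", "RasterGrid", function(x) x@categorical)
#' @rdname raster-accessors
setMethod("isCategorical", "AnnualCube", function(x) x@categorical)

#' @rdname raster-accessors
setMethod("cubeYears", "AnnualCube", function(x) x@years)
#' @rdname raster-accessors
setMethod("cubeYears", "MonthlyCube", function(x) x@years)
#' @rdname raster-accessors
setMethod("cubeMonths", "MonthlyCube", function(x) x@months)

#' @describeIn RasterGrid dimensions of the value matrix.
#' @param x a RasterGrid.
#' @export
setMethod("dim", "RasterGrid", function(x) dim(x@values))
#' @describeIn AnnualCube dimensions (row, col, year).
#' @param x an AnnualCube.
#' @export
setMethod("dim", "AnnualCube", function(x) dim(x@data))
#' @describeIn MonthlyCube dimensions (row, col, time).
#' @param x a MonthlyCube.
#' @export
setMethod("dim", "MonthlyCube", function(x) dim(x@data))

setMethod("getGrid", "AnnualCube", function(x, year, month) {
  k <- match(as.integer(year), x@years)
  if (is.na(k)) stop("year ", year, " not present in cube")
  RasterGrid(x@data[, , k, drop = TRUE], transform = x@transform,
             crs = x@crs, categorical = x@categorical)
})

setMethod("getGrid", "MonthlyCube", function(x, year, month) {
  k <- which(x@years == as.integer(year) & x@months == as.integer(month))
  if (length(k) != 1L) stop("layer (", year, ", ", month, ") not in cube")
  RasterGrid(x@data[, , k, drop = TRUE], transform = x@transform, crs = x@crs)
})

setMethod("changeCode", "ChangeMap", function(x) x@code)
setMethod("sfMask", "ChangeMap", function(x) x@sfMask)
setMethod("cfMask", "ChangeMap", function(x) x@cfMask)
setMethod("changeLegend", "ChangeMap", function(x) x@legend)

setMethod("totalImportance", "AttributionResult", function(x) x@totalImportance)
setMethod("mainImportance", "AttributionResult", function(x) x@mainImportance)
setMethod("interactionMatrix", "AttributionResult",
          function(x) x@interactionMatrix)
setMethod("shapValues", "AttributionResult", function(x) x@shap)

setMethod("show", "RasterGrid", function(object) {
  d <- dim(object@values)
  nNA <- sum(is.na(object@values))
  cat("RasterGrid ", d[1], " x ", d[2],
      if (object@categorical) " (categorical)" else "", "\n", sep = "")
  cat("  crs: ", object@crs, "\n", sep = "")
  cat("  pixel: ", object@transform[2], " x ", abs(object@transform[6]),
      ", origin (", object@transform[1], ", ", object@transform[4], ")\n",
      sep = "")
  rng <- suppressWarnings(range(object@values, na.rm = TRUE))
  cat("  values: [", signif(rng[1], 6), ", ", signif(rng[2], 6), "], ",
      nNA, " nodata cells\n", sep = "")
  invisible(NULL)
})

setMethod("show", "AnnualCube", function(object) {
  d <- dim(object@data)
  cat("AnnualCube ", d[1], " x ", d[2], " x ", d[3], " years (",
      min(object@years), "-", max(object@years), ")",
      if (object@categorical) " [categorical]" else "", "\n", sep = "")
  invisible(NULL)
})

setMethod("show", "MonthlyCube", function(object) {
  d <- dim(object@data)
  cat("MonthlyCube ", d[1], " x ", d[2], " x ", d[3], " layers (",
      min(object@years), "-", max(object@years), ", monthly)\n", sep = "")
  invisible(NULL)
})

setMethod("show", "ChangeMap", function(object) {
  cat("ChangeMap ", nrow(object@code), " x ", ncol(object@code), "\n",
      sep = "")
  cat("  stable forest: ", sum(object@sfMask), " px; changing forest: ",
      sum(object@cfMask), " px; unlabeled: ",
      sum(!object@sfMask & !object@cfMask), " px\n", sep = "")
  invisible(NULL)
})

setMethod("show", "AttributionModel", function(object) {
  cat("AttributionModel (random forest, ", length(object@trainIdx),
      " train / ", length(object@testIdx), " test rows)\n", sep = "")
  cat("  holdout R2 = ", round(object@metrics[["r2"]], 3),
      ", RMSE = ", round(object@metrics[["rmse"]], 2), "\n", sep = "")
  hp <- object@hyperparams
  cat("  trees = ", hp$num.trees, ", depth = ", hp$max.depth,
      ", mtry = ", hp$mtry, ", min node = ", hp$min.node.size, "\n", sep = "")
  invisible(NULL)
})

setMethod("show", "AttributionResult", function(object) {
  cat("AttributionResult: ", nrow(object@shap), " samples x ",
      ncol(object@shap), " features\n", sep = "")
  imp <- sort(object@totalImportance, decreasing = TRUE)
  cat("  top drivers (total): ",
      paste(names(imp)[seq_len(min(3, length(imp)))], collapse = ", "),
      "\n", sep = "")
  invisible(NULL)
})

# shared-geometry check used across the pipeline: misalignment is an error,
# never silent resampling
sameGeometry <- function(a, b, tol = 1e-9) {
  da <- dim(gridValues(a)); db <- dim(gridValues(b))
  identical(da[1:2], db[1:2]) &&
    all(abs(gridTransform(a) - gridTransform(b)) <= tol) &&
    identical(gridCrs(a), gridCrs(b))
}

stopIfMisaligned <- function(..., what = "inputs") {
  objs <- list(...)
  for (k in seq_along(objs)[-1]) {
    if (!sameGeometry(objs[[1]], objs[[k]])) {
      stop(what, " are not geometry-aligned; align explicitly with ",
           "alignToTemplate() first", call. = FALSE)
    }
  }
  invisible(TRUE)
}
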