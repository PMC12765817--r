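#' @useDynLib forestNPP, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
NULL

#' RasterGrid: a single georeferenced 2-D field
#'
#' Container for one raster band: a numeric matrix of cell values (with
#' \code{NA} marking nodata cells), a six-number affine geotransform in GDAL
#' order \code{c(x0, dx, rx, y0, ry, dy)} mapping (col, row) pixel indices to
#' map coordinates, and a CRS identifier. Pixel-is-area convention with the
#' origin at the upper-left corner; \code{values[1, 1]} is the north-west cell.
#'
#' @slot values numeric matrix of cell values; \code{NA} encodes nodata.
#' @slot transform numeric(6) affine geotransform; \code{dx > 0}, \code{dy < 0}.
#' @slot crs single character CRS identifier (free text, e.g. WKT or an
#'   EPSG tag); never empty.
#' @slot categorical logical flag: \code{TRUE} for integer-coded class grids,
#'   which may only be resampled with nearest-neighbour.
#' @export
setClass("RasterGrid",
  representation(
    values = "matrix",
    transform = "numeric",
    crs = "character",
    categorical = "logical"
  ),
  prototype(
    transform = c(0, 1, 0, 0, 0, -1),
    crs = "local",
    categorical = FALSE
  )
)

setValidity("RasterGrid", function(object) {
  msg <- character()
  if (!is.numeric(object@values)) {
    msg <- c(msg, "'values' must be a numeric matrix")
  }
  if (length(object@transform) != 6L) {
    msg <- c(msg, "'transform' must have 6 elements (x0, dx, rx, y0, ry, dy)")
  } else {
    if (!(object@transform[2] > 0)) msg <- c(msg, "pixel width dx must be > 0")
    if (!(object@transform[6] < 0)) msg <- c(msg, "pixel height dy must be < 0")
  }
  if (length(object@crs) != 1L || is.na(object@crs) || !nzchar(object@crs)) {
    msg <- c(msg, "'crs' must be a non-empty character scalar")
  }
  if (length(object@categorical) != 1L || is.na(object@categorical)) {
    msg <- c(msg, "'categorical' must be TRUE or FALSE")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a RasterGrid
#'
#' @param values numeric matrix (\code{NA} = nodata).
#' @param transform numeric(6) affine geotransform \code{c(x0, dx, rx, y0,
#'   ry, dy)}; the default places the grid at the origin with unit pixels.
#' @param crs CRS identifier string.
#' @param categorical logical; mark integer-coded class grids so that
#'   bilinear resampling is refused for them.
#' @return A \linkS4class{RasterGrid}.
#' @examples
#' g <- RasterGrid(matrix(1:12, 3, 4))
#' dim(g)
#' @export
RasterGrid <- function(values,
                       transform = c(0, 1, 0, nrow(values), 0, -1),
                       crs = "local",
                       categorical = FALSE) {
  storage.mode(values) <- "double"
  new("RasterGrid", values = values, transform = as.numeric(transform),
      crs = as.character(crs), categorical = isTRUE(categorical))
}

#' AnnualCube: a stack of annual RasterGrids
#'
#' Time-ordered stack of co-registered rasters, one layer per calendar year,
#' stored as a \code{nrow x ncol x nyear} array.
#'
#' @slot data 3-D numeric array (row, col, year); \code{NA} = nodata.
#' @slot years strictly increasing integer vector, one per layer.
#' @slot transform,crs,categorical shared geometry, as in
#'   \linkS4class{RasterGrid}.
#' @export
setClass("AnnualCube",
  representation(
    data = "array",
    years = "integer",
    transform = "numeric",
    crs = "character",
    categorical = "logical"
  ),
  prototype(transform = c(0, 1, 0, 0, 0, -1), crs = "local",
            categorical = FALSE)
)

setValidity("AnnualCube", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 3L) {
    msg <- c(msg, "'data' must be a 3-D array (row, col, year)")
  } else if (dim(object@data)[3] != length(object@years)) {
    msg <- c(msg, "third dimension of 'data' must match length(years)")
  }
  if (length(object@years) && any(diff(object@years) <= 0)) {
    msg <- c(msg, "'years' must be strictly increasing")
  }
  if (length(object@transform) != 6L) {
    msg <- c(msg, "'transform' must have 6 elements")
  }
  if (length(msg)) msg else TRUE
})

#' MonthlyCube: a stack of monthly RasterGrids
#'
#' Layers keyed by (year, month); every included year carries all 12 months,
#' in calendar order.
#'
#' @slot data 3-D numeric array (row, col, time).
#' @slot years integer vector, one entry per layer.
#' @slot months integer vector in 1..12, one entry per layer.
#' @slot transform,crs shared geometry.
#' @export
setClass("MonthlyCube",
  representation(
    data = "array",
    years = "integer",
    months = "integer",
    transform = "numeric",
    crs = "character"
  ),
  prototype(transform = c(0, 1, 0, 0, 0, -1), crs = "local")
)

setValidity("MonthlyCube", function(object) {
  msg <- character()
  d <- dim(object@data)
  if (length(d) != 3L) {
    msg <- c(msg, "'data' must be a 3-D array (row, col, time)")
  } else if (d[3] != length(object@years) || d[3] != length(object@months)) {
    msg <- c(msg, "'years'/'months' must each match the time dimension")
  }
  if (length(object@months) && any(object@months < 1L | object@months > 12L)) {
    msg <- c(msg, "'months' must lie in 1..12")
  }
  if (length(object@years)) {
    tab <- table(object@years)
    if (any(tab != 12L)) {
      msg <- c(msg, "every included year must carry exactly 12 months")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct an AnnualCube
#'
#' @param data 3-D array (row, col, year) or list of matrices.
#' @param years integer vector of calendar years.
#' @param transform,crs,categorical geometry metadata; see
#'   \linkS4class{RasterGrid}.
#' @return An \linkS4class{AnnualCube}.
#' @export
annualCube <- function(data, years,
                       transform = c(0, 1, 0, dim(data)[1], 0, -1),
                       crs = "local", categorical = FALSE) {
  if (is.list(data)) data <- simplify2array(data)
  storage.mode(data) <- "double"
  new("AnnualCube", data = data, years = as.integer(years),
      transform = as.numeric(transform), crs = as.character(crs),
      categorical = isTRUE(categorical))
}

#' Construct a MonthlyCube
#'
#' @param data 3-D array (row, col, time) with time running
#'   year-major, month-minor.
#' @param years,months integer vectors keying each layer.
#' @param transform,crs geometry metadata.
#' @return A \linkS4class{MonthlyCube}.
#' @export
monthlyCube <- function(data, years, months,
                        transform = c(0, 1, 0, dim(data)[1], 0, -1),
                        crs = "local") {
  if (is.list(data)) data <- simplify2array(data)
  storage.mode(data) <- "double"
  new("MonthlyCube", data = data, years = as.integer(years),
      months = as.integer(months), transform = as.numeric(transform),
      crs = as.character(crs))
}

#' ChangeMap: tupu-coded land-cover change with SF/CF labels
#'
#' Per-pixel two-digit change code \eqn{C = 10A + B} built from the remapped
#' first-year class A and last-year class B, together with stable-forest (SF)
#' and changing-forest (CF) masks and a legend decoding every code.
#'
#' @slot code integer matrix of change codes; \code{NA} where the pixel was
#'   never forest (unlabeled).
#' @slot sfMask,cfMask logical matrices; mutually exclusive.
#' @slot legend data.frame with columns \code{code}, \code{from}, \code{to}.
#' @slot transform,crs geometry metadata.
#' @export
setClass("ChangeMap",
  representation(
    code = "matrix",
    sfMask = "matrix",
    cfMask = "matrix",
    legend = "data.frame",
    transform = "numeric",
    crs = "character"
  )
)

setValidity("ChangeMap", function(object) {
  msg <- character()
  if (!identical(dim(object@code), dim(object@sfMask)) ||
      !identical(dim(object@code), dim(object@cfMask))) {
    msg <- c(msg, "code/sfMask/cfMask must share one shape")
  }
  if (any(object@sfMask & object@cfMask, na.rm = TRUE)) {
    msg <- c(msg, "a pixel cannot be both stable and changing forest")
  }
  if (!all(c("code", "from", "to") %in% names(object@legend))) {
    msg <- c(msg, "legend must have columns code, from, to")
  }
  if (anyDuplicated(object@legend$code)) {
    msg <- c(msg, "legend codes must be unique")
  }
  if (length(msg)) msg else TRUE
})

#' AttributionModel: a fitted, tuned random-forest regression
#'
#' Wraps the fitted forest together with the driver table, the 70/30 split,
#' holdout metrics and the tuning trace so that downstream SHAP and
#' partial-dependence computations are fully reproducible.
#'
#' @slot forest the fitted \code{ranger} object.
#' @slot table driver table (data.frame) the model was fitted on, with the
#'   encoded feature columns actually passed to the forest.
#' @slot features character vector of feature column names.
#' @slot response name of the response column.
#' @slot trainIdx,testIdx integer row indices of the 70/30 split.
#' @slot metrics named numeric: holdout \code{r2}, \code{rmse}, \code{n_train},
#'   \code{n_test}.
#' @slot hyperparams named list of the selected hyperparameters.
#' @slot tuning data.frame trace of the tuner (one row per evaluation), or an
#'   empty data.frame when tuning was skipped.
#' @slot seed integer seed that fixed split, search and forest.
#' @export
setClass("AttributionModel",
  representation(
    forest = "ANY",
    table = "data.frame",
    features = "character",
    response = "character",
    trainIdx = "integer",
    testIdx = "integer",
    metrics = "numeric",
    hyperparams = "list",
    tuning = "data.frame",
    seed = "integer"
  )
)

#' AttributionResult: SHAP decomposition of a fitted model
#'
#' Exact path-dependent tree-Shapley decomposition on a seeded evaluation
#' subsample: per-sample total SHAP values, the symmetric interaction-value
#' array, normalized total/main importances and the mean absolute pairwise
#' interaction matrix.
#'
#' @slot shap numeric matrix (samples x features) of SHAP values.
#' @slot interactions numeric array (samples x features x features) of SHAP
#'   interaction values; symmetric in the feature dimensions.
#' @slot baseValue numeric(1): path-dependent expectation of the forest.
#' @slot predictions numeric vector of forest predictions on the evaluated
#'   samples.
#' @slot totalImportance named numeric, normalized mean |SHAP| (sums to 1).
#' @slot mainImportance named numeric, normalized mean |diagonal interaction|.
#' @slot interactionMatrix symmetric feature x feature mean |off-diagonal|
#'   matrix (diagonal carries the mean |main effect| for reference).
#' @slot evalIdx integer row indices (into the model table) that were
#'   evaluated.
#' @export
setClass("AttributionResult",
  representation(
    shap = "matrix",
    interactions = "array",
    baseValue = "numeric",
    predictions = "numeric",
    totalImportance = "numeric",
    mainImportance = "numeric",
    interactionMatrix = "matrix",
    evalIdx = "integer"
  )
)
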