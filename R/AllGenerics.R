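#' @include AllClasses.R
NULL

#' Accessors for raster containers
#'
#' \code{gridValues} returns the value matrix/array, \code{nodataMask} the
#' logical nodata mask, \code{gridTransform} the affine geotransform,
#' \code{gridCrs} the CRS string, \code{isCategorical} the categorical flag,
#' \code{cubeYears}/\code{cubeMonths} the time keys.
#'
#' @param x a \linkS4class{RasterGrid}, \linkS4class{AnnualCube} or
#'   \linkS4class{MonthlyCube}.
#' @return The requested component.
#' @name raster-accessors
#' @aliases gridValues nodataMask gridTransform gridCrs isCategorical
#'   cubeYears cubeMonths
NULL

#' @rdname raster-accessors
#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))
#' @rdname raster-accessors
#' @export
setGeneric("nodataMask", function(x) standardGeneric("nodataMask"))
#' @rdname raster-accessors
#' @export
setGeneric("gridTransform", function(x) standardGeneric("gridTransform"))
#' @rdname raster-accessors
#' @export
setGeneric("gridCrs", function(x) standardGeneric("gridCrs"))
#' @rdname raster-accessors
#' @export
setGeneric("isCategorical", function(x) standardGeneric("isCategorical"))
#' @rdname raster-accessors
#' @export
setGeneric("cubeYears", function(x) standardGeneric("cubeYears"))
#' @rdname raster-accessors
#' @export
setGeneric("cubeMonths", function(x) standardGeneric("cubeMonths"))

#' Extract one layer of a cube as a RasterGrid
#'
#' @param x an \linkS4class{AnnualCube} or \linkS4class{MonthlyCube}.
#' @param year calendar year of the layer.
#' @param month month 1..12 (MonthlyCube only).
#' @return A \linkS4class{RasterGrid}.
#' @export
setGeneric("getGrid", function(x, year, month) standardGeneric("getGrid"))

#' ChangeMap accessors
#'
#' @param x a \linkS4class{ChangeMap}.
#' @return \code{changeCode}: integer code matrix; \code{sfMask}/\code{cfMask}:
#'   logical matrices; \code{changeLegend}: the decoding data.frame.
#' @name changemap-accessors
#' @aliases changeCode sfMask cfMask changeLegend
NULL

#' @rdname changemap-accessors
#' @export
setGeneric("changeCode", function(x) standardGeneric("changeCode"))
#' @rdname changemap-accessors
#' @export
setGeneric("sfMask", function(x) standardGeneric("sfMask"))
#' @rdname changemap-accessors
#' @export
setGeneric("cfMask", function(x) standardGeneric("cfMask"))
#' @rdname changemap-accessors
#' @export
setGeneric("changeLegend", function(x) standardGeneric("changeLegend"))

#' AttributionResult accessors
#'
#' @param x an \linkS4class{AttributionResult}.
#' @return \code{totalImportance}/\code{mainImportance}: named numeric vectors
#'   that sum to 1; \code{interactionMatrix}: symmetric feature-by-feature
#'   matrix of mean absolute pairwise interaction values; \code{shapValues}:
#'   the per-sample SHAP matrix.
#' @name attribution-accessors
#' @aliases totalImportance mainImportance interactionMatrix shapValues
NULL

#' @rdname attribution-accessors
#' @export
setGeneric("totalImportance", function(x) standardGeneric("totalImportance"))
#' @rdname attribution-accessors
#' @export
setGeneric("mainImportance", function(x) standardGeneric("mainImportance"))
#' @rdname attribution-accessors
#' @export
setGeneric("interactionMatrix",
           function(x) standardGeneric("interactionMatrix"))
#' @rdname attribution-accessors
#' @export
setGeneric("shapValues", function(x) standardGeneric("shapValues"))
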