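#' @include methods.R
NULL

# ESRI ASCII grid (.asc) carries no CRS in its header; the CRS travels in a
# .prj sidecar next to the raster, as GIS tools conventionally write it.
prjPath <- function(path) sub("\\.[^.]*$", ".prj", path)

#' Read a raster from an ESRI ASCII grid
#'
#' Reads a single-band plain-text raster (.asc). The nodata value declared in
#' the header becomes \code{NA}. The CRS is taken from the \code{.prj}
#' sidecar; if the sidecar is absent and no \code{crs} is supplied the read
#' fails rather than silently assuming a coordinate system.
#'
#' @param path path to the .asc file.
#' @param crs optional CRS string overriding/standing in for the sidecar.
#' @param categorical mark the grid as integer-coded classes.
#' @return A \linkS4class{RasterGrid}.
#' @export
readAsciiGrid <- function(path, crs = NULL, categorical = FALSE) {
  if (!file.exists(path)) stop("raster file not found: ", path)
  con <- file(path, "r")
  on.exit(close(con))
  hdr <- list()
  repeat {
    pos <- seek(con)
    line <- readLines(con, n = 1L)
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(tok) == 2L && grepl("^[A-Za-z_]+$", tok[1])) {
      hdr[[tolower(tok[1])]] <- as.numeric(tok[2])
    } else {
      seek(con, pos)
      break
    }
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr))) {
    stop("not an ESRI ASCII grid (missing header fields): ", path)
  }
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(con, what = double(), quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc) {
    stop("raster body has ", length(vals), " cells, expected ", nr * nc,
         ": ", path)
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)  # rows top-down
  m[m == nodata] <- NA_real_
  if (is.null(crs)) {
    pf <- prjPath(path)
    if (!file.exists(pf)) {
      stop("no CRS for raster ", path,
           ": .prj sidecar missing and no 'crs' supplied")
    }
    crs <- paste(readLines(pf, warn = FALSE), collapse = "\n")
  }
  xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner else 0
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner else 0
  cs <- hdr$cellsize
  RasterGrid(m, transform = c(xll, cs, 0, yll + nr * cs, 0, -cs), crs = crs,
             categorical = categorical)
}

#' Write a raster to an ESRI ASCII grid
#'
#' Writes the grid as a plain-text .asc plus a .prj sidecar with the CRS.
#' \code{NA} cells are written as the nodata value. Requires square pixels
#' (the .asc format has a single \code{cellsize}).
#'
#' @param grid a \linkS4class{RasterGrid}.
#' @param path output .asc path.
#' @param nodata nodata sentinel written for \code{NA} cells.
#' @param digits significant digits used for cell values.
#' @return \code{path}, invisibly.
#' @export
writeAsciiGrid <- function(grid, path, nodata = -9999, digits = 15) {
  tr <- gridTransform(grid)
  if (abs(tr[2] - abs(tr[6])) > 1e-9 * tr[2]) {
    stop("ASCII grid requires square pixels; got dx=", tr[2],
         ", dy=", tr[6])
  }
  m <- gridValues(grid)
  nr <- nrow(m); nc <- ncol(m)
  hdr <- c(
    paste("ncols", nc),
    paste("nrows", nr),
    paste("xllcorner", format(tr[1], digits = 15)),
    paste("yllcorner", format(tr[4] + nr * tr[6], digits = 15)),
    paste("cellsize", format(tr[2], digits = 15)),
    paste("NODATA_value", nodata)
  )
  body <- m
  body[is.na(body)] <- nodata
  lines <- apply(body, 1L, function(r) {
    paste(format(r, digits = digits, trim = TRUE, scientific = FALSE),
          collapse = " ")
  })
  writeLines(c(hdr, lines), path)
  writeLines(gridCrs(grid), prjPath(path))
  invisible(path)
}

#' Write / read a cube as one ASCII grid per layer
#'
#' Layers are written as \code{<prefix>_<year>.asc} (annual) or
#' \code{<prefix>_<year>_<mm>.asc} (monthly) in a directory, the layout
#' \code{readAnnualCube}/\code{readMonthlyCube} scan back.
#'
#' @param cube an \linkS4class{AnnualCube} or \linkS4class{MonthlyCube}.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return The vector of files written, invisibly.
#' @export
writeCube <- function(cube, dir, prefix) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  if (is(cube, "AnnualCube")) {
    for (y in cubeYears(cube)) {
      f <- file.path(dir, sprintf("%s_%d.asc", prefix, y))
      writeAsciiGrid(getGrid(cube, y), f)
      files <- c(files, f)
    }
  } else {
    ys <- cubeYears(cube); ms <- cubeMonths(cube)
    for (k in seq_along(ys)) {
      f <- file.path(dir, sprintf("%s_%d_%02d.asc", prefix, ys[k], ms[k]))
      writeAsciiGrid(getGrid(cube, ys[k], ms[k]), f)
      files <- c(files, f)
    }
  }
  invisible(files)
}

#' @rdname writeCube
#' @param categorical mark layers as integer-coded classes.
#' @export
readAnnualCube <- function(dir, prefix, categorical = FALSE) {
  fs <- sort(list.files(dir, sprintf("^%s_\\d{4}\\.asc$", prefix),
                        full.names = TRUE))
  if (!length(fs)) stop("no '", prefix, "_<year>.asc' layers under ", dir)
  years <- as.integer(sub(".*_(\\d{4})\\.asc$", "\\1", fs))
  gs <- lapply(fs, readAsciiGrid, categorical = categorical)
  g1 <- gs[[1]]
  annualCube(lapply(gs, gridValues), years, transform = gridTransform(g1),
             crs = gridCrs(g1), categorical = categorical)
}

#' @rdname writeCube
#' @export
readMonthlyCube <- function(dir, prefix) {
  fs <- sort(list.files(dir, sprintf("^%s_\\d{4}_\\d{2}\\.asc$", prefix),
                        full.names = TRUE))
  if (!length(fs)) stop("no '", prefix, "_<year>_<mm>.asc' layers under ", dir)
  years <- as.integer(sub(".*_(\\d{4})_\\d{2}\\.asc$", "\\1", fs))
  months <- as.integer(sub(".*_(\\d{2})\\.asc$", "\\1", fs))
  gs <- lapply(fs, readAsciiGrid)
  g1 <- gs[[1]]
  monthlyCube(lapply(gs, gridValues), years, months,
              transform = gridTransform(g1), crs = gridCrs(g1))
}

#' Resample a raster onto a template geometry
#'
#' Affine alignment of same-CRS grids: each template cell centre is projected
#' into the source grid and sampled with the requested rule. Continuous
#' fields use \code{"bilinear"}; integer-coded class grids must use
#' \code{"nearest"} (bilinear on a categorical grid is refused, as it would
#' invent classes). Cells falling outside the source extent become nodata.
#'
#' @param grid source \linkS4class{RasterGrid}.
#' @param template \linkS4class{RasterGrid} whose geometry the output takes.
#' @param rule \code{"nearest"} or \code{"bilinear"}.
#' @return A \linkS4class{RasterGrid} on the template geometry.
#' @export
alignToTemplate <- function(grid, template, rule = c("nearest", "bilinear")) {
  rule <- match.arg(rule)
  if (!identical(gridCrs(grid), gridCrs(template))) {
    stop("CRS mismatch (", gridCrs(grid), " vs ", gridCrs(template),
         "); reprojection is out of scope")
  }
  if (rule == "bilinear" && isCategorical(grid)) {
    stop("bilinear resampling refused for a categorical class grid; ",
         "use rule = 'nearest'")
  }
  if (sameGeometry(grid, template)) {
    return(RasterGrid(gridValues(grid), transform = gridTransform(template),
                      crs = gridCrs(template),
                      categorical = isCategorical(grid)))
  }
  src <- gridValues(grid)
  ts <- gridTransform(template); ss <- gridTransform(grid)
  nrT <- nrow(gridValues(template)); ncT <- ncol(gridValues(template))
  # template cell centres in map coordinates
  cx <- ts[1] + (seq_len(ncT) - 0.5) * ts[2]
  cy <- ts[4] + (seq_len(nrT) - 0.5) * ts[6]
  # fractional pixel coordinates in the source (1-based cell centres)
  px <- (matrix(cx, nrT, ncT, byrow = TRUE) - ss[1]) / ss[2] + 0.5
  py <- (matrix(cy, nrT, ncT) - ss[4]) / ss[6] + 0.5
  out <- matrix(NA_real_, nrT, ncT)
  if (rule == "nearest") {
    ri <- round(py); ci <- round(px)
    ok <- ri >= 1 & ri <= nrow(src) & ci >= 1 & ci <= ncol(src)
    out[ok] <- src[cbind(ri[ok], ci[ok])]
  } else {
    # clamp to the band of cell centres, so edge cells repeat outward
    pyc <- pmin(pmax(py, 1), nrow(src))
    pxc <- pmin(pmax(px, 1), ncol(src))
    r0 <- as.vector(floor(pyc)); c0 <- as.vector(floor(pxc))
    r1 <- pmin(r0 + 1, nrow(src)); c1 <- pmin(c0 + 1, ncol(src))
    fr <- as.vector(pyc) - r0; fc <- as.vector(pxc) - c0
    inside <- py >= 0.5 & py <= nrow(src) + 0.5 &
      px >= 0.5 & px <= ncol(src) + 0.5
    v00 <- src[cbind(r0, c0)]; v01 <- src[cbind(r0, c1)]
    v10 <- src[cbind(r1, c0)]; v11 <- src[cbind(r1, c1)]
    val <- matrix((1 - fr) * ((1 - fc) * v00 + fc * v01) +
                    fr * ((1 - fc) * v10 + fc * v11), nrT, ncT)
    out[inside] <- val[inside]
  }
  RasterGrid(out, transform = ts, crs = gridCrs(template),
             categorical = isCategorical(grid))
}
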