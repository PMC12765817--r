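#' @include pdp.R
NULL

configDefaults <- list(
  first_year = 2001L, last_year = 2022L,
  alpha = 0.05,
  seed = 1L,
  nrow = 48L, ncol = 48L,
  change_fraction = 0.3,
  resampling = "bilinear",
  sample_cap = 5000L,
  tuner_budget = 0L,
  cv_folds = 3L,
  eval_cap = 300L,
  pdp_grid = 30L,
  top_features = 6L,
  casa_params = NULL,     # path to an edited parameter CSV
  subregions = NULL,      # path to a label raster (.asc)
  out_dir = "npp_out"
)

#' Read and validate a run configuration
#'
#' YAML key/value file; unknown keys are rejected, missing keys take the
#' documented defaults. See the package README for the schema.
#'
#' @param path YAML file path, or a named list of overrides.
#' @return Validated configuration list.
#' @export
readRunConfig <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else as.list(path)
  unknown <- setdiff(names(cfg), names(configDefaults))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  full <- configDefaults
  full[names(cfg)] <- cfg
  if (full$first_year >= full$last_year) {
    stop("config error: first_year must be < last_year")
  }
  if (full$alpha <= 0 || full$alpha >= 1) {
    stop("config error: alpha must lie in (0, 1)")
  }
  if (full$change_fraction < 0 || full$change_fraction >= 1) {
    stop("config error: change_fraction must lie in [0, 1)")
  }
  full
}

logLine <- function(log, ...) {
  msg <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), ...)
  cat(msg, "\n", file = log, append = TRUE, sep = "")
  message(msg)
}

#' Run the full NPP analysis pipeline
#'
#' Chains the stages on a synthetic study system: simulate inputs, CASA NPP
#' estimation, stable/changing-forest classification, per-pixel trend and
#' Hurst/persistence analysis with future-trend superposition, and
#' random-forest + SHAP driver attribution per forest stratum. Every
#' intermediate product is written under \code{out_dir} (rasters as ASCII
#' grids, tables as CSV) and a log records the seed, package version and
#' per-stage pixel/row counts. All randomness derives from
#' \code{config$seed}, so a rerun with the same config is identical.
#'
#' @param config path to a YAML config or a named list
#'   (see \code{\link{readRunConfig}}).
#' @param stages character vector of stages to run; default \code{"all"}.
#' @return Invisible list with the in-memory products of the executed
#'   stages.
#' @export
runPipeline <- function(config, stages = "all") {
  cfg <- readRunConfig(config)
  all <- c("simulate", "casa", "dynamics", "trend", "hurst", "attribute")
  stages <- if (identical(stages, "all")) all else match.arg(stages, all,
                                                             several.ok = TRUE)
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log <- file.path(out, "pipeline.log")
  logLine(log, "forestNPP ", as.character(utils::packageVersion("forestNPP")),
          " | seed ", cfg$seed, " | period ", cfg$first_year, "-",
          cfg$last_year)
  years <- cfg$first_year:cfg$last_year
  res <- list(config = cfg)

  runStage <- function(name, fun) {
    tryCatch(fun(), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  sys <- runStage("simulate", function() {
    s <- generateStudySystem(cfg$nrow, cfg$ncol, years,
                             changeFraction = cfg$change_fraction,
                             seed = cfg$seed)
    logLine(log, "simulate: ", cfg$nrow, "x", cfg$ncol, " grid, ",
            length(years), " years, ", sum(s$sfTruth | s$cfTruth),
            " forest px")
    s
  })
  res$system <- sys
  if ("simulate" %in% stages) {
    writeAsciiGrid(sys$elevation, file.path(out, "elevation.asc"))
    writeAsciiGrid(sys$slope, file.path(out, "slope.asc"))
    writeAsciiGrid(sys$aspect, file.path(out, "aspect.asc"))
    writeAsciiGrid(sys$ha, file.path(out, "ha.asc"))
    writeAsciiGrid(sys$age, file.path(out, "forest_age.asc"))
    writeAsciiGrid(sys$ftype, file.path(out, "forest_type.asc"))
    writeCube(sys$landcover, file.path(out, "landcover"), "lc")
    writeCube(sys$npp, file.path(out, "npp_true"), "npp")
  }

  params <- if (is.null(cfg$casa_params)) casaParams() else
    casaParams(cfg$casa_params)
  if (any(c("casa", "trend", "hurst", "attribute") %in% stages)) {
    est <- runStage("casa", function() {
      casaNpp(sys$ndvi, sys$landcover, sys$pre, sys$tem, sys$srad, params)
    })
    res$casa <- est
    val <- validateAgainstReference(est$annual, sys$npp)
    res$validation <- val
    logLine(log, "casa: annual NPP for ", length(years), " years; R2 vs ",
            "synthetic truth ", round(val$r2, 3), " (n=", val$n, ")")
    if ("casa" %in% stages) {
      writeCube(est$annual, file.path(out, "npp_casa"), "npp")
      utils::write.csv(data.frame(r2 = val$r2, rmse = val$rmse, n = val$n),
                       file.path(out, "casa_validation.csv"),
                       row.names = FALSE)
    }
  }

  cm <- runStage("dynamics", function() classifyForestDynamics(sys$landcover))
  res$changeMap <- cm
  if ("dynamics" %in% stages) {
    writeAsciiGrid(RasterGrid(changeCode(cm) + 0,
                              gridTransform(sys$landcover),
                              gridCrs(sys$landcover), categorical = TRUE),
                   file.path(out, "change_code.asc"))
    utils::write.csv(changeLegend(cm), file.path(out, "change_legend.csv"),
                     row.names = FALSE)
    cs <- changeSummary(cm)
    utils::write.csv(cs$dynamics, file.path(out, "change_summary.csv"),
                     row.names = FALSE)
    logLine(log, "dynamics: ", sum(sfMask(cm)), " SF px, ", sum(cfMask(cm)),
            " CF px")
  }

  forestMask <- sfMask(cm) | cfMask(cm)
  subreg <- if (!is.null(cfg$subregions)) {
    readAsciiGrid(cfg$subregions, categorical = TRUE)
  } else NULL

  if ("trend" %in% stages || "hurst" %in% stages ||
      "attribute" %in% stages) {
    tt <- runStage("trend", function() {
      trendAnalysis(res$casa$annual, alpha = cfg$alpha, mask = forestMask)
    })
    res$trend <- tt
    logLine(log, "trend: ", nrow(tt), " px analysed")
    if ("trend" %in% stages) {
      utils::write.csv(tt, file.path(out, "trend.csv"), row.names = FALSE)
      utils::write.csv(
        areaProportions(tt, subregions = if (is.null(subreg)) NULL else
          gridValues(subreg), dims = dim(forestMask)),
        file.path(out, "trend_proportions.csv"), row.names = FALSE)
    }
  }

  if ("hurst" %in% stages || "attribute" %in% stages) {
    ht <- runStage("hurst", function() {
      hurstAnalysis(res$casa$annual, mask = forestMask)
    })
    res$hurst <- ht
    res$future <- futureTrend(res$trend, ht)
    logLine(log, "hurst: mean H ", round(mean(ht$H, na.rm = TRUE), 3),
            " over ", nrow(ht), " px")
    if ("hurst" %in% stages) {
      utils::write.csv(ht, file.path(out, "hurst.csv"), row.names = FALSE)
      utils::write.csv(res$future, file.path(out, "future_trend.csv"),
                       row.names = FALSE)
      utils::write.csv(
        areaProportions(res$future, classCol = "future_class",
                        dims = dim(forestMask)),
        file.path(out, "future_proportions.csv"), row.names = FALSE)
    }
  }

  if ("attribute" %in% stages) {
    climate <- list(pre = sys$pre, tem = sys$tem, srad = sys$srad)
    terrain <- list(elevation = sys$elevation, slope = sys$slope,
                    aspect = sys$aspect)
    anthro <- list(ha = sys$ha, age = sys$age, ftype = sys$ftype)
    res$attribution <- list()
    for (stratum in c("SF", "CF")) {
      mask <- if (stratum == "SF") sfMask(cm) else cfMask(cm)
      if (sum(mask) < 200) {
        logLine(log, "attribute: skipping ", stratum,
                " (only ", sum(mask), " px)")
        next
      }
      tab <- buildDriverTable(res$casa$annual, climate, terrain, anthro,
                              mask, subregions = subreg, stratum = stratum,
                              sampleCap = cfg$sample_cap, seed = cfg$seed)
      model <- runStage("attribute", function() {
        fitRf(tab, budget = cfg$tuner_budget, folds = cfg$cv_folds,
              seed = cfg$seed)
      })
      shap <- shapEffects(model, evalCap = cfg$eval_cap, seed = cfg$seed)
      ranks <- rankDrivers(shap)
      topF <- utils::head(ranks$feature, cfg$top_features)
      curves <- lapply(topF, function(f) {
        partialDependence(model, f, nGrid = cfg$pdp_grid)
      })
      names(curves) <- topF
      thresholds <- lapply(curves, function(cu) {
        tryCatch(extractThresholds(cu), error = function(e) NULL)
      })
      res$attribution[[stratum]] <- list(table = tab, model = model,
                                         shap = shap, ranks = ranks,
                                         curves = curves,
                                         thresholds = thresholds)
      pfx <- file.path(out, paste0("attribution_", stratum))
      utils::write.csv(ranks, paste0(pfx, "_importance.csv"),
                       row.names = FALSE)
      utils::write.csv(as.data.frame(interactionMatrix(shap)),
                       paste0(pfx, "_interactions.csv"))
      pdTab <- do.call(rbind, lapply(names(curves), function(f) {
        cu <- curves[[f]]
        data.frame(feature = f, grid = cu$grid, pd = cu$pd,
                   density = cu$density, sparse = cu$sparse)
      }))
      utils::write.csv(pdTab, paste0(pfx, "_pdp.csv"), row.names = FALSE)
      optTab <- do.call(rbind, lapply(names(thresholds), function(f) {
        th <- thresholds[[f]]
        if (is.null(th) || is.null(th$optimum)) return(NULL)
        data.frame(feature = f, opt_lo = th$optimum[1],
                   opt_hi = th$optimum[2],
                   n_breakpoints = nrow(th$breakpoints))
      }))
      if (!is.null(optTab)) {
        utils::write.csv(optTab, paste0(pfx, "_thresholds.csv"),
                         row.names = FALSE)
      }
      meta <- list(stratum = stratum, seed = cfg$seed,
                   hyperparams = model@hyperparams,
                   metrics = as.list(model@metrics))
      jsonlite::write_json(meta, paste0(pfx, "_model.json"),
                           auto_unbox = TRUE, digits = NA)
      logLine(log, "attribute[", stratum, "]: n=", nrow(tab),
              ", holdout R2=", round(model@metrics[["r2"]], 3),
              ", top driver ", ranks$feature[1])
    }
  }
  invisible(res)
}
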