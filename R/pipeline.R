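## Orchestration: run configuration (YAML round-trip), the end-to-end
## pipeline over a synthetic scene, and the standard test fixture.

#' Run configuration for the mapping pipeline
#'
#' Bundles every tunable of the workflow. The \code{gee_four_season}
#' variant forces the constraints of the cloud-platform re-run: four
#' shorter seasons, no inter-seasonal difference features, a single
#' unbalanced forest with \code{sqrt(k)} variables per split, and
#' presence/absence output at the 0.5 vote threshold. Season windows must
#' not overlap in months.
#'
#' @param workflow \code{"hpc_two_season"} or \code{"gee_four_season"}.
#' @param seasonWindows named month windows; defaults per workflow.
#' @param nTrees trees per forest.
#' @param varsPerSplit variables tried per split; \code{NULL} =
#'   \code{sqrt(k)}. Forced to \code{NULL} in the GEE variant.
#' @param fusion \code{"dual_min"} (two forests, minimum fused) or
#'   \code{"single"}.
#' @param output \code{"probability"} (kappa-optimal threshold) or
#'   \code{"presence"}.
#' @param darkObjectPercentile percentile for [darkObjectSubtract()].
#' @param maxShift co-registration search radius (pixels).
#' @param minValidFraction registration-failure threshold.
#' @param nPerPolygon training points drawn per polygon.
#' @param slopeMax,altMax terrain mask thresholds (degrees, m).
#' @param validate run the stratified validation stage.
#' @param seed master seed for every stochastic stage.
#' @return a \code{runConfig} list.
#' @export
runConfig <- function(workflow = c("hpc_two_season", "gee_four_season"),
                      seasonWindows = NULL, nTrees = 500L,
                      varsPerSplit = 3L, fusion = NULL, output = NULL,
                      darkObjectPercentile = 0.01, maxShift = 3L,
                      minValidFraction = 0.03, nPerPolygon = 100L,
                      slopeMax = 10, altMax = 470, validate = TRUE,
                      seed = 1L) {
  workflow <- match.arg(workflow)
  if (is.null(seasonWindows)) seasonWindows <- defaultSeasonWindows(workflow)
  checkSeasonWindows(seasonWindows)
  if (workflow == "gee_four_season") {
    fusion <- "single"; output <- "presence"; varsPerSplit <- NULL
  } else {
    if (is.null(fusion)) fusion <- "dual_min"
    if (is.null(output)) output <- "probability"
  }
  stopifnot(fusion %in% c("dual_min", "single"),
            output %in% c("probability", "presence"))
  structure(list(workflow = workflow, seasonWindows = seasonWindows,
                 nTrees = as.integer(nTrees), varsPerSplit = varsPerSplit,
                 fusion = fusion, output = output,
                 darkObjectPercentile = darkObjectPercentile,
                 maxShift = as.integer(maxShift),
                 minValidFraction = minValidFraction,
                 nPerPolygon = as.integer(nPerPolygon),
                 slopeMax = slopeMax, altMax = altMax,
                 validate = validate, seed = as.integer(seed)),
            class = "runConfig")
}

#' Write a run configuration as YAML
#' @param config a [runConfig()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeRunConfig <- function(config, path) {
  x <- unclass(config)
  x$seasonWindows <- lapply(x$seasonWindows, as.integer)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read a run configuration written by [writeRunConfig()]
#' @param path YAML path.
#' @return a [runConfig()].
#' @export
readRunConfig <- function(path) {
  x <- yaml::read_yaml(path)
  runConfig(workflow = x$workflow,
            seasonWindows = lapply(x$seasonWindows, as.integer),
            nTrees = x$nTrees, varsPerSplit = x$varsPerSplit,
            fusion = x$fusion, output = x$output,
            darkObjectPercentile = x$darkObjectPercentile,
            maxShift = x$maxShift, minValidFraction = x$minValidFraction,
            nPerPolygon = x$nPerPolygon, slopeMax = x$slopeMax,
            altMax = x$altMax, validate = x$validate, seed = x$seed)
}

#' Standard synthetic fixture scene
#'
#' A rare-reedbed landscape (reedbed 1% of land among water, grassland and
#' the arable confusion class) observed by six passes -- three 'green'
#' season, three 'brown' season -- carrying clouds with displaced shadows
#' on two passes, integer mis-registration up to three pixels, and mild
#' per-pass gain/offset reflectance error.
#'
#' @param nRows,nCols scene size in 10 m pixels.
#' @param seed master seed.
#' @param cloudy add clouds/shadows to two passes.
#' @param shifts list of per-pass \code{c(dx, dy)}; defaults exercise the
#'   \[-3, 3\] range.
#' @return a [SyntheticScene-class].
#' @export
makeFixture <- function(nRows = 200L, nCols = 200L, seed = 1L,
                        cloudy = TRUE, shifts = NULL) {
  land <- landscapeSpec(nRows, nCols, seed = seed)
  if (is.null(shifts))
    shifts <- list(c(0L, 0L), c(2L, -1L), c(-1L, 2L),
                   c(0L, 0L), c(3L, 1L), c(-2L, -3L))
  cf <- if (cloudy) c(0, 0.15, 0, 0, 0.25, 0) else rep(0, 6)
  dates <- as.Date(c("2016-06-20", "2016-07-15", "2016-08-20",
                     "2016-02-15", "2016-12-05", "2016-01-10"))
  gains <- list(1, 1.03, 0.97, 1, 1.02, 0.98)
  offsets <- list(0, 0.015, 0.005, 0.01, 0, 0.02)
  specs <- lapply(seq_along(dates), function(i)
    passSpec(dates[i], cloudFraction = cf[i], shadowFraction = cf[i],
             shift = shifts[[i]], gain = gains[[i]], offset = offsets[[i]]))
  generateDataset(land, specs)
}

#' Run the full mapping pipeline over a synthetic scene
#'
#' Executes every stage in order: dark-object subtraction, cloud-model
#' training and masking, co-registration against the most-valid pass
#' (passes failing registration are dropped), seasonal median composites,
#' the index feature stack, training-point sampling, the (dual) random
#' forest, threshold selection on fused out-of-bag probabilities,
#' prediction, hectare aggregation, terrain masking, and (optionally) the
#' stratified validation with corrected-extent estimation. A manifest of
#' seeds, thresholds and per-stage counts is kept in the returned log.
#'
#' @param config a [runConfig()].
#' @param scene a [SyntheticScene-class]; defaults to
#'   [makeFixture()]\code{(seed = config$seed)}.
#' @param outDir optional artifact directory; when given, composites,
#'   stack, maps, validation records and metrics are written there.
#' @return list with the probability map, cover maps, metrics, validation
#'   records, model, threshold, extents and the stage log.
#' @export
runPipeline <- function(config, scene = NULL, outDir = NULL) {
  stopifnot(inherits(config, "runConfig"))
  if (is.null(scene)) scene <- makeFixture(seed = config$seed)
  log <- list(seed = config$seed, workflow = config$workflow)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  ## 1. dark-object subtraction
  passes <- stage("dark_object", lapply(scene@passes, darkObjectSubtract,
                                        percentile = config$darkObjectPercentile))

  ## 2. cloud model + masking (skipped when the scene is cloud-free)
  cloudTrainIdx <- which(vapply(scene@cloudTruth, any, logical(1)))[1]
  if (!is.na(cloudTrainIdx)) {
    stage("cloud_mask", {
      polys <- cloudTrainingPolygons(scene@cloudTruth[[cloudTrainIdx]],
                                     seed = config$seed)
      cloudModel <- trainCloudModel(passes[[cloudTrainIdx]], polys,
                                    nTrees = config$nTrees,
                                    seed = config$seed)
      log$cloudModelOob <- oobError(cloudModel)
      passes <- lapply(passes, maskClouds, model = cloudModel)
    })
  } else {
    log$cloudModelOob <- NA_real_
  }
  log$maskedFractions <- vapply(passes, function(p) 1 - validFraction(p),
                                numeric(1))

  ## 3. co-registration (reference = most-valid pass); failures dropped
  refIdx <- which.max(vapply(passes, validFraction, numeric(1)))
  shifts <- vector("list", length(passes))
  dropped <- integer(0)
  for (i in seq_along(passes)) {
    if (i == refIdx) { shifts[[i]] <- c(dx = 0L, dy = 0L); next }
    sh <- tryCatch(
      estimateShift(passes[[refIdx]], passes[[i]],
                    maxShift = config$maxShift,
                    minValidFraction = config$minValidFraction),
      reedmapRegistrationFailure = function(e) NULL)
    if (is.null(sh)) { dropped <- c(dropped, i); next }
    shifts[[i]] <- sh
    passes[[i]] <- applyShift(passes[[i]], sh)
  }
  if (length(dropped)) passes <- passes[-dropped]
  log$estimatedShifts <- shifts
  log$droppedPasses <- dropped
  log$passesUsed <- length(passes)

  ## 4. seasonal composites + 5. feature stack
  composites <- stage("composite",
                      seasonalMedianComposite(passes, config$seasonWindows))
  seasonMode <- if (config$workflow == "hpc_two_season") "two_season"
                else "four_season"
  stack <- stage("features", buildFeatureStack(composites, seasonMode))
  log$nLayers <- length(layerNames(stack))

  ## 6. training sample + 7. forests
  trainSample <- stage("train",
                       sampleTrainingPoints(scene@polygons, stack,
                                            nPerPolygon = config$nPerPolygon,
                                            seed = config$seed))
  balanced <- if (config$fusion == "dual_min") c(TRUE, FALSE) else FALSE
  model <- stage("train",
                 fitReedModel(trainSample, balanced = balanced,
                              nTrees = config$nTrees,
                              varsPerSplit = config$varsPerSplit,
                              seeds = deriveSeeds(config$seed, length(balanced))))

  ## 8. threshold on fused out-of-bag probabilities
  threshold <- if (config$output == "probability") {
    kt <- stage("threshold",
                kappaThreshold(oobProbabilities(model), model@forests[[1]]$y))
    log$kappaAtThreshold <- kt$kappa
    kt$threshold
  } else 0.5
  log$threshold <- threshold

  ## 9. prediction + 10. aggregation + 11. terrain mask
  probMap <- stage("predict", predictProbability(model, stack, threshold))
  coverRaw <- stage("aggregate", aggregateToHectare(probMap))
  demHa <- blockMeanNA(scene@dem, 10L)
  slopeHa <- slopeFromDem(demHa, cellSize = 100)
  coverMasked <- stage("terrain_mask",
                       terrainMask(coverRaw, slopeHa, demHa,
                                   slopeMax = config$slopeMax,
                                   altMax = config$altMax))
  extents <- c(predicted = totalExtent(coverRaw),
               masked = totalExtent(coverMasked))
  log$extents <- extents

  ## 12. validation against simulator truth
  validation <- NULL
  if (isTRUE(config$validate)) {
    validation <- stage("validate", {
      truth <- scene@classMap == "reedbed"
      records <- simulateFieldSurvey(truth, scene@classMap, probMap,
                                     coverRaw, seed = config$seed)
      cm10 <- confusionFromRecords(records, "tenm")
      cmHa <- confusionFromRecords(records, "hectare")
      aucCells <- tryCatch(rocAuc(records$cell_prob, records$cell_obs),
                           error = function(e) NA_real_)
      p <- as.vector(probabilityGrid(probMap))
      okPix <- !is.na(p)
      aucTruth <- tryCatch(rocAuc(p[okPix], as.vector(truth)[okPix]),
                           error = function(e) NA_real_)
      haRecs <- records[!duplicated(records$hectare_id), ]
      reg <- tryCatch(coverRegression(haRecs$predicted_cover,
                                      haRecs$observed_cover),
                      error = function(e) NULL)
      corrected <- tryCatch(
        correctedExtent(extents[["predicted"]], cm10, variant = "standard"),
        error = function(e) NA_real_)
      list(records = records, confusion10m = cm10, confusionHa = cmHa,
           auc = aucCells, aucTruth = aucTruth, regression = reg,
           correctedExtent = corrected)
    })
  }

  result <- list(config = config, model = model, stack = stack,
                 composites = composites, probabilityMap = probMap,
                 cover = coverRaw, coverMasked = coverMasked,
                 threshold = threshold, extents = extents,
                 validation = validation, sample = trainSample, log = log)

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    for (ss in names(composites))
      writeRasterTiff(composites[[ss]]@bands,
                      file.path(outDir, sprintf("composite_%s.tif", ss)))
    writeRasterTiff(stack@layers, file.path(outDir, "feature_stack.tif"))
    write.csv(data.frame(layer = layerNames(stack)),
              file.path(outDir, "feature_layers.csv"), row.names = FALSE)
    writeRasterTiff(list(probability = probabilityGrid(probMap),
                         presence = presenceGrid(probMap)),
                    file.path(outDir, "reed_map.tif"))
    writeRasterTiff(list(cover = coverGrid(coverRaw),
                         cover_masked = coverGrid(coverMasked)),
                    file.path(outDir, "cover.tif"))
    write.csv(data.frame(feature = rownames(variableImportance(model)),
                         variableImportance(model)),
              file.path(outDir, "variable_importance.csv"),
              row.names = FALSE)
    if (!is.null(validation)) {
      write.csv(validation$records, file.path(outDir, "validation_records.csv"),
                row.names = FALSE)
      cm <- validation$confusion10m
      jsonlite::write_json(list(
        confusion10m = as.list(confusionCounts(cm)),
        commission = commissionError(cm)[["reedbed"]],
        omission = omissionError(cm)[["reedbed"]],
        auc = validation$auc,
        correctedExtent = validation$correctedExtent),
        file.path(outDir, "metrics.json"), auto_unbox = TRUE, digits = NA)
    }
    jsonlite::write_json(
      list(seed = config$seed, workflow = config$workflow,
           threshold = threshold, passesUsed = log$passesUsed,
           droppedPasses = log$droppedPasses, extents = as.list(extents)),
      file.path(outDir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(result)
}
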