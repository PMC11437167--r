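## Accessors and show methods. Slots are never reached into by user code.

#' @name accessors
#' @title Accessors for reedmap containers
#' @param x an object.
#' @param band band name, one of [S2_BANDS].
#' @description Small accessor generics for the S4 containers: band grids,
#'   validity masks, dates, layer names, probability/presence grids, cover
#'   grids and confusion-matrix statistics.
NULL

#' @rdname accessors
#' @export
setGeneric("getBand", function(x, band) standardGeneric("getBand"))

#' @rdname accessors
#' @export
setGeneric("validMask", function(x) standardGeneric("validMask"))

#' @rdname accessors
#' @export
setGeneric("passDate", function(x) standardGeneric("passDate"))

#' @rdname accessors
#' @export
setGeneric("layerNames", function(x) standardGeneric("layerNames"))

#' @rdname accessors
#' @export
setGeneric("getLayer", function(x, band) standardGeneric("getLayer"))

#' @rdname accessors
#' @export
setGeneric("probabilityGrid", function(x) standardGeneric("probabilityGrid"))

#' @rdname accessors
#' @export
setGeneric("presenceGrid", function(x) standardGeneric("presenceGrid"))

#' @rdname accessors
#' @export
setGeneric("presenceThreshold", function(x) standardGeneric("presenceThreshold"))

#' @rdname accessors
#' @export
setGeneric("coverGrid", function(x) standardGeneric("coverGrid"))

#' @rdname accessors
#' @export
setGeneric("coverageGrid", function(x) standardGeneric("coverageGrid"))

#' @rdname accessors
#' @export
setMethod("getBand", "MultibandPass", function(x, band) {
  x@bands[, , match.arg(band, S2_BANDS)]
})

#' @rdname accessors
#' @export
setMethod("getBand", "SeasonalComposite", function(x, band) {
  x@bands[, , match.arg(band, S2_BANDS)]
})

#' @rdname accessors
#' @export
setMethod("validMask", "MultibandPass", function(x) x@valid)

#' @rdname accessors
#' @export
setMethod("validMask", "SeasonalComposite", function(x) x@coverage > 0L)

#' @rdname accessors
#' @export
setMethod("passDate", "MultibandPass", function(x) x@date)

#' @rdname accessors
#' @export
setMethod("coverageGrid", "SeasonalComposite", function(x) x@coverage)

#' @rdname accessors
#' @export
setMethod("layerNames", "FeatureStack", function(x) dimnames(x@layers)[[3]])

#' @rdname accessors
#' @export
setMethod("getLayer", "FeatureStack", function(x, band) {
  nm <- dimnames(x@layers)[[3]]
  if (!band %in% nm) stop("unknown layer: ", band)
  x@layers[, , band]
})

#' @rdname accessors
#' @export
setMethod("probabilityGrid", "ReedProbabilityMap", function(x) x@p)

#' @rdname accessors
#' @export
setMethod("presenceGrid", "ReedProbabilityMap", function(x) {
  pres <- (x@p > x@threshold) * 1
  pres[is.na(x@p)] <- NA_real_
  pres
})

#' @rdname accessors
#' @export
setMethod("presenceThreshold", "ReedProbabilityMap", function(x) x@threshold)

#' @rdname accessors
#' @export
setMethod("coverGrid", "HectareCoverMap", function(x) x@cover)

## ---- confusion-matrix statistics -----------------------------------------

#' @rdname confusionMetrics
#' @export
setGeneric("commissionError", function(x) standardGeneric("commissionError"))

#' @rdname confusionMetrics
#' @export
setGeneric("omissionError", function(x) standardGeneric("omissionError"))

#' @rdname confusionMetrics
#' @export
setGeneric("overallAccuracy", function(x) standardGeneric("overallAccuracy"))

#' @rdname confusionMetrics
#' @export
setGeneric("predictedPrevalence", function(x) standardGeneric("predictedPrevalence"))

#' @rdname confusionMetrics
#' @export
setGeneric("truePrevalence", function(x) standardGeneric("truePrevalence"))

#' @rdname confusionMetrics
#' @export
setGeneric("kappaStatistic", function(x) standardGeneric("kappaStatistic"))

#' @rdname confusionMetrics
#' @export
setGeneric("confusionCounts", function(x) standardGeneric("confusionCounts"))

#' Confusion counts and the accuracy statistics derived from them
#'
#' \code{confusionMetrics()} stores the four counts of a binary confusion
#' matrix with reedbed as the positive class. All derived statistics are
#' recomputed exactly from the counts: per-class commission error
#' (\code{fp/(tp+fp)} for reedbed, \code{fn/(fn+tn)} for non-reedbed),
#' per-class omission error (\code{fn/(tp+fn)}, \code{fp/(fp+tn)}), overall
#' accuracy, Cohen's kappa, and predicted/true reedbed prevalence.
#'
#' @param tp,fp,fn,tn non-negative counts.
#' @param x a \code{ConfusionMetrics} object.
#' @return \code{confusionMetrics()} returns a [ConfusionMetrics-class];
#'   the accessors return named numerics.
#' @examples
#' cm <- confusionMetrics(tp = 21, fp = 297, fn = 18, tn = 588)
#' commissionError(cm)["reedbed"]   # 0.934
#' omissionError(cm)["reedbed"]     # 0.461
#' @name confusionMetrics
#' @export
confusionMetrics <- function(tp, fp, fn, tn) {
  new("ConfusionMetrics", tp = as.numeric(tp), fp = as.numeric(fp),
      fn = as.numeric(fn), tn = as.numeric(tn))
}

#' @rdname confusionMetrics
#' @export
setMethod("confusionCounts", "ConfusionMetrics", function(x) {
  c(tp = x@tp, fp = x@fp, fn = x@fn, tn = x@tn)
})

#' @rdname confusionMetrics
#' @export
setMethod("commissionError", "ConfusionMetrics", function(x) {
  c(reedbed = x@fp / (x@tp + x@fp), nonreedbed = x@fn / (x@fn + x@tn))
})

#' @rdname confusionMetrics
#' @export
setMethod("omissionError", "ConfusionMetrics", function(x) {
  c(reedbed = x@fn / (x@tp + x@fn), nonreedbed = x@fp / (x@fp + x@tn))
})

#' @rdname confusionMetrics
#' @export
setMethod("overallAccuracy", "ConfusionMetrics", function(x) {
  (x@tp + x@tn) / sum(confusionCounts(x))
})

#' @rdname confusionMetrics
#' @export
setMethod("predictedPrevalence", "ConfusionMetrics", function(x) {
  (x@tp + x@fp) / sum(confusionCounts(x))
})

#' @rdname confusionMetrics
#' @export
setMethod("truePrevalence", "ConfusionMetrics", function(x) {
  (x@tp + x@fn) / sum(confusionCounts(x))
})

#' @rdname confusionMetrics
#' @export
setMethod("kappaStatistic", "ConfusionMetrics", function(x) {
  cohensKappa(x@tp, x@fp, x@fn, x@tn)
})

## ---- show ----------------------------------------------------------------

setMethod("show", "MultibandPass", function(object) {
  d <- dim(object@valid)
  cat(sprintf("MultibandPass %s: %d x %d pixels, 13 bands, %.1f%% valid\n",
              format(object@date), d[1], d[2], 100 * mean(object@valid)))
})

setMethod("show", "SeasonalComposite", function(object) {
  d <- dim(object@coverage)
  cat(sprintf(
    "SeasonalComposite '%s': %d x %d pixels, mean coverage %.2f passes\n",
    object@season, d[1], d[2], mean(object@coverage)))
})

setMethod("show", "FeatureStack", function(object) {
  d <- dim(object@layers)
  cat(sprintf("FeatureStack (%s): %d x %d pixels, %d layers\n",
              object@seasonMode, d[1], d[2], d[3]))
  cat(" ", paste(layerNames(object), collapse = ", "), "\n")
})

setMethod("show", "TrainingSample", function(object) {
  cat(sprintf(
    "TrainingSample: %d points (%d reedbed / %d non-reedbed) from %d polygons\n",
    length(object@labels), sum(object@labels == "reedbed"),
    sum(object@labels == "nonreedbed"), length(object@polygonCounts)))
})

setMethod("show", "ReedModel", function(object) {
  cat(sprintf("ReedModel: %d forest(s) on %d features; balanced = %s\n",
              length(object@forests), length(object@featureNames),
              paste(object@balanced, collapse = "/")))
})

setMethod("show", "ReedProbabilityMap", function(object) {
  d <- dim(object@p)
  cat(sprintf(
    "ReedProbabilityMap: %d x %d pixels, threshold %.3f, %.2f%% predicted presence\n",
    d[1], d[2], object@threshold,
    100 * mean(presenceGrid(object), na.rm = TRUE)))
})

setMethod("show", "HectareCoverMap", function(object) {
  d <- dim(object@cover)
  cat(sprintf("HectareCoverMap: %d x %d ha cells, total extent %.1f ha\n",
              d[1], d[2], totalExtent(object)))
})

setMethod("show", "ConfusionMetrics", function(object) {
  cts <- confusionCounts(object)
  cat("ConfusionMetrics (reedbed positive)\n")
  cat(sprintf("  tp %g  fp %g  fn %g  tn %g\n",
              cts[1], cts[2], cts[3], cts[4]))
  cat(sprintf("  commission %.3f  omission %.3f  overall %.3f  kappa %.4f\n",
              commissionError(object)[["reedbed"]],
              omissionError(object)[["reedbed"]],
              overallAccuracy(object), kappaStatistic(object)))
})

setMethod("show", "SyntheticScene", function(object) {
  d <- dim(object@classMap)
  tab <- table(object@classMap)
  cat(sprintf("SyntheticScene: %d x %d pixels, %d passes, %d polygons\n",
              d[1], d[2], length(object@passes),
              length(unique(object@polygons$polygon))))
  cat("  class fractions:",
      paste(sprintf("%s %.3f", names(tab), tab / sum(tab)), collapse = ", "),
      "\n")
})
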