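## Central S4 containers. Grids are plain numeric matrices (row 1 = northern
## edge, column-major R storage); invalid pixels are carried either in a
## logical mask (passes) or as NA (derived layers).

#' One satellite acquisition: 13-band reflectance grid with validity mask
#'
#' @slot bands numeric array \code{nrow x ncol x 13}; third dimension named
#'   by [S2_BANDS]. Unitless surface reflectance, nominally in \[0, 1\].
#' @slot date acquisition date (\code{Date}).
#' @slot valid logical matrix; \code{FALSE} pixels are excluded from every
#'   statistic downstream.
#' @export
setClass("MultibandPass",
         slots = c(bands = "array", date = "Date", valid = "matrix"))

setValidity("MultibandPass", function(object) {
  d <- dim(object@bands)
  if (length(d) != 3L || d[3] != 13L)
    return("bands must be an nrow x ncol x 13 array")
  if (!identical(dimnames(object@bands)[[3]], S2_BANDS))
    return("third dimension of bands must be named by S2_BANDS")
  if (!identical(dim(object@valid), d[1:2]))
    return("valid mask dimensions must match the bands")
  if (!is.logical(object@valid)) return("valid must be logical")
  if (length(object@date) != 1L || is.na(object@date))
    return("date must be a single non-NA Date")
  TRUE
})

#' Per-season median reflectance composite
#'
#' @slot season season label.
#' @slot bands numeric array \code{nrow x ncol x 13} of per-pixel median
#'   reflectance; NA where no pass contributed.
#' @slot coverage integer matrix counting contributing (valid) passes per
#'   pixel; pixels with coverage 0 are invalid.
#' @export
setClass("SeasonalComposite",
         slots = c(season = "character", bands = "array",
                   coverage = "matrix"))

setValidity("SeasonalComposite", function(object) {
  d <- dim(object@bands)
  if (length(d) != 3L || d[3] != 13L)
    return("bands must be an nrow x ncol x 13 array")
  if (!identical(dimnames(object@bands)[[3]], S2_BANDS))
    return("third dimension of bands must be named by S2_BANDS")
  if (!identical(dim(object@coverage), d[1:2]))
    return("coverage dimensions must match the bands")
  if (any(object@coverage < 0)) return("coverage must be non-negative")
  if (length(object@season) != 1L) return("season must be a single label")
  TRUE
})

#' Named stack of spectral-index layers on the 10 m grid
#'
#' Seven indices per season, plus (two-season mode only) the summer-winter
#' differences in SAVI and NDWI: 16 layers in \code{two_season} mode,
#' 7 x number-of-seasons in \code{four_season} mode.
#'
#' @slot layers numeric array \code{nrow x ncol x k}; third dimension named
#'   by layer (e.g. \code{NDVI_summer}, \code{dSAVI}).
#' @slot seasonMode \code{"two_season"} or \code{"four_season"}.
#' @export
setClass("FeatureStack",
         slots = c(layers = "array", seasonMode = "character"))

setValidity("FeatureStack", function(object) {
  d <- dim(object@layers)
  if (length(d) != 3L) return("layers must be a 3-d array")
  nm <- dimnames(object@layers)[[3]]
  if (is.null(nm) || anyDuplicated(nm))
    return("layers must carry unique names")
  if (!object@seasonMode %in% c("two_season", "four_season"))
    return("seasonMode must be 'two_season' or 'four_season'")
  if (object@seasonMode == "two_season" && d[3] != 16L)
    return("two_season stacks have 16 layers (7 per season + dSAVI, dNDWI)")
  TRUE
})

#' Random-forest cloud classifier trained on the 13 raw bands
#'
#' @slot forest fitted \code{randomForest} object (500 trees, 3 variables
#'   per split by default).
#' @slot oobError out-of-bag error fraction reported by the forest.
#' @export
setClass("CloudModel", slots = c(forest = "ANY", oobError = "numeric"))

#' Training points sampled from labelled polygons
#'
#' @slot features numeric matrix, one row per retained point, columns named
#'   by feature layer.
#' @slot labels factor with levels \code{reedbed}, \code{nonreedbed}.
#' @slot pixels data.frame with columns \code{row}, \code{col},
#'   \code{polygon}, \code{landcover}.
#' @slot polygonCounts named integer vector of retained points per polygon.
#' @export
setClass("TrainingSample",
         slots = c(features = "matrix", labels = "factor",
                   pixels = "data.frame", polygonCounts = "integer"))

setValidity("TrainingSample", function(object) {
  if (nrow(object@features) != length(object@labels))
    return("features and labels disagree in length")
  if (!identical(levels(object@labels), c("reedbed", "nonreedbed")))
    return("labels must have levels reedbed, nonreedbed")
  if (nrow(object@pixels) != nrow(object@features))
    return("pixels and features disagree in length")
  dup <- duplicated(object@pixels[c("row", "col", "polygon")])
  if (any(dup)) return("points within a polygon's draw must occupy distinct pixels")
  TRUE
})

#' Dual random-forest reedbed model
#'
#' One or two forests (500 trees, 3 variables per split by default) trained
#' on the same feature names, differing by seed and optionally by class
#' balancing. Prediction fuses them by per-pixel minimum reedbed
#' probability.
#'
#' @slot forests list of fitted \code{randomForest} objects (length 1 or 2).
#' @slot featureNames character vector of the training feature layers.
#' @slot importance matrix (features x forests) of mean decrease in Gini.
#' @slot oobCommission matrix (class x forests) of out-of-bag commission
#'   error per predicted class.
#' @slot balanced logical, per forest, whether class-balanced sampling was
#'   used.
#' @slot seeds integer seeds used per forest.
#' @export
setClass("ReedModel",
         slots = c(forests = "list", featureNames = "character",
                   importance = "matrix", oobCommission = "matrix",
                   balanced = "logical", seeds = "integer"))

#' Per-pixel reedbed probability map at 10 m with presence threshold
#'
#' @slot p numeric matrix of fused reedbed probability in \[0, 1\]; NA where
#'   any contributing feature is invalid.
#' @slot threshold probability cutoff; presence is \code{p > threshold}.
#' @export
setClass("ReedProbabilityMap",
         slots = c(p = "matrix", threshold = "numeric"))

setValidity("ReedProbabilityMap", function(object) {
  vals <- object@p[!is.na(object@p)]
  if (length(vals) && (min(vals) < 0 || max(vals) > 1))
    return("probabilities must lie in [0, 1]")
  if (length(object@threshold) != 1L || object@threshold < 0 ||
      object@threshold > 1)
    return("threshold must be a single value in [0, 1]")
  TRUE
})

#' Hectare-scale proportional reedbed cover
#'
#' Cover per origin-aligned 100 m x 100 m block: presence pixels over valid
#' pixels; blocks with no valid pixel are NA.
#'
#' @slot cover numeric matrix of proportional cover in \[0, 1\] (NA =
#'   invalid block).
#' @export
setClass("HectareCoverMap", slots = c(cover = "matrix"))

setValidity("HectareCoverMap", function(object) {
  vals <- object@cover[!is.na(object@cover)]
  if (length(vals) && (min(vals) < 0 || max(vals) > 1))
    return("cover must lie in [0, 1]")
  TRUE
})

#' Binary confusion counts with derived accuracy statistics
#'
#' Stores only the four counts; commission, omission, overall accuracy,
#' kappa and prevalences are recomputed exactly from them by accessors.
#'
#' @slot tp,fp,fn,tn numeric counts (reedbed is the positive class).
#' @export
setClass("ConfusionMetrics",
         slots = c(tp = "numeric", fp = "numeric", fn = "numeric",
                   tn = "numeric"))

setValidity("ConfusionMetrics", function(object) {
  cts <- c(object@tp, object@fp, object@fn, object@tn)
  if (length(cts) != 4L || any(is.na(cts)) || any(cts < 0))
    return("counts must be four non-negative numbers")
  if (sum(cts) <= 0) return("total count must be positive")
  TRUE
})

#' Complete labelled synthetic dataset
#'
#' @slot classMap character matrix of true land-cover labels.
#' @slot dem numeric matrix of altitude (m).
#' @slot passes list of [MultibandPass-class].
#' @slot passSpecs list of the pass specifications used (date, clouds,
#'   shift, gain, offset, seed).
#' @slot cloudTruth list of logical matrices, one per pass, of true cloud
#'   (not shadow) pixels, aligned to the delivered (shifted) pass.
#' @slot polygons data.frame of truth polygons (\code{polygon},
#'   \code{class}, \code{row}, \code{col}), eroded one pixel from patch
#'   boundaries.
#' @slot seasonWindows named list of \code{c(startMonth, endMonth)} used for
#'   phenology during simulation.
#' @slot phenology the class phenology table used.
#' @slot notes character vector of generation warnings (e.g. a season
#'   window with no pass).
#' @export
setClass("SyntheticScene",
         slots = c(classMap = "matrix", dem = "matrix", passes = "list",
                   passSpecs = "list", cloudTruth = "list",
                   polygons = "data.frame", seasonWindows = "list",
                   phenology = "list", notes = "character"))

setValidity("SyntheticScene", function(object) {
  d <- dim(object@classMap)
  if (!identical(dim(object@dem), d))
    return("dem and classMap dimensions differ")
  for (p in object@passes)
    if (!identical(dim(p@valid), d)) return("pass dimensions differ from classMap")
  for (ct in object@cloudTruth)
    if (!identical(dim(ct), d)) return("cloudTruth dimensions differ from classMap")
  if (length(object@cloudTruth) != length(object@passes))
    return("one cloudTruth grid is required per pass")
  TRUE
})
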