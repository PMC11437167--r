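## Spectral-index feature stack. Seven indices per season; the two-season
## workflow adds the summer-winter differences in SAVI and NDWI.

#' Compute one spectral index from a seasonal composite
#'
#' Index formulas (band names per [S2_BANDS]):
#' \describe{
#'   \item{NDVI}{(B8 - B4) / (B8 + B4)}
#'   \item{NDWI}{(B3 - B8) / (B3 + B8) (McFeeters green--NIR, water-positive)}
#'   \item{SAVI}{1.5 (B8 - B4) / (B8 + B4 + 0.5)}
#'   \item{EVI}{2.5 (B8 - B4) / (B8 + 6 B4 - 7.5 B2 + 1)}
#'   \item{RG}{B4 / B3 (red/green ratio)}
#'   \item{GB}{B3 / B2 (green/blue ratio)}
#'   \item{SB4}{B4 / sum of all 13 bands (standardised red band)}
#' }
#' Zero denominators yield invalid (NA) pixels, not errors; pixels invalid
#' in the composite stay invalid.
#'
#' @param composite a [SeasonalComposite-class].
#' @param indexName one of [INDEX_NAMES].
#' @return numeric matrix.
#' @export
computeIndex <- function(composite, indexName) {
  stopifnot(is(composite, "SeasonalComposite"))
  if (!indexName %in% INDEX_NAMES)
    stop("unknown index name: ", indexName)
  B <- function(nm) composite@bands[, , nm]
  safeDiv <- function(num, den) {
    out <- num / den
    out[!is.na(den) & den == 0] <- NA_real_
    out
  }
  switch(indexName,
    NDVI = safeDiv(B("B8") - B("B4"), B("B8") + B("B4")),
    NDWI = safeDiv(B("B3") - B("B8"), B("B3") + B("B8")),
    SAVI = safeDiv(1.5 * (B("B8") - B("B4")), B("B8") + B("B4") + 0.5),
    EVI  = safeDiv(2.5 * (B("B8") - B("B4")),
                   B("B8") + 6 * B("B4") - 7.5 * B("B2") + 1),
    RG   = safeDiv(B("B4"), B("B3")),
    GB   = safeDiv(B("B3"), B("B2")),
    SB4  = safeDiv(B("B4"),
                   matrix(rowSums(matrix(composite@bands,
                                         ncol = 13L)),
                          nrow(composite@coverage))))
}

#' Build the classification feature stack from seasonal composites
#'
#' All seven indices are computed for each season. In \code{two_season}
#' mode (seasons \code{summer} and \code{winter}) the inter-seasonal
#' differences \code{dSAVI = SAVI_summer - SAVI_winter} and \code{dNDWI =
#' NDWI_summer - NDWI_winter} are appended, giving 16 layers; in
#' \code{four_season} mode no difference layers are used, giving 7 layers
#' per season. A pixel invalid in any contributing composite is invalid in
#' the derived layers. Layer order is stable: seasons in the order given,
#' indices in [INDEX_NAMES] order, difference layers last.
#'
#' @param composites named list of [SeasonalComposite-class] covering all
#'   seasons of the mode.
#' @param seasonMode \code{"two_season"} or \code{"four_season"}.
#' @return a [FeatureStack-class].
#' @export
buildFeatureStack <- function(composites,
                              seasonMode = c("two_season", "four_season")) {
  seasonMode <- match.arg(seasonMode)
  seasons <- names(composites)
  if (seasonMode == "two_season") {
    need <- c("summer", "winter")
    if (!all(need %in% seasons))
      stop("two_season mode requires seasons: ",
           paste(setdiff(need, seasons), collapse = ", "))
    seasons <- need
  } else if (length(seasons) < 2L) {
    stop("four_season mode requires at least two seasonal composites")
  }
  d <- dim(composites[[seasons[1]]]@coverage)
  layers <- list()
  for (ss in seasons) {
    comp <- composites[[ss]]
    if (!identical(dim(comp@coverage), d))
      stop("composite grids disagree in shape")
    for (ix in INDEX_NAMES)
      layers[[paste(ix, ss, sep = "_")]] <- computeIndex(comp, ix)
  }
  if (seasonMode == "two_season") {
    layers[["dSAVI"]] <- layers[["SAVI_summer"]] - layers[["SAVI_winter"]]
    layers[["dNDWI"]] <- layers[["NDWI_summer"]] - layers[["NDWI_winter"]]
  }
  arr <- array(NA_real_, c(d, length(layers)),
               dimnames = list(NULL, NULL, names(layers)))
  for (i in seq_along(layers)) arr[, , i] <- layers[[i]]
  new("FeatureStack", layers = arr, seasonMode = seasonMode)
}
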