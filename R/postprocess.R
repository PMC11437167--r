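## Post-processing: terrain masking, hectare aggregation, mosaicking and
## total-extent summation.

#' Slope from a digital elevation model (Horn's method)
#'
#' 3 x 3 finite-difference gradient (Horn's weights) with replicated
#' margins; slope is \code{atan(|grad z|)} in degrees.
#'
#' @param dem altitude matrix (m), at least 2 x 2.
#' @param cellSize pixel edge length (m).
#' @return slope matrix (degrees).
#' @export
slopeFromDem <- function(dem, cellSize) {
  stopifnot(is.matrix(dem), nrow(dem) >= 2L, ncol(dem) >= 2L, cellSize > 0)
  nr <- nrow(dem); nc <- ncol(dem)
  pad <- rbind(dem[1, , drop = FALSE], dem, dem[nr, , drop = FALSE])
  pad <- cbind(pad[, 1, drop = FALSE], pad, pad[, nc, drop = FALSE])
  at <- function(dr, dc) pad[(1 + dr):(nr + dr), (1 + dc):(nc + dc)]
  ## Horn: z1..z9 over rows (N->S) and cols (W->E)
  gx <- ((at(0, 2) + 2 * at(1, 2) + at(2, 2)) -
         (at(0, 0) + 2 * at(1, 0) + at(2, 0))) / (8 * cellSize)
  gy <- ((at(2, 0) + 2 * at(2, 1) + at(2, 2)) -
         (at(0, 0) + 2 * at(0, 1) + at(0, 2))) / (8 * cellSize)
  atan(sqrt(gx^2 + gy^2)) * 180 / pi
}

#' Aggregate a 10 m presence grid to hectare proportional cover
#'
#' Cover per origin-aligned 10 x 10 pixel block is the mean of presence
#' over the block's valid pixels; partial edge blocks use the pixels that
#' exist, and blocks with no valid pixel are invalid.
#'
#' @param presence 0/1 matrix with NA invalid pixels, or a
#'   [ReedProbabilityMap-class] (its thresholded presence grid is used).
#' @param blockSize pixels per block edge (10 for 10 m pixels and 100 m
#'   cells).
#' @return a [HectareCoverMap-class].
#' @export
aggregateToHectare <- function(presence, blockSize = 10L) {
  if (is(presence, "ReedProbabilityMap")) presence <- presenceGrid(presence)
  stopifnot(is.matrix(presence))
  new("HectareCoverMap", cover = blockMeanNA(presence, blockSize))
}

#' Mask steep or high-altitude hectare cells
#'
#' Cells with slope strictly above \code{slopeMax} (degrees) or altitude
#' strictly above \code{altMax} (m) -- terrain where reed does not occur --
#' are assigned cover 0; all other cells are unchanged.
#'
#' @param cover a [HectareCoverMap-class].
#' @param slope,altitude matrices aligned to the cover grid.
#' @param slopeMax,altMax strict thresholds (10 degrees, 470 m: the maximum
#'   recorded altitude of reed in Britain).
#' @return masked [HectareCoverMap-class].
#' @export
terrainMask <- function(cover, slope, altitude, slopeMax = 10,
                        altMax = 470) {
  stopifnot(is(cover, "HectareCoverMap"))
  cv <- cover@cover
  if (!identical(dim(slope), dim(cv)) || !identical(dim(altitude), dim(cv)))
    stop("slope/altitude grids are not aligned to the cover map")
  drop <- (slope > slopeMax) | (altitude > altMax)
  cv[drop & !is.na(cv)] <- 0
  new("HectareCoverMap", cover = cv)
}

#' Mosaic hectare cover maps on a common grid
#'
#' Per cell, combines the valid values across maps by the chosen rule
#' (mean by default); cells invalid in every map stay invalid.
#'
#' @param maps list of [HectareCoverMap-class] on one grid.
#' @param rule overlap rule: \code{"mean"}, \code{"min"} or \code{"max"}.
#' @return a [HectareCoverMap-class].
#' @export
mosaicCover <- function(maps, rule = c("mean", "min", "max")) {
  rule <- match.arg(rule)
  stopifnot(length(maps) >= 1L)
  d <- dim(maps[[1]]@cover)
  for (m in maps)
    if (!identical(dim(m@cover), d)) stop("cover grids disagree in shape")
  stackM <- vapply(maps, function(m) as.vector(m@cover),
                   numeric(prod(d)))
  stackM <- matrix(stackM, prod(d), length(maps))
  f <- switch(rule,
              mean = function(v) mean(v, na.rm = TRUE),
              min = function(v) min(v, na.rm = TRUE),
              max = function(v) max(v, na.rm = TRUE))
  out <- apply(stackM, 1, function(v)
    if (all(is.na(v))) NA_real_ else f(v))
  new("HectareCoverMap", cover = matrix(out, d[1], d[2]))
}

#' Total mapped extent in hectares
#'
#' Sum of proportional cover over valid hectare cells (each cell is 1 ha).
#'
#' @param cover a [HectareCoverMap-class].
#' @return extent in hectares.
#' @export
totalExtent <- function(cover) {
  stopifnot(is(cover, "HectareCoverMap"))
  sum(cover@cover, na.rm = TRUE)
}
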