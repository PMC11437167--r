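## Synthetic scene generator: labelled landscapes and multi-temporal
## 13-band passes with the statistical structure the analysis assumes --
## class-specific seasonal phenology, rare contiguous reedbed patches,
## spectrally overlapping confusion classes, clouds and displaced shadows,
## integer mis-registration and per-pass gain/offset reflectance error.

#' Default season windows for the two workflow variants
#'
#' The two-season workflow uses a 'green' summer (June--September) and a
#' 'brown' winter (November--April) with a gap month either side; the
#' four-season variant uses February--March, June--July, August--September
#' and November--December.
#'
#' @param workflow \code{"hpc_two_season"} or \code{"gee_four_season"}.
#' @return named list of \code{c(startMonth, endMonth)}.
#' @export
defaultSeasonWindows <- function(workflow = c("hpc_two_season",
                                              "gee_four_season")) {
  workflow <- match.arg(workflow)
  if (workflow == "hpc_two_season")
    list(summer = c(6L, 9L), winter = c(11L, 4L))
  else
    list(feb_mar = c(2L, 3L), jun_jul = c(6L, 7L),
         aug_sep = c(8L, 9L), nov_dec = c(11L, 12L))
}

#' Phenology of one land-cover class
#'
#' @param class class label.
#' @param seasonMeans numeric matrix (seasons x 13 bands) of mean
#'   reflectance in \[0, 1\], rows named by season, columns by [S2_BANDS].
#' @param bandSd per-band reflectance standard deviation (length 13 or 1).
#' @param latitudeShift phenology delay in days per km northing; positive
#'   values make the 'green' phase later further north.
#' @return a \code{classPhenology} list.
#' @export
classPhenology <- function(class, seasonMeans, bandSd = 0.02,
                           latitudeShift = 0) {
  seasonMeans <- as.matrix(seasonMeans)
  if (ncol(seasonMeans) != 13L)
    stop("seasonMeans must have 13 band columns")
  if (is.null(colnames(seasonMeans))) colnames(seasonMeans) <- S2_BANDS
  if (any(seasonMeans < 0 | seasonMeans > 1))
    stop("seasonMeans entries must lie in [0, 1]")
  bandSd <- rep(bandSd, length.out = 13L)
  if (any(bandSd < 0)) stop("bandSd must be non-negative")
  structure(list(class = class, seasonMeans = seasonMeans,
                 bandSd = bandSd, latitudeShift = latitudeShift),
            class = "classPhenology")
}

## Spectral archetypes (13 bands, B1..B12 incl. B8A). Free parameters of the
## simulator: chosen as plausible surface reflectances, not fitted to any
## observed scene. 'green' = photosynthetically active canopy; 'brown' =
## senescent canopy over a wet or bare base; arable's brown phase is
## deliberately close to reedbed's to act as the confusion class.
.spectralArchetypes <- function() {
  list(
    water_any    = c(.09, .07, .06, .04, .03, .02, .02, .02, .02, .01, .01, .01, .01),
    reed_green   = c(.08, .04, .08, .05, .12, .28, .38, .45, .47, .20, .02, .18, .09),
    reed_brown   = c(.09, .08, .10, .14, .16, .15, .15, .15, .15, .08, .02, .20, .15),
    grass_green  = c(.08, .06, .09, .06, .13, .26, .33, .40, .42, .18, .02, .20, .11),
    grass_brown  = c(.08, .06, .08, .07, .12, .20, .26, .32, .33, .15, .02, .18, .10),
    arable_green = c(.08, .05, .08, .05, .12, .27, .36, .44, .46, .19, .02, .19, .10),
    arable_brown = c(.09, .075, .10, .135, .155, .15, .155, .16, .16, .08, .02, .21, .16))
}

## A window is 'green' if the majority of its months fall in May-September.
.windowPhase <- function(window) {
  m <- windowMonths(window)
  if (mean(m %in% 5:9) >= 0.5) "green" else "brown"
}

#' Default class phenology table
#'
#' Builds per-season band means for the standard synthetic classes
#' (\code{water}, \code{grassland}, \code{arable}, \code{reedbed}) under the
#' given season windows. Each season inherits the class's 'green' or
#' 'brown' archetype according to its calendar months (piecewise-constant
#' phenology). Reedbed is green in summer and brown (senescent over a
#' flooded base, hence depressed NIR) in winter; grassland stays green-ish
#' year round; arable mimics reedbed in both phases and is the confusion
#' class.
#'
#' @param seasonWindows named list of month windows (see
#'   [defaultSeasonWindows()]).
#' @param classes subset of the standard classes to include.
#' @param bandSd per-band noise standard deviation (reflectance units).
#' @param latitudeShift days of phenological delay per km northing.
#' @return named list of [classPhenology()] entries.
#' @export
defaultPhenology <- function(seasonWindows = defaultSeasonWindows(),
                             classes = c("water", "grassland", "arable",
                                         "reedbed"),
                             bandSd = 0.02, latitudeShift = 0) {
  arch <- .spectralArchetypes()
  phases <- vapply(seasonWindows, .windowPhase, character(1))
  pick <- function(greenKey, brownKey) {
    m <- t(vapply(phases, function(ph)
      if (ph == "green") arch[[greenKey]] else arch[[brownKey]],
      numeric(13)))
    rownames(m) <- names(seasonWindows)
    colnames(m) <- S2_BANDS
    m
  }
  defs <- list(
    water     = pick("water_any", "water_any"),
    grassland = pick("grass_green", "grass_brown"),
    arable    = pick("arable_green", "arable_brown"),
    reedbed   = pick("reed_green", "reed_brown"))
  out <- lapply(classes, function(cl)
    classPhenology(cl, defs[[cl]], bandSd = bandSd,
                   latitudeShift = if (cl == "reedbed") latitudeShift else 0))
  names(out) <- classes
  out
}

#' Specification of a synthetic landscape
#'
#' @param nRows,nCols pixel counts (10 m pixels).
#' @param classFractions named target area fractions summing to 1; the
#'   reedbed fraction must stay below 0.05 (the rare-class regime).
#' @param reedPatchSize mean reedbed patch area in pixels.
#' @param patchSize mean patch area (pixels) for the other non-background
#'   classes.
#' @param demParams list with \code{base} altitude (m), \code{gradient}
#'   (m of altitude per m of northing) and \code{hillAmplitude} /
#'   \code{hillPeriod} (m / pixels) of the sinusoidal relief.
#' @param seed integer RNG seed.
#' @return a \code{landscapeSpec} list.
#' @export
landscapeSpec <- function(nRows, nCols,
                          classFractions = c(water = 0.05, grassland = 0.64,
                                             arable = 0.30, reedbed = 0.01),
                          reedPatchSize = 80, patchSize = 600,
                          demParams = list(base = 20, gradient = 0.01,
                                           hillAmplitude = 15,
                                           hillPeriod = 100),
                          seed = 1L) {
  if (nRows < 1 || nCols < 1) stop("zero-area grid")
  if (abs(sum(classFractions) - 1) > 1e-9)
    stop("class fractions must sum to 1")
  if (any(classFractions < 0)) stop("class fractions must be non-negative")
  reedFrac <- if ("reedbed" %in% names(classFractions))
    classFractions[["reedbed"]] else 0
  if (reedFrac >= 0.05)
    stop("reedbed fraction must stay below 0.05 (rare-class regime)")
  structure(list(nRows = as.integer(nRows), nCols = as.integer(nCols),
                 classFractions = classFractions,
                 reedPatchSize = reedPatchSize, patchSize = patchSize,
                 demParams = demParams, seed = as.integer(seed)),
            class = "landscapeSpec")
}

#' Specification of one synthetic acquisition
#'
#' @param date acquisition date (coerced with [as.Date()]).
#' @param cloudFraction,shadowFraction target area fractions of cloud and of
#'   cloud shadow in \[0, 1\].
#' @param shift integer \code{c(dx, dy)} mis-registration, components in
#'   \[-3, 3\] (dx = columns east, dy = rows south).
#' @param gain per-band multiplicative reflectance error (> 0; length 1 or
#'   13).
#' @param offset per-band additive haze in reflectance units (>= 0; length 1
#'   or 13).
#' @param seed optional integer seed for this pass's noise, clouds and
#'   shadows.
#' @return a \code{passSpec} list.
#' @export
passSpec <- function(date, cloudFraction = 0, shadowFraction = 0,
                     shift = c(0L, 0L), gain = 1, offset = 0, seed = NULL) {
  shift <- as.integer(round(shift))
  if (length(shift) != 2L || any(abs(shift) > 3L))
    stop("shift components must be integers in [-3, 3]")
  gain <- rep(gain, length.out = 13L)
  offset <- rep(offset, length.out = 13L)
  if (any(gain <= 0)) stop("gain must be positive")
  if (any(offset < 0)) stop("offset must be non-negative")
  if (cloudFraction < 0 || cloudFraction > 1 ||
      shadowFraction < 0 || shadowFraction > 1)
    stop("cloud and shadow fractions must lie in [0, 1]")
  structure(list(date = as.Date(date), cloudFraction = cloudFraction,
                 shadowFraction = shadowFraction, shift = shift,
                 gain = gain, offset = offset,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "passSpec")
}

#' Generate a labelled landscape and its digital elevation model
#'
#' Non-background classes are laid down as contiguous patches by seeded
#' region growing from Poisson-placed seeds until each class reaches its
#' target pixel count; the largest-fraction class fills the remainder. The
#' DEM combines a base altitude, a south-to-north gradient and sinusoidal
#' relief. Deterministic given the spec's seed.
#'
#' @param spec a [landscapeSpec()].
#' @return list with \code{classMap} (character matrix) and \code{dem}
#'   (numeric matrix, metres).
#' @export
generateLandscape <- function(spec) {
  stopifnot(inherits(spec, "landscapeSpec"))
  set.seed(spec$seed)
  nr <- spec$nRows; nc <- spec$nCols; n <- nr * nc
  fr <- spec$classFractions
  background <- names(fr)[which.max(fr)]
  others <- setdiff(names(fr)[fr > 0], background)
  ## grow small classes first so they are not crowded out
  others <- others[order(fr[others])]

  classIdx <- rep.int(match(background, names(fr)), n)
  assigned <- rep.int(FALSE, n)

  growClass <- function(className, classIdx, assigned) {
    target <- round(fr[[className]] * n)
    if (target < 1) return(list(classIdx, assigned))
    meanPatch <- if (className == "reedbed") spec$reedPatchSize else spec$patchSize
    nSeeds <- max(1L, as.integer(round(target / meanPatch)))
    free <- which(!assigned)
    if (length(free) == 0L) return(list(classIdx, assigned))
    seeds <- sample(free, min(nSeeds, length(free)))
    ci <- match(className, names(fr))
    buf <- integer(max(16L, 8L * nSeeds))
    len <- 0L
    for (s in seeds) { len <- len + 1L; buf[len] <- s }
    placed <- 0L
    while (placed < target && len > 0L) {
      j <- sample.int(len, 1L)
      cell <- buf[j]
      buf[j] <- buf[len]; len <- len - 1L
      if (assigned[cell]) next
      assigned[cell] <- TRUE
      classIdx[cell] <- ci
      placed <- placed + 1L
      r <- ((cell - 1L) %% nr) + 1L
      nb <- c(if (r > 1L) cell - 1L, if (r < nr) cell + 1L,
              if (cell > nr) cell - nr, if (cell <= n - nr) cell + nr)
      nb <- nb[!assigned[nb]]
      if (length(nb)) {
        if (len + length(nb) > length(buf)) buf <- c(buf, integer(length(buf)))
        buf[(len + 1L):(len + length(nb))] <- nb
        len <- len + length(nb)
      }
    }
    list(classIdx, assigned)
  }

  for (cl in others) {
    res <- growClass(cl, classIdx, assigned)
    classIdx <- res[[1]]; assigned <- res[[2]]
  }
  classMap <- matrix(names(fr)[classIdx], nr, nc)

  dp <- spec$demParams
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  dem <- dp$base + dp$gradient * (nr - rows) * 10 +
    dp$hillAmplitude * sin(2 * pi * rows / dp$hillPeriod) *
      sin(2 * pi * cols / dp$hillPeriod)
  dem <- pmax(dem, 0)
  list(classMap = classMap, dem = dem)
}

#' Simulate one 13-band acquisition of a labelled landscape
#'
#' Per-pixel reflectance is \code{gain * (class seasonal mean + Gaussian
#' band noise, truncated to \[0, 1\]) + offset}; cloud pixels are then
#' overwritten with bright reflectance (all bands >= 0.6 before gain),
#' shadow pixels (displaced copies of the cloud blobs; invisible to the
#' cloud truth, mirroring a cloud classifier that cannot see shadow) are
#' darkened by 60\%, the final grid is clamped to \[0, 1\] and translated
#' by the spec's mis-registration shift, with the exposed margin flagged
#' invalid.
#'
#' @param classMap character matrix of class labels.
#' @param dem altitude matrix (m); reserved for terrain-dependent effects.
#' @param phenology named list of [classPhenology()] covering every class
#'   present in \code{classMap}.
#' @param spec a [passSpec()].
#' @param seasonWindows named month windows mapping the pass date to a
#'   season.
#' @return list with \code{pass} ([MultibandPass-class]) and
#'   \code{cloudTruth} (logical matrix, aligned to the delivered pass).
#' @export
simulatePass <- function(classMap, dem, phenology, spec,
                         seasonWindows = defaultSeasonWindows()) {
  stopifnot(inherits(spec, "passSpec"))
  classes <- unique(as.vector(classMap))
  missing <- setdiff(classes, names(phenology))
  if (length(missing))
    stop("no phenology for class(es): ", paste(missing, collapse = ", "))
  if (!is.null(spec$seed)) set.seed(spec$seed)

  nr <- nrow(classMap); nc <- ncol(classMap); n <- nr * nc
  classIdx <- match(as.vector(classMap), names(phenology))

  ## season per row: the phenology delay shifts the effective date with
  ## northing (row 1 = north edge)
  latShifts <- vapply(phenology, function(p) p$latitudeShift, numeric(1))
  maxShift <- max(abs(latShifts))
  baseSeason <- seasonForDate(spec$date, seasonWindows)
  seasonByRowClass <- function(lat) {
    if (lat == 0) return(rep(baseSeason, nr))
    northKm <- (nr - seq_len(nr)) * 0.01
    seasonForDate(spec$date - round(lat * northKm), seasonWindows)
  }
  if (maxShift == 0 && is.na(baseSeason))
    stop("pass date ", format(spec$date),
         " maps to no season under the given windows ",
         "(piecewise-constant phenology has no interpolation)")

  refl <- array(NA_real_, c(nr, nc, 13L),
                dimnames = list(NULL, NULL, S2_BANDS))
  for (ci in seq_along(phenology)) {
    sel <- classIdx == ci
    if (!any(sel)) next
    ph <- phenology[[ci]]
    rowSeason <- seasonByRowClass(ph$latitudeShift)
    if (anyNA(rowSeason))
      stop("pass date ", format(spec$date),
           " maps to no season for class '", ph$class,
           "' under the given windows")
    seasonOfPixel <- rowSeason[((which(sel) - 1L) %% nr) + 1L]
    mu <- ph$seasonMeans[seasonOfPixel, , drop = FALSE]
    for (b in seq_len(13L)) {
      v <- mu[, b]
      if (ph$bandSd[b] > 0) v <- v + rnorm(length(v), 0, ph$bandSd[b])
      v <- pmin(pmax(v, 0), 1)
      refl[, , b][sel] <- spec$gain[b] * v + spec$offset[b]
    }
  }

  ## clouds: bright blobs; shadows: displaced darkened copies
  cloudMask <- makeBlobMask(nr, nc, spec$cloudFraction)
  shadowSrc <- if (spec$cloudFraction > 0) cloudMask
               else makeBlobMask(nr, nc, spec$shadowFraction)
  shadowMask <- if (spec$shadowFraction > 0)
    shiftContent(shadowSrc, 8L, 8L, fill = FALSE) & !cloudMask
  else matrix(FALSE, nr, nc)

  if (any(cloudMask)) {
    idx <- which(cloudMask)
    for (b in seq_len(13L)) {
      cb <- 0.6 + 0.35 * runif(length(idx))
      refl[, , b][idx] <- spec$gain[b] * cb + spec$offset[b]
    }
  }
  if (any(shadowMask)) {
    idx <- which(shadowMask)
    for (b in seq_len(13L)) refl[, , b][idx] <- 0.4 * refl[, , b][idx]
  }
  refl <- pmin(pmax(refl, 0), 1)

  valid <- matrix(TRUE, nr, nc)
  dx <- spec$shift[1]; dy <- spec$shift[2]
  if (dx != 0L || dy != 0L) {
    for (b in seq_len(13L)) refl[, , b] <- shiftContent(refl[, , b], dx, dy)
    valid <- shiftContent(valid, dx, dy, fill = FALSE)
    cloudMask <- shiftContent(cloudMask, dx, dy, fill = FALSE)
  }
  valid <- valid & !is.na(refl[, , 1])

  pass <- new("MultibandPass", bands = refl, date = spec$date, valid = valid)
  list(pass = pass, cloudTruth = cloudMask)
}

## Truth polygons: connected patches per class, eroded one pixel so polygon
## edges sit away from class boundaries; patches larger than maxPolyPixels
## are split into 30 x 30-aligned tiles to yield several polygons.
makeTruthPolygons <- function(classMap, maxPolyPixels = 900L, tile = 30L) {
  nr <- nrow(classMap); nc <- ncol(classMap)
  brush <- matrix(1L, 3L, 3L)
  out <- vector("list", 64L); k <- 0L
  for (cl in sort(unique(as.vector(classMap)))) {
    mask <- (classMap == cl) * 1
    lab <- EBImage::imageData(EBImage::bwlabel(mask))
    eroded <- EBImage::imageData(EBImage::erode(mask, brush)) > 0
    for (patch in setdiff(unique(as.vector(lab)), 0)) {
      cells <- which(lab == patch & eroded)
      if (length(cells) == 0L) next
      rows <- ((cells - 1L) %% nr) + 1L
      cols <- ((cells - 1L) %/% nr) + 1L
      if (length(cells) > maxPolyPixels) {
        tileId <- paste((rows - 1L) %/% tile, (cols - 1L) %/% tile)
        pieces <- split(seq_along(cells), tileId)
      } else {
        pieces <- list(seq_along(cells))
      }
      for (pc in pieces) {
        if (length(pc) == 0L) next
        k <- k + 1L
        if (k > length(out)) out <- c(out, vector("list", length(out)))
        out[[k]] <- data.frame(
          polygon = sprintf("%s_%03d", cl, k), class = cl,
          row = rows[pc], col = cols[pc], stringsAsFactors = FALSE)
      }
    }
  }
  if (k == 0L)
    return(data.frame(polygon = character(), class = character(),
                      row = integer(), col = integer()))
  do.call(rbind, out[seq_len(k)])
}

#' Generate a complete labelled synthetic dataset
#'
#' Builds the landscape, simulates every pass, and derives truth polygons by
#' vectorising the class patches eroded by one pixel (so training polygons
#' avoid class boundaries). Season windows with no pass are recorded as a
#' note on the returned scene, which is still produced.
#'
#' @param landscape a [landscapeSpec()].
#' @param passSpecs list of [passSpec()].
#' @param phenology named list of [classPhenology()]; defaults to
#'   [defaultPhenology()] under \code{seasonWindows}.
#' @param seasonWindows named month windows used for phenology.
#' @return a [SyntheticScene-class].
#' @export
generateDataset <- function(landscape, passSpecs,
                            phenology = NULL,
                            seasonWindows = defaultSeasonWindows()) {
  stopifnot(inherits(landscape, "landscapeSpec"))
  if (is.null(phenology)) {
    phenology <- defaultPhenology(
      seasonWindows, classes = names(landscape$classFractions))
  }
  land <- generateLandscape(landscape)

  seeds <- deriveSeeds(landscape$seed, length(passSpecs))
  passes <- vector("list", length(passSpecs))
  cloudTruth <- vector("list", length(passSpecs))
  for (i in seq_along(passSpecs)) {
    ps <- passSpecs[[i]]
    if (is.null(ps$seed)) ps$seed <- seeds[i]
    sim <- simulatePass(land$classMap, land$dem, phenology, ps,
                        seasonWindows)
    passes[[i]] <- sim$pass
    cloudTruth[[i]] <- sim$cloudTruth
    passSpecs[[i]] <- ps
  }

  notes <- character()
  dates <- as.Date(vapply(passSpecs, function(p) format(p$date), character(1)))
  assigned <- seasonForDate(dates, seasonWindows)
  for (nm in names(seasonWindows)) {
    if (!any(assigned == nm, na.rm = TRUE)) {
      msg <- paste0("season '", nm, "' has no pass")
      warning(msg)
      notes <- c(notes, msg)
    }
  }

  polygons <- makeTruthPolygons(land$classMap)
  new("SyntheticScene", classMap = land$classMap, dem = land$dem,
      passes = passes, passSpecs = passSpecs, cloudTruth = cloudTruth,
      polygons = polygons, seasonWindows = seasonWindows,
      phenology = phenology, notes = notes)
}

#' Labelled cloud/clear training polygons from a cloud-truth grid
#'
#' Vectorises the cloud blobs of one pass into 'cloud' polygons and carves
#' clear-sky tiles into 'clear' polygons, for training the cloud
#' classifier.
#'
#' @param cloudTruth logical matrix of true cloud pixels.
#' @param nClearTiles number of clear-sky tiles to carve.
#' @param tile tile edge (pixels).
#' @param seed RNG seed for tile placement.
#' @return data.frame with columns \code{polygon}, \code{class}
#'   (\code{cloud}/\code{clear}), \code{row}, \code{col}.
#' @export
cloudTrainingPolygons <- function(cloudTruth, nClearTiles = 8L, tile = 20L,
                                  seed = 1L) {
  nr <- nrow(cloudTruth); nc <- ncol(cloudTruth)
  set.seed(seed)
  lab <- EBImage::imageData(EBImage::bwlabel(cloudTruth * 1))
  out <- list()
  for (patch in setdiff(unique(as.vector(lab)), 0)) {
    cells <- which(lab == patch)
    out[[length(out) + 1L]] <- data.frame(
      polygon = sprintf("cloud_%03d", patch), class = "cloud",
      row = ((cells - 1L) %% nr) + 1L, col = ((cells - 1L) %/% nr) + 1L,
      stringsAsFactors = FALSE)
  }
  placed <- 0L; tries <- 0L
  while (placed < nClearTiles && tries < 200L) {
    tries <- tries + 1L
    r0 <- sample.int(max(1L, nr - tile), 1L)
    c0 <- sample.int(max(1L, nc - tile), 1L)
    rows <- r0:(min(nr, r0 + tile - 1L))
    cols <- c0:(min(nc, c0 + tile - 1L))
    if (any(cloudTruth[rows, cols])) next
    placed <- placed + 1L
    grid <- expand.grid(row = rows, col = cols)
    out[[length(out) + 1L]] <- data.frame(
      polygon = sprintf("clear_%03d", placed), class = "clear",
      row = grid$row, col = grid$col, stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(polygon = character(), class = character(),
                      row = integer(), col = integer()))
  do.call(rbind, out)
}
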