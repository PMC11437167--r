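## File interchange. Rasters travel as multi-page float32 TIFF with a JSON
## sidecar (band names and per-band affine value encoding; TIFF float pages
## here carry [0,1] only and do not preserve NA, so each band is packed into
## [0.1, 0.9] with 0 as the NA sentinel). Vectors travel as GeoJSON
## (rectilinear multipolygons of pixel runs, property "class"), tables as
## CSV. Pixel (row 1, col 1) is the north-west corner; GeoJSON coordinates
## are metres with x east and y north of the south-west scene corner.

.sidecarPath <- function(path) paste0(path, ".json")

#' Write grids as multi-page TIFF with a JSON value-encoding sidecar
#'
#' @param x matrix, 3-d array (layers on the third dimension) or list of
#'   matrices.
#' @param path output TIFF path; the sidecar is written at
#'   \code{<path>.json}.
#' @param layerNames layer names; defaults to array/list names.
#' @return \code{path}, invisibly.
#' @export
writeRasterTiff <- function(x, path, layerNames = NULL) {
  if (is.matrix(x)) x <- list(x)
  if (is.array(x) && length(dim(x)) == 3L) {
    nm <- dimnames(x)[[3]]
    x <- lapply(seq_len(dim(x)[3]), function(i) x[, , i])
    names(x) <- nm
  }
  if (is.null(layerNames)) layerNames <- names(x)
  if (is.null(layerNames)) layerNames <- sprintf("layer%02d", seq_along(x))
  enc <- vector("list", length(x))
  meta <- vector("list", length(x))
  for (i in seq_along(x)) {
    m <- x[[i]]
    storage.mode(m) <- "double"
    fin <- is.finite(m)
    if (any(fin)) {
      lo <- min(m[fin]); hi <- max(m[fin])
    } else {
      lo <- 0; hi <- 1
    }
    if (hi <= lo) hi <- lo + 1
    e <- 0.1 + 0.8 * (m - lo) / (hi - lo)
    e[!fin] <- 0
    enc[[i]] <- e
    meta[[i]] <- list(name = layerNames[i], lo = lo, hi = hi)
  }
  tiff::writeTIFF(enc, path, bits.per.sample = 32L)
  jsonlite::write_json(
    list(layers = meta, nrow = nrow(x[[1]]), ncol = ncol(x[[1]])),
    .sidecarPath(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read grids written by [writeRasterTiff()]
#'
#' @param path TIFF path (sidecar expected at \code{<path>.json}).
#' @return named list of matrices.
#' @export
readRasterTiff <- function(path) {
  meta <- jsonlite::read_json(.sidecarPath(path), simplifyVector = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  out <- vector("list", length(pages))
  for (i in seq_along(pages)) {
    m <- pages[[i]]
    li <- meta$layers[[i]]
    v <- (m - 0.1) / 0.8 * (li$hi - li$lo) + li$lo
    v[m < 0.05] <- NA_real_
    out[[i]] <- v
  }
  names(out) <- vapply(meta$layers, function(l) l$name, character(1))
  out
}

#' Write a multiband pass (bands TIFF + validity in the sidecar scheme)
#' @param pass a [MultibandPass-class].
#' @param path TIFF path.
#' @return \code{path}, invisibly.
#' @export
writePass <- function(pass, path) {
  layers <- lapply(seq_len(13L), function(b) {
    m <- pass@bands[, , b]
    m[!pass@valid] <- NA_real_
    m
  })
  names(layers) <- S2_BANDS
  writeRasterTiff(layers, path)
}

#' Read a multiband pass written by [writePass()]
#' @param path TIFF path.
#' @param date acquisition date to attach.
#' @return a [MultibandPass-class].
#' @export
readPass <- function(path, date) {
  layers <- readRasterTiff(path)
  stopifnot(identical(names(layers), S2_BANDS))
  d <- dim(layers[[1]])
  bands <- array(NA_real_, c(d, 13L), dimnames = list(NULL, NULL, S2_BANDS))
  for (b in seq_len(13L)) bands[, , b] <- layers[[b]]
  valid <- !is.na(bands[, , 1])
  bands[is.na(bands)] <- 0
  new("MultibandPass", bands = bands, date = as.Date(date), valid = valid)
}

#' Write truth polygons as GeoJSON
#'
#' Each polygon becomes a MultiPolygon of its horizontal pixel runs
#' (rectilinear geometry), with properties \code{polygon} and
#' \code{class}. Coordinates are metres; pixel edge \code{cellSize}.
#'
#' @param polygons data.frame with columns \code{polygon}, \code{class},
#'   \code{row}, \code{col}.
#' @param path output path.
#' @param nRows scene row count (sets the northing origin).
#' @param cellSize pixel edge (m).
#' @return \code{path}, invisibly.
#' @export
writePolygonsGeoJSON <- function(polygons, path, nRows, cellSize = 10) {
  feats <- lapply(split(polygons, polygons$polygon), function(sub) {
    rings <- list()
    for (r in sort(unique(sub$row))) {
      cls <- sort(sub$col[sub$row == r])
      runStart <- cls[c(TRUE, diff(cls) != 1L)]
      runEnd <- cls[c(diff(cls) != 1L, TRUE)]
      for (k in seq_along(runStart)) {
        x0 <- (runStart[k] - 1) * cellSize; x1 <- runEnd[k] * cellSize
        y0 <- (nRows - r) * cellSize; y1 <- (nRows - r + 1) * cellSize
        rings[[length(rings) + 1L]] <- list(list(
          c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1), c(x0, y0)))
      }
    }
    list(type = "Feature",
         properties = list(polygon = sub$polygon[1], class = sub$class[1]),
         geometry = list(type = "MultiPolygon", coordinates = rings))
  })
  names(feats) <- NULL
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read polygons written by [writePolygonsGeoJSON()]
#'
#' Rasterises each rectilinear ring back to pixel membership.
#'
#' @param path GeoJSON path.
#' @param nRows scene row count.
#' @param cellSize pixel edge (m).
#' @return data.frame with columns \code{polygon}, \code{class},
#'   \code{row}, \code{col}.
#' @export
readPolygonsGeoJSON <- function(path, nRows, cellSize = 10) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  out <- list()
  for (ft in gj$features) {
    pid <- ft$properties$polygon
    cls <- ft$properties$class
    for (ring in ft$geometry$coordinates) {
      pts <- do.call(rbind, lapply(ring[[1]], function(p)
        c(p[[1]], p[[2]])))
      x0 <- min(pts[, 1]); x1 <- max(pts[, 1])
      y0 <- min(pts[, 2]); y1 <- max(pts[, 2])
      cols <- (round(x0 / cellSize) + 1L):round(x1 / cellSize)
      rows <- (nRows - round(y1 / cellSize) + 1L):(nRows - round(y0 / cellSize))
      grid <- expand.grid(row = rows, col = cols)
      out[[length(out) + 1L]] <- data.frame(
        polygon = pid, class = cls, row = grid$row, col = grid$col,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write a synthetic scene to a directory
#'
#' Lays out the class map and DEM (TIFF + sidecar), every pass and its
#' cloud truth, the truth polygons (GeoJSON) and a CSV pass manifest
#' (date, cloud/shadow fractions, shift, mean gain/offset, seed).
#'
#' @param scene a [SyntheticScene-class].
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeScene <- function(scene, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  classes <- sort(unique(as.vector(scene@classMap)))
  classIdx <- matrix(match(scene@classMap, classes), nrow(scene@classMap))
  writeRasterTiff(list(class_index = classIdx), file.path(dir, "class_map.tif"))
  jsonlite::write_json(list(classes = classes),
                       file.path(dir, "class_map_levels.json"),
                       auto_unbox = TRUE)
  writeRasterTiff(list(dem = scene@dem), file.path(dir, "dem.tif"))
  man <- data.frame()
  for (i in seq_along(scene@passes)) {
    ps <- scene@passSpecs[[i]]
    writePass(scene@passes[[i]], file.path(dir, sprintf("pass_%02d.tif", i)))
    writeRasterTiff(list(cloud = scene@cloudTruth[[i]] * 1),
                    file.path(dir, sprintf("cloud_truth_%02d.tif", i)))
    man <- rbind(man, data.frame(
      pass = i, date = format(ps$date), cloud_fraction = ps$cloudFraction,
      shadow_fraction = ps$shadowFraction, dx = ps$shift[1],
      dy = ps$shift[2], gain = mean(ps$gain), offset = mean(ps$offset),
      seed = if (is.null(ps$seed)) NA_integer_ else ps$seed))
  }
  write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  writePolygonsGeoJSON(scene@polygons, file.path(dir, "polygons.geojson"),
                       nRows = nrow(scene@classMap))
  jsonlite::write_json(
    list(seasonWindows = scene@seasonWindows, notes = scene@notes),
    file.path(dir, "scene_meta.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a scene directory written by [writeScene()]
#'
#' Phenology and pass specifications are not round-tripped beyond the
#' manifest; the returned scene carries everything the pipeline consumes.
#'
#' @param dir scene directory.
#' @return a [SyntheticScene-class].
#' @export
readScene <- function(dir) {
  levels <- unlist(jsonlite::read_json(
    file.path(dir, "class_map_levels.json"), simplifyVector = TRUE))
  classIdx <- readRasterTiff(file.path(dir, "class_map.tif"))[[1]]
  classMap <- matrix(levels[round(classIdx)], nrow(classIdx))
  dem <- readRasterTiff(file.path(dir, "dem.tif"))[[1]]
  meta <- jsonlite::read_json(file.path(dir, "scene_meta.json"),
                              simplifyVector = FALSE)
  windows <- lapply(meta$seasonWindows, function(w) as.integer(unlist(w)))
  man <- read.csv(file.path(dir, "manifest.csv"))
  passes <- list(); cloudTruth <- list(); specs <- list()
  for (i in man$pass) {
    passes[[i]] <- readPass(file.path(dir, sprintf("pass_%02d.tif", i)),
                            man$date[i])
    ct <- readRasterTiff(file.path(dir, sprintf("cloud_truth_%02d.tif", i)))[[1]]
    ct[is.na(ct)] <- 0
    cloudTruth[[i]] <- ct > 0.5
    specs[[i]] <- passSpec(man$date[i], man$cloud_fraction[i],
                           man$shadow_fraction[i],
                           shift = c(man$dx[i], man$dy[i]),
                           gain = man$gain[i], offset = man$offset[i],
                           seed = if (is.na(man$seed[i])) NULL else man$seed[i])
  }
  polygons <- readPolygonsGeoJSON(file.path(dir, "polygons.geojson"),
                                  nRows = nrow(classMap))
  new("SyntheticScene", classMap = classMap, dem = dem, passes = passes,
      passSpecs = specs, cloudTruth = cloudTruth, polygons = polygons,
      seasonWindows = windows, phenology = list(),
      notes = as.character(unlist(meta$notes)))
}
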