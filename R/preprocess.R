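## Pre-processing: reflectance-domain dark-object subtraction, random-forest
## cloud masking on the 13 raw bands, integer co-registration by normalised
## cross-correlation, and per-season per-pixel median compositing.

#' Dark-object subtraction
#'
#' Image-based atmospheric correction: per band, the given low percentile of
#' the valid pixels (the 'dark object', an estimate of additive path
#' radiance/haze) is subtracted and the result clamped at zero. The 1st
#' percentile rather than the minimum is used by default to resist
#' single-pixel artefacts. The validity mask is unchanged.
#'
#' @param pass a [MultibandPass-class] with at least one valid pixel.
#' @param percentile fraction in \[0, 1\]; 0 subtracts the band minimum.
#' @return corrected [MultibandPass-class].
#' @export
darkObjectSubtract <- function(pass, percentile = 0.01) {
  stopifnot(is(pass, "MultibandPass"))
  if (!any(pass@valid)) stop("pass has no valid pixels")
  bands <- pass@bands
  v <- pass@valid
  for (b in seq_len(13L)) {
    vals <- bands[, , b][v]
    vals <- vals[!is.na(vals)]
    dark <- quantile(vals, percentile, names = FALSE, type = 7)
    bands[, , b] <- pmax(bands[, , b] - dark, 0)
  }
  new("MultibandPass", bands = bands, date = pass@date, valid = v)
}

#' Train the random-forest cloud classifier
#'
#' A random forest (by default 500 trees, three variables tried at each
#' split) trained on all 13 bands at pixels drawn from labelled cloud /
#' clear polygons. Deterministic given \code{seed}.
#'
#' @param passes a [MultibandPass-class] or list thereof; the \code{pass}
#'   column of \code{polygons} (default 1) selects which pass each polygon's
#'   pixels are read from.
#' @param polygons data.frame with columns \code{polygon}, \code{class}
#'   (exactly two classes, e.g. \code{cloud} / \code{clear}), \code{row},
#'   \code{col} and optionally \code{pass}.
#' @param nTrees,varsPerSplit forest size and variables tried per split.
#' @param maxPixelsPerPolygon cap on pixels drawn per polygon.
#' @param seed RNG seed.
#' @return a [CloudModel-class] carrying the forest and its out-of-bag
#'   error estimate.
#' @export
trainCloudModel <- function(passes, polygons, nTrees = 500L,
                            varsPerSplit = 3L,
                            maxPixelsPerPolygon = 400L, seed = 1L) {
  if (is(passes, "MultibandPass")) passes <- list(passes)
  if (is.null(polygons$pass)) polygons$pass <- 1L
  if (length(unique(polygons$class)) < 2L)
    stop("cloud training requires two classes (cloud and non-cloud)")
  set.seed(seed)
  rows <- split(seq_len(nrow(polygons)), polygons$polygon)
  feats <- list(); labs <- list()
  for (idx in rows) {
    if (length(idx) > maxPixelsPerPolygon)
      idx <- sample(idx, maxPixelsPerPolygon)
    p <- passes[[polygons$pass[idx[1]]]]
    cells <- cbind(polygons$row[idx], polygons$col[idx])
    X <- vapply(seq_len(13L), function(b) p@bands[, , b][cells],
                numeric(length(idx)))
    feats[[length(feats) + 1L]] <- X
    labs[[length(labs) + 1L]] <- polygons$class[idx]
  }
  X <- do.call(rbind, feats)
  colnames(X) <- S2_BANDS
  y <- factor(unlist(labs))
  keep <- stats::complete.cases(X)
  X <- X[keep, , drop = FALSE]; y <- y[keep]
  set.seed(seed)
  rf <- randomForest::randomForest(X, y, ntree = nTrees,
                                   mtry = varsPerSplit)
  oob <- unname(rf$err.rate[nTrees, "OOB"])
  new("CloudModel", forest = rf, oobError = oob)
}

#' Out-of-bag error of a cloud model
#' @param model a [CloudModel-class].
#' @export
oobError <- function(model) model@oobError

#' Mask predicted cloud pixels out of a pass
#'
#' Every valid pixel the model predicts as cloud becomes invalid; all other
#' pixels are untouched.
#'
#' @param pass a [MultibandPass-class].
#' @param model a [CloudModel-class].
#' @param cloudClass label the model uses for cloud.
#' @return the pass with cloud pixels invalidated.
#' @export
maskClouds <- function(pass, model, cloudClass = "cloud") {
  stopifnot(is(pass, "MultibandPass"), is(model, "CloudModel"))
  idx <- which(pass@valid)
  if (length(idx) == 0L) return(pass)
  X <- vapply(seq_len(13L), function(b) pass@bands[, , b][idx],
              numeric(length(idx)))
  colnames(X) <- S2_BANDS
  pred <- predict(model@forest, X)
  valid <- pass@valid
  valid[idx[pred == cloudClass]] <- FALSE
  new("MultibandPass", bands = pass@bands, date = pass@date, valid = valid)
}

#' Estimate the integer mis-registration between two passes
#'
#' Exhaustively scores every integer translation in
#' \code{\[-maxShift, maxShift\]^2} by the normalised cross-correlation
#' (Pearson correlation) of the designated band over the jointly valid
#' overlap, and returns the maximising \code{c(dx, dy)}. Ties are broken by
#' the smallest \code{|dx| + |dy|}, then row-major order over \code{(dy,
#' dx)}. Passes whose valid fraction is below \code{minValidFraction} raise
#' a registration-failure error (condition class
#' \code{reedmapRegistrationFailure}); callers drop such passes.
#'
#' @param reference,secondary [MultibandPass-class] objects on one grid.
#' @param maxShift maximum absolute shift searched per axis (pixels).
#' @param band band used for matching (near-infrared by default: strongest
#'   land contrast).
#' @param minValidFraction failure threshold on the secondary's valid
#'   fraction.
#' @return named integer vector \code{c(dx, dy)} such that the secondary
#'   equals the reference translated by \code{(dx, dy)}.
#' @export
estimateShift <- function(reference, secondary, maxShift = 3L, band = "B8",
                          minValidFraction = 0.03) {
  stopifnot(is(reference, "MultibandPass"), is(secondary, "MultibandPass"))
  if (!identical(dim(reference@valid), dim(secondary@valid)))
    stop("reference and secondary must share grid shape")
  if (validFraction(secondary) < minValidFraction)
    stop(errorCondition(
      sprintf("registration failure: secondary valid fraction %.4f below %.2f",
              validFraction(secondary), minValidFraction),
      class = c("reedmapRegistrationFailure", "error", "condition")))
  refB <- getBand(reference, band); refB[!reference@valid] <- NA
  secB <- getBand(secondary, band); secB[!secondary@valid] <- NA
  nr <- nrow(refB); nc <- ncol(refB)

  cand <- expand.grid(dx = -maxShift:maxShift, dy = -maxShift:maxShift)
  cand <- cand[order(abs(cand$dx) + abs(cand$dy), cand$dy, cand$dx), ]
  best <- c(0L, 0L); bestScore <- -Inf
  for (i in seq_len(nrow(cand))) {
    dx <- cand$dx[i]; dy <- cand$dy[i]
    rr <- max(1L, 1L + dy):min(nr, nr + dy)  # secondary rows
    cc <- max(1L, 1L + dx):min(nc, nc + dx)
    a <- refB[rr - dy, cc - dx]
    b <- secB[rr, cc]
    ok <- !is.na(a) & !is.na(b)
    if (sum(ok) < 25L) next
    av <- a[ok]; bv <- b[ok]
    if (sd(av) == 0 || sd(bv) == 0) next
    score <- cor(av, bv)
    if (score > bestScore + 1e-12) {
      bestScore <- score
      best <- c(dx, dy)
    }
  }
  c(dx = as.integer(best[1]), dy = as.integer(best[2]))
}

#' Undo an estimated mis-registration
#'
#' Translates the pass content by \code{(-dx, -dy)}; the newly exposed
#' margin is flagged invalid.
#'
#' @param pass a [MultibandPass-class].
#' @param shift integer \code{c(dx, dy)} as returned by [estimateShift()].
#' @return the aligned [MultibandPass-class].
#' @export
applyShift <- function(pass, shift) {
  stopifnot(is(pass, "MultibandPass"), length(shift) == 2L)
  dx <- as.integer(round(shift[1])); dy <- as.integer(round(shift[2]))
  if (dx == 0L && dy == 0L) return(pass)
  bands <- pass@bands
  for (b in seq_len(13L)) bands[, , b] <- shiftContent(bands[, , b], -dx, -dy)
  valid <- shiftContent(pass@valid, -dx, -dy, fill = FALSE)
  valid <- valid & !is.na(bands[, , 1])
  new("MultibandPass", bands = bands, date = pass@date, valid = valid)
}

#' Per-season per-pixel median composites
#'
#' Assigns each pass to at most one season by its date, then takes, per
#' pixel and per band, the median over the valid contributing values (even
#' counts average the two central values). Pixels valid in no pass are
#' invalid (coverage 0). The median suppresses transient contamination --
#' in particular cloud shadows, which the cloud classifier cannot see.
#'
#' @param passes list of [MultibandPass-class].
#' @param seasonWindows named list of month windows.
#' @param seasons seasons to composite; defaults to all windows. A
#'   requested season with zero passes is an error naming the season.
#' @return named list of [SeasonalComposite-class].
#' @export
seasonalMedianComposite <- function(passes,
                                    seasonWindows = defaultSeasonWindows(),
                                    seasons = names(seasonWindows)) {
  dates <- as.Date(vapply(passes, function(p) format(p@date), character(1)))
  assigned <- seasonForDate(dates, seasonWindows)
  missing <- seasons[!seasons %in% assigned]
  if (length(missing))
    stop("no passes for season(s): ", paste(missing, collapse = ", "))
  d <- dim(passes[[1]]@valid)
  out <- list()
  for (ss in seasons) {
    members <- passes[which(assigned == ss)]
    n <- length(members)
    bands <- array(NA_real_, c(d, 13L), dimnames = list(NULL, NULL, S2_BANDS))
    cover <- matrix(0L, d[1], d[2])
    for (p in members) cover <- cover + p@valid
    for (b in seq_len(13L)) {
      vals <- vapply(members, function(p) {
        m <- p@bands[, , b]
        m[!p@valid] <- NA_real_
        as.vector(m)
      }, numeric(prod(d)))
      if (n == 1L) med <- vals[, 1] else med <- rowMediansNA(vals)
      bands[, , b] <- matrix(med, d[1], d[2])
    }
    out[[ss]] <- new("SeasonalComposite", season = ss, bands = bands,
                     coverage = cover)
  }
  out
}
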