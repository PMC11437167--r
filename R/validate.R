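## Validation: stratified hectare sampling targeted at predicted reedbed,
## within-hectare cell sampling, a virtual field observer for synthetic
## truth, two-scale confusion metrics, rank AUC, cover regression, the
## false-positive land-cover chi-square, and error-corrected extent.

#' Stratified validation design
#'
#' Hectares are stratified by predicted proportional cover into
#' \code{p = 0}, \code{0 < p <= 1/3-ish}, ... using half-open \code{(low,
#' high]} intervals with \{0\} its own stratum; up to \code{nPerStratum}
#' hectares are drawn per stratum from the scene quadrant richest in
#' non-zero predicted cover, and within each hectare
#' \code{cellsPerClass} predicted-presence plus \code{cellsPerClass}
#' predicted-absence 10 m cells are drawn.
#'
#' @param breaks upper stratum bounds above zero (default 0.33, 0.66, 1).
#' @param nPerStratum hectares per stratum per scene.
#' @param cellsPerClass 10 m cells per predicted class per hectare.
#' @return a \code{validationDesign} list.
#' @export
validationDesign <- function(breaks = c(0.33, 0.66, 1), nPerStratum = 10L,
                             cellsPerClass = 3L) {
  stopifnot(all(diff(breaks) > 0), breaks[length(breaks)] == 1)
  structure(list(breaks = breaks, nPerStratum = as.integer(nPerStratum),
                 cellsPerClass = as.integer(cellsPerClass)),
            class = "validationDesign")
}

#' Stratum label of a predicted cover value
#'
#' @param cover numeric cover values in \[0, 1\].
#' @param breaks upper bounds as in [validationDesign()].
#' @return character labels: \code{"p=0"} or \code{"(lo,hi]"}.
#' @export
coverStratum <- function(cover, breaks = c(0.33, 0.66, 1)) {
  lo <- c(0, breaks[-length(breaks)])
  lab <- sprintf("(%g,%g]", lo, breaks)
  out <- rep(NA_character_, length(cover))
  out[!is.na(cover) & cover == 0] <- "p=0"
  pos <- which(!is.na(cover) & cover > 0)
  if (length(pos)) {
    bin <- findInterval(cover[pos], lo, left.open = TRUE,
                        rightmost.closed = FALSE)
    out[pos] <- lab[pmin(bin, length(lab))]
  }
  out
}

#' Draw validation hectares, stratified by predicted cover
#'
#' Restricts to the geographic quadrant (2 x 2 split of the cover grid)
#' holding the most hectares of non-zero predicted cover (field effort is
#' clustered to cut travel), then draws up to \code{nPerStratum} hectares
#' uniformly per stratum; strata holding fewer qualifying hectares
#' contribute all of them.
#'
#' @param cover a [HectareCoverMap-class].
#' @param design a [validationDesign()].
#' @param seed RNG seed.
#' @return data.frame with columns \code{hectare_id}, \code{row},
#'   \code{col}, \code{stratum}, \code{predicted_cover}.
#' @export
stratifyHectares <- function(cover, design = validationDesign(), seed = 1L) {
  stopifnot(is(cover, "HectareCoverMap"))
  cv <- cover@cover
  if (all(is.na(cv))) stop("cover map is empty")
  nr <- nrow(cv); nc <- ncol(cv)
  rHalf <- (row(cv) - 1L) %/% max(1L, ceiling(nr / 2))
  cHalf <- (col(cv) - 1L) %/% max(1L, ceiling(nc / 2))
  quad <- rHalf * 2L + cHalf
  nonzero <- !is.na(cv) & cv > 0
  quadCounts <- vapply(0:3, function(q) sum(nonzero[quad == q]), integer(1))
  bestQuad <- (0:3)[which.max(quadCounts)]
  inQuad <- quad == bestQuad & !is.na(cv)
  strata <- coverStratum(cv, design$breaks)
  set.seed(seed)
  out <- list()
  for (st in c("p=0", sprintf("(%g,%g]",
                              c(0, design$breaks[-length(design$breaks)]),
                              design$breaks))) {
    cand <- which(inQuad & strata == st)
    if (length(cand) == 0L) next
    take <- if (length(cand) <= design$nPerStratum) cand
            else sample(cand, design$nPerStratum)
    out[[st]] <- data.frame(
      row = ((take - 1L) %% nr) + 1L, col = ((take - 1L) %/% nr) + 1L,
      stratum = st, predicted_cover = cv[take], stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$hectare_id <- sprintf("ha_%03d_%03d", res$row, res$col)
  res[c("hectare_id", "row", "col", "stratum", "predicted_cover")]
}

#' Draw the within-hectare validation cells
#'
#' Uniform draws without replacement of \code{cellsPerClass} predicted
#' reedbed and \code{cellsPerClass} predicted non-reedbed 10 m cells inside
#' one hectare; a class with fewer qualifying cells contributes all of
#' them, and the shortfall is recorded.
#'
#' @param presence 0/1/NA matrix at 10 m (e.g. from [presenceGrid()]).
#' @param haRow,haCol hectare block indices (1-based).
#' @param design a [validationDesign()].
#' @param seed RNG seed.
#' @param blockSize pixels per hectare edge.
#' @return data.frame with columns \code{cell_row}, \code{cell_col},
#'   \code{cell_pred}; attribute \code{shortfall} counts missing cells.
#' @export
sampleCells <- function(presence, haRow, haCol, design = validationDesign(),
                        seed = 1L, blockSize = 10L) {
  rows <- ((haRow - 1L) * blockSize + 1L):min(nrow(presence),
                                              haRow * blockSize)
  cols <- ((haCol - 1L) * blockSize + 1L):min(ncol(presence),
                                              haCol * blockSize)
  block <- presence[rows, cols, drop = FALSE]
  set.seed(seed)
  pick <- function(values, want) {
    cand <- which(!is.na(block) & block == values)
    if (length(cand) <= want) cand else sample(cand, want)
  }
  presIdx <- pick(1, design$cellsPerClass)
  absIdx <- pick(0, design$cellsPerClass)
  idx <- c(presIdx, absIdx)
  short <- 2L * design$cellsPerClass - length(idx)
  out <- data.frame(
    cell_row = rows[((idx - 1L) %% length(rows)) + 1L],
    cell_col = cols[((idx - 1L) %/% length(rows)) + 1L],
    cell_pred = c(rep(1L, length(presIdx)), rep(0L, length(absIdx))))
  attr(out, "shortfall") <- short
  out
}

#' Virtual field survey of a synthetic scene
#'
#' Emulates the field campaign on simulator truth: for each stratified
#' hectare the observer estimates true reedbed cover to the nearest 10%,
#' notes the hectare's dominant land cover, and visits the sampled 10 m
#' cells recording true presence/absence.
#'
#' @param truthPresence logical or 0/1 matrix of true reedbed at 10 m.
#' @param classMap character matrix of true land-cover labels.
#' @param probMap a [ReedProbabilityMap-class] (supplies per-cell predicted
#'   presence and probability).
#' @param cover predicted [HectareCoverMap-class] used for stratification.
#' @param design a [validationDesign()].
#' @param seed RNG seed.
#' @param blockSize pixels per hectare edge.
#' @return data.frame, one row per visited cell, with columns
#'   \code{hectare_id}, \code{stratum}, \code{predicted_cover},
#'   \code{observed_cover}, \code{landcover}, \code{cell_row},
#'   \code{cell_col}, \code{cell_pred}, \code{cell_obs}, \code{cell_prob}.
#' @export
simulateFieldSurvey <- function(truthPresence, classMap, probMap, cover,
                                design = validationDesign(), seed = 1L,
                                blockSize = 10L) {
  truth <- truthPresence * 1
  pres <- presenceGrid(probMap)
  prob <- probabilityGrid(probMap)
  hect <- stratifyHectares(cover, design, seed = seed)
  cellSeeds <- deriveSeeds(seed, nrow(hect))
  recs <- vector("list", nrow(hect))
  for (i in seq_len(nrow(hect))) {
    hr <- hect$row[i]; hc <- hect$col[i]
    rows <- ((hr - 1L) * blockSize + 1L):min(nrow(truth), hr * blockSize)
    cols <- ((hc - 1L) * blockSize + 1L):min(ncol(truth), hc * blockSize)
    obsCover <- round(mean(truth[rows, cols]) * 10) / 10
    lc <- names(which.max(table(classMap[rows, cols])))
    cells <- sampleCells(pres, hr, hc, design, seed = cellSeeds[i],
                         blockSize = blockSize)
    if (nrow(cells) == 0L) next
    recs[[i]] <- data.frame(
      hectare_id = hect$hectare_id[i], stratum = hect$stratum[i],
      predicted_cover = hect$predicted_cover[i],
      observed_cover = obsCover, landcover = lc,
      cell_row = cells$cell_row, cell_col = cells$cell_col,
      cell_pred = cells$cell_pred,
      cell_obs = truth[cbind(cells$cell_row, cells$cell_col)],
      cell_prob = prob[cbind(cells$cell_row, cells$cell_col)],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Confusion metrics from validation records
#'
#' At the 10 m scale, tallies per-cell predicted against observed presence;
#' at the hectare scale, each hectare is presence iff its cover exceeds
#' \code{haPresenceThreshold} on each side (predicted and observed).
#'
#' @param records data.frame as produced by [simulateFieldSurvey()] (or
#'   read from a field CSV with the same columns).
#' @param scale \code{"tenm"} or \code{"hectare"}.
#' @param haPresenceThreshold cover cutoff for hectare-scale presence.
#' @return a [ConfusionMetrics-class].
#' @export
confusionFromRecords <- function(records, scale = c("tenm", "hectare"),
                                 haPresenceThreshold = 0) {
  scale <- match.arg(scale)
  if (is.null(records) || nrow(records) == 0L)
    stop("no validation records")
  if (scale == "tenm") {
    pred <- records$cell_pred == 1
    obs <- records$cell_obs == 1
  } else {
    ha <- records[!duplicated(records$hectare_id), ]
    pred <- ha$predicted_cover > haPresenceThreshold
    obs <- ha$observed_cover > haPresenceThreshold
  }
  confusionMetrics(tp = sum(pred & obs), fp = sum(pred & !obs),
                   fn = sum(!pred & obs), tn = sum(!pred & !obs))
}

#' Area under the ROC curve (rank statistic)
#'
#' The probability that a randomly drawn positive outscores a randomly
#' drawn negative, ties counted one half -- the Mann-Whitney form of the
#' AUC.
#'
#' @param scores numeric scores (higher = more reedbed-like).
#' @param labels logical (TRUE = positive) or factor/character where
#'   \code{"reedbed"} (or 1) is positive.
#' @return AUC in \[0, 1\].
#' @export
rocAuc <- function(scores, labels) {
  pos <- if (is.logical(labels)) labels
         else labels == "reedbed" | labels == 1
  ok <- !is.na(scores) & !is.na(pos)
  scores <- scores[ok]; pos <- pos[ok]
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Regression of observed on predicted hectare cover
#'
#' Ordinary least squares of observed cover on predicted cover, reporting
#' slope, intercept and the coefficient of determination.
#'
#' @param predicted,observed numeric cover vectors (>= 3 pairs; the
#'   observed values must vary).
#' @return list with \code{slope}, \code{intercept}, \code{r.squared}.
#' @export
coverRegression <- function(predicted, observed) {
  ok <- !is.na(predicted) & !is.na(observed)
  predicted <- predicted[ok]; observed <- observed[ok]
  if (length(predicted) < 3L) stop("at least 3 pairs are required")
  if (var(observed) == 0) stop("observed cover has zero variance")
  fit <- lm(observed ~ predicted)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r.squared = cor(predicted, observed)^2)
}

#' Chi-square test of false positives against land-cover composition
#'
#' Pearson chi-square comparing the distribution of false positives over
#' land-cover groups with the expectation from the sample's composition.
#'
#' @param fpCounts named integer vector of false positives per group.
#' @param composition sample composition fractions (same groups; normalised
#'   internally).
#' @return list with \code{statistic}, \code{df}, \code{p.value}.
#' @export
fpLandcoverChisq <- function(fpCounts, composition) {
  stopifnot(length(fpCounts) == length(composition))
  p <- composition / sum(composition)
  if (any(p * sum(fpCounts) == 0))
    stop("expected count of zero in at least one group")
  ht <- suppressWarnings(chisq.test(fpCounts, p = p))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p.value = unname(ht$p.value))
}

#' Commission/omission-corrected extent estimate
#'
#' Shrinks the mapped total by the commission error to the estimated
#' true-positive area \code{TP = P (1 - c)}, then inflates it for missed
#' reedbed. The \code{standard} estimator divides by \code{(1 - o)} (the
#' design-based area estimator); the \code{as_printed} variant divides by
#' \code{o} instead, reproducing the published headline figure whose
#' intended form cannot be resolved from the text. Both are exposed;
#' \code{standard} is the default.
#'
#' @param predictedTotal mapped extent P in hectares.
#' @param metrics a [ConfusionMetrics-class], or the commission error as a
#'   plain number (then \code{omission} must be given).
#' @param omission omission error when \code{metrics} is a number.
#' @param variant \code{"standard"} or \code{"as_printed"}.
#' @return corrected extent in hectares.
#' @export
correctedExtent <- function(predictedTotal, metrics, omission = NULL,
                            variant = c("standard", "as_printed")) {
  variant <- match.arg(variant)
  if (is(metrics, "ConfusionMetrics")) {
    commission <- commissionError(metrics)[["reedbed"]]
    omission <- omissionError(metrics)[["reedbed"]]
  } else {
    commission <- metrics
    if (is.null(omission)) stop("omission error is required")
  }
  stopifnot(commission >= 0, commission < 1, omission >= 0, omission <= 1)
  tpArea <- predictedTotal * (1 - commission)
  if (variant == "standard") {
    if (omission >= 1) stop("omission error of 1 leaves no information")
    tpArea / (1 - omission)
  } else {
    if (omission <= 0) stop("as_printed variant divides by the omission error")
    tpArea / omission
  }
}
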