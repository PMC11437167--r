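## Classification: polygon point sampling, the dual random-forest reedbed
## model fused by per-pixel minimum probability, Cohen's kappa and the
## kappa-optimal presence threshold, and the out-of-bag learning curve.

#' Sample training points from labelled polygons
#'
#' Draws \code{nPerPolygon} uniform points inside each polygon (uniform
#' pixel draws with replacement, the pixel-grid equivalent of uniform
#' points); later points sharing a pixel with an earlier point of the same
#' polygon are discarded, and points falling on invalid feature pixels are
#' dropped. Labels collapse to \code{reedbed} / \code{nonreedbed}.
#'
#' @param polygons data.frame with columns \code{polygon}, \code{class},
#'   \code{row}, \code{col}.
#' @param stack a [FeatureStack-class].
#' @param nPerPolygon points drawn per polygon before deduplication.
#' @param seed RNG seed.
#' @return a [TrainingSample-class].
#' @export
sampleTrainingPoints <- function(polygons, stack, nPerPolygon = 100L,
                                 seed = 1L) {
  stopifnot(is(stack, "FeatureStack"))
  d <- dim(stack@layers)
  bad <- polygons$row < 1L | polygons$row > d[1] |
         polygons$col < 1L | polygons$col > d[2]
  if (any(bad))
    stop("polygon(s) outside the raster: ",
         paste(unique(polygons$polygon[bad]), collapse = ", "))
  set.seed(seed)
  flat <- matrix(stack@layers, d[1] * d[2], d[3])
  colnames(flat) <- dimnames(stack@layers)[[3]]
  ids <- unique(polygons$polygon)
  rows <- list(); counts <- integer(length(ids)); names(counts) <- ids
  for (pid in ids) {
    sub <- polygons[polygons$polygon == pid, ]
    draw <- sample.int(nrow(sub), nPerPolygon, replace = TRUE)
    draw <- draw[!duplicated(draw)]
    pts <- sub[draw, ]
    cellIdx <- (pts$col - 1L) * d[1] + pts$row
    feats <- flat[cellIdx, , drop = FALSE]
    keep <- stats::complete.cases(feats)
    pts <- pts[keep, , drop = FALSE]
    feats <- feats[keep, , drop = FALSE]
    counts[pid] <- nrow(pts)
    if (nrow(pts) == 0L) next
    rows[[pid]] <- cbind(pts, as.data.frame(feats))
  }
  all <- do.call(rbind, rows)
  featCols <- dimnames(stack@layers)[[3]]
  labels <- factor(ifelse(all$class == "reedbed", "reedbed", "nonreedbed"),
                   levels = c("reedbed", "nonreedbed"))
  new("TrainingSample",
      features = as.matrix(all[, featCols, drop = FALSE]),
      labels = labels,
      pixels = data.frame(row = all$row, col = all$col,
                          polygon = all$polygon, landcover = all$class,
                          stringsAsFactors = FALSE),
      polygonCounts = counts)
}

## OOB commission error per predicted class from a randomForest fit.
.oobCommission <- function(rf) {
  conf <- rf$confusion[, colnames(rf$confusion) != "class.error",
                       drop = FALSE]
  predTot <- colSums(conf)
  out <- numeric(ncol(conf)); names(out) <- colnames(conf)
  for (cl in colnames(conf))
    out[cl] <- if (predTot[cl] > 0)
      (predTot[cl] - conf[cl, cl]) / predTot[cl] else NA_real_
  out
}

#' Fit the dual random-forest reedbed model
#'
#' Trains one forest per entry of \code{balanced} (500 trees, three
#' variables tried at each split by default), each with its own seed.
#' Balanced forests draw equal per-class bootstrap samples
#' (\code{strata}/\code{sampsize}); unbalanced forests use the ordinary
#' bootstrap. Variable importance (mean decrease in Gini) and per-class
#' out-of-bag commission errors are recorded per forest.
#'
#' @param sample a [TrainingSample-class] containing both classes.
#' @param balanced logical vector, one entry per forest; the default
#'   \code{c(TRUE, FALSE)} gives the balanced/unbalanced pair whose
#'   minimum-probability fusion shrinks false-positive area.
#' @param nTrees trees per forest.
#' @param varsPerSplit variables tried at each split; \code{NULL} uses the
#'   square root of the number of features.
#' @param seeds integer seeds, one per forest.
#' @return a [ReedModel-class].
#' @export
fitReedModel <- function(sample, balanced = c(TRUE, FALSE), nTrees = 500L,
                         varsPerSplit = 3L, seeds = NULL) {
  stopifnot(is(sample, "TrainingSample"))
  tab <- table(sample@labels)
  if (any(tab == 0L))
    stop("both classes must be present; missing: ",
         paste(names(tab)[tab == 0L], collapse = ", "))
  nForests <- length(balanced)
  if (is.null(seeds)) seeds <- seq_len(nForests)
  seeds <- as.integer(seeds)
  stopifnot(length(seeds) == nForests)
  X <- sample@features
  y <- sample@labels
  mtry <- if (is.null(varsPerSplit)) max(1L, floor(sqrt(ncol(X))))
          else varsPerSplit
  forests <- vector("list", nForests)
  imp <- matrix(NA_real_, ncol(X), nForests,
                dimnames = list(colnames(X),
                                paste0("RF", seq_len(nForests))))
  oobC <- matrix(NA_real_, 2L, nForests,
                 dimnames = list(levels(y), paste0("RF", seq_len(nForests))))
  for (i in seq_len(nForests)) {
    set.seed(seeds[i])
    if (balanced[i]) {
      m <- min(tab)
      rf <- randomForest::randomForest(X, y, ntree = nTrees, mtry = mtry,
                                       strata = y,
                                       sampsize = c(m, m))
    } else {
      rf <- randomForest::randomForest(X, y, ntree = nTrees, mtry = mtry)
    }
    forests[[i]] <- rf
    imp[, i] <- rf$importance[, "MeanDecreaseGini"]
    oobC[, i] <- .oobCommission(rf)[levels(y)]
  }
  new("ReedModel", forests = forests, featureNames = colnames(X),
      importance = imp, oobCommission = oobC,
      balanced = as.logical(balanced), seeds = seeds)
}

#' Variable importance of a reed model
#' @param model a [ReedModel-class].
#' @return matrix (features x forests) of mean decrease in Gini.
#' @export
variableImportance <- function(model) model@importance

#' Out-of-bag commission errors of a reed model
#' @param model a [ReedModel-class].
#' @return matrix (class x forests).
#' @export
oobCommissionError <- function(model) model@oobCommission

#' Fused out-of-bag reedbed probabilities at the training points
#'
#' Per training point, the minimum across forests of the out-of-bag vote
#' fraction for reedbed -- the held-out analogue of the fused prediction,
#' used to choose the presence threshold without threshold overfitting.
#'
#' @param model a [ReedModel-class].
#' @return numeric vector, one value per training point.
#' @export
oobProbabilities <- function(model) {
  probs <- vapply(model@forests,
                  function(rf) rf$votes[, "reedbed"],
                  numeric(nrow(model@forests[[1]]$votes)))
  apply(probs, 1, min)
}

#' Predict the fused reedbed probability map
#'
#' Each forest predicts a per-pixel reedbed probability; the fused map is
#' their per-pixel minimum, which shrinks false-positive area while leaving
#' shared true positives intact. Pixels with any invalid feature are
#' invalid.
#'
#' @param model a [ReedModel-class].
#' @param stack a [FeatureStack-class] whose layer names match the model's
#'   training features.
#' @param threshold presence threshold attached to the returned map.
#' @return a [ReedProbabilityMap-class].
#' @export
predictProbability <- function(model, stack, threshold = 0.5) {
  stopifnot(is(model, "ReedModel"), is(stack, "FeatureStack"))
  nm <- layerNames(stack)
  if (!identical(nm, model@featureNames)) {
    diff <- c(setdiff(model@featureNames, nm), setdiff(nm, model@featureNames))
    stop("feature names disagree with training: ",
         if (length(diff)) paste(unique(diff), collapse = ", ")
         else "same names, different order")
  }
  d <- dim(stack@layers)
  flat <- matrix(stack@layers, d[1] * d[2], d[3])
  colnames(flat) <- nm
  ok <- stats::complete.cases(flat)
  p <- rep(NA_real_, d[1] * d[2])
  if (any(ok)) {
    X <- flat[ok, , drop = FALSE]
    per <- vapply(model@forests,
                  function(rf) predict(rf, X, type = "prob")[, "reedbed"],
                  numeric(sum(ok)))
    p[ok] <- if (length(model@forests) == 1L) per[, 1]
             else apply(per, 1, min)
  }
  new("ReedProbabilityMap", p = matrix(p, d[1], d[2]),
      threshold = threshold)
}

#' Cohen's kappa from binary confusion counts
#'
#' \code{kappa = (po - pe) / (1 - pe)} with observed agreement
#' \code{po = (tp + tn) / N} and chance agreement
#' \code{pe = ((tp + fn)(tp + fp) + (tn + fp)(tn + fn)) / N^2}. The
#' degenerate case \code{pe = 1} (a single occupied cell) returns 0 by
#' convention.
#'
#' @param tp,fp,fn,tn non-negative counts with a positive total.
#' @return kappa in \[-1, 1\].
#' @export
cohensKappa <- function(tp, fp, fn, tn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0)
  N <- tp + fp + fn + tn
  stopifnot(N > 0)
  po <- (tp + tn) / N
  pe <- ((tp + fn) * (tp + fp) + (tn + fp) * (tn + fn)) / N^2
  if (abs(1 - pe) < .Machine$double.eps * 4) return(0)
  (po - pe) / (1 - pe)
}

#' Probability threshold maximising Cohen's kappa
#'
#' Candidate thresholds are the midpoints between consecutive sorted unique
#' probabilities, plus 0 and 1; presence is declared when \code{p >
#' threshold}. Returns the smallest candidate attaining the maximal kappa.
#'
#' @param probs predicted probabilities.
#' @param labels logical (TRUE = positive) or factor/character with level
#'   \code{"reedbed"} as the positive class.
#' @return list with \code{threshold} and \code{kappa}.
#' @export
kappaThreshold <- function(probs, labels) {
  pos <- if (is.logical(labels)) labels else labels == "reedbed"
  if (!any(pos) || all(pos))
    stop("both classes must be present")
  u <- sort(unique(probs))
  if (length(u) < 2L) stop("all probabilities are identical")
  cand <- sort(unique(c(0, (u[-1] + u[-length(u)]) / 2, 1)))
  ks <- vapply(cand, function(t) {
    pred <- probs > t
    cohensKappa(sum(pred & pos), sum(pred & !pos),
                sum(!pred & pos), sum(!pred & !pos))
  }, numeric(1))
  best <- which(ks >= max(ks) - 1e-12)[1]
  list(threshold = cand[best], kappa = ks[best])
}

#' Out-of-bag commission error as reedbed training polygons accumulate
#'
#' Refits the model on cumulative subsets of the reedbed polygons (all
#' non-reedbed points always included) and reports the per-class out-of-bag
#' commission errors, averaged over forests -- the learning curve whose
#' flattening signals that further reedbed polygons would not help.
#'
#' @param sample a [TrainingSample-class] with at least two reedbed
#'   polygons.
#' @param polygonOrder order in which reedbed polygons accumulate; defaults
#'   to order of appearance.
#' @param steps cumulative counts to evaluate; defaults to every count from
#'   1 to the number of reedbed polygons.
#' @param balanced,nTrees,varsPerSplit,seeds passed to [fitReedModel()].
#' @return data.frame with columns \code{nReedPolygons},
#'   \code{commissionReed}, \code{commissionNonreed}.
#' @export
oobLearningCurve <- function(sample, polygonOrder = NULL, steps = NULL,
                             balanced = c(TRUE, FALSE), nTrees = 500L,
                             varsPerSplit = 3L, seeds = NULL) {
  stopifnot(is(sample, "TrainingSample"))
  isReed <- sample@labels == "reedbed"
  reedPolys <- unique(sample@pixels$polygon[isReed])
  if (length(reedPolys) < 2L)
    stop("at least two reedbed polygons are required")
  if (is.null(polygonOrder)) polygonOrder <- reedPolys
  stopifnot(setequal(polygonOrder, reedPolys))
  if (is.null(steps)) steps <- seq_along(polygonOrder)
  out <- data.frame(nReedPolygons = integer(0),
                    commissionReed = numeric(0),
                    commissionNonreed = numeric(0))
  for (k in steps) {
    keepPolys <- polygonOrder[seq_len(k)]
    keep <- !isReed | sample@pixels$polygon %in% keepPolys
    sub <- new("TrainingSample",
               features = sample@features[keep, , drop = FALSE],
               labels = sample@labels[keep],
               pixels = sample@pixels[keep, , drop = FALSE],
               polygonCounts = sample@polygonCounts)
    fit <- fitReedModel(sub, balanced = balanced, nTrees = nTrees,
                        varsPerSplit = varsPerSplit, seeds = seeds)
    cc <- rowMeans(fit@oobCommission)
    out <- rbind(out, data.frame(nReedPolygons = k,
                                 commissionReed = cc[["reedbed"]],
                                 commissionNonreed = cc[["nonreedbed"]]))
  }
  out
}
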