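test_that("cover strata use half-open intervals with zero its own stratum", {
  expect_identical(coverStratum(c(0, 0.2, 0.33, 0.5, 0.66, 0.67, 1)),
                   c("p=0", "(0,0.33]", "(0,0.33]", "(0.33,0.66]",
                     "(0.33,0.66]", "(0.66,1]", "(0.66,1]"))
  expect_true(is.na(coverStratum(NA_real_)))
})

test_that("hectare stratification draws from the richest quadrant", {
  set.seed(2)
  cv <- matrix(0, 20L, 20L)
  # quadrant 4 (bottom-right) carries nearly all non-zero cover
  cv[11:20, 11:20] <- sample(c(0, 0.2, 0.5, 0.9), 100, replace = TRUE)
  cv[1, 1] <- 0.4
  cover <- new("HectareCoverMap", cover = cv)
  h1 <- stratifyHectares(cover, seed = 7L)
  h2 <- stratifyHectares(cover, seed = 7L)
  expect_identical(h1, h2)
  # all draws fall in the chosen quadrant
  expect_true(all(h1$row >= 11 & h1$col >= 11))
  expect_true(all(table(h1$stratum) <= 10))
  # strata with fewer qualifying hectares contribute all of them
  cvSmall <- matrix(0, 10L, 10L)
  cvSmall[1:4, 1:2] <- 0.9   # 8 cells, all inside one quadrant
  few <- stratifyHectares(new("HectareCoverMap", cover = cvSmall), seed = 1L)
  expect_identical(sum(few$stratum == "(0.66,1]"), 8L)
  expect_error(stratifyHectares(
    new("HectareCoverMap", cover = matrix(NA_real_, 2, 2))), "empty")
})

test_that("cell sampling draws three per predicted class with shortfall", {
  pres <- matrix(0, 20L, 20L)
  pres[1:10, 1:5] <- 1
  cells <- sampleCells(pres, 1L, 1L, seed = 3L)
  expect_identical(nrow(cells), 6L)
  expect_identical(sum(cells$cell_pred), 3L)
  expect_identical(attr(cells, "shortfall"), 0L)
  expect_false(any(duplicated(cells[c("cell_row", "cell_col")])))
  expect_identical(cells, sampleCells(pres, 1L, 1L, seed = 3L))
  # hectare entirely predicted presence: 3 presence cells, shortfall 3
  allPres <- matrix(1, 10L, 10L)
  deg <- sampleCells(allPres, 1L, 1L, seed = 1L)
  expect_identical(nrow(deg), 3L)
  expect_identical(attr(deg, "shortfall"), 3L)
})

test_that("printed confusion-matrix statistics recompute from counts", {
  hpc <- confusionMetrics(tp = 21, fp = 297, fn = 18, tn = 588)
  expect_equal(commissionError(hpc)[["reedbed"]], 0.934, tolerance = 5e-4)
  expect_equal(omissionError(hpc)[["reedbed"]], 0.4615, tolerance = 5e-4)
  expect_equal(predictedPrevalence(hpc), 0.3442, tolerance = 5e-4)
  expect_equal(truePrevalence(hpc), 0.0422, tolerance = 5e-4)
  gee <- confusionMetrics(tp = 10, fp = 17, fn = 29, tn = 868)
  expect_equal(commissionError(gee)[["reedbed"]], 0.630, tolerance = 1e-3)
  expect_equal(omissionError(gee)[["reedbed"]], 0.744, tolerance = 1e-3)
  perfect <- confusionMetrics(5, 0, 0, 20)
  expect_equal(commissionError(perfect)[["reedbed"]], 0)
  expect_equal(omissionError(perfect)[["reedbed"]], 0)
  expect_equal(overallAccuracy(perfect), 1)
})

test_that("records tally into confusion metrics at both scales", {
  records <- data.frame(
    hectare_id = rep(c("a", "b", "c"), each = 2),
    stratum = "(0,0.33]",
    predicted_cover = rep(c(0.2, 0, 0.3), each = 2),
    observed_cover = rep(c(0.1, 0.2, 0), each = 2),
    landcover = "grassland",
    cell_row = 1:6, cell_col = 1:6,
    cell_pred = c(1, 0, 0, 0, 1, 1),
    cell_obs  = c(1, 0, 1, 0, 0, 1))
  cm10 <- confusionFromRecords(records, "tenm")
  expect_equal(confusionCounts(cm10),
               c(tp = 2, fp = 1, fn = 1, tn = 2))
  cmHa <- confusionFromRecords(records, "hectare")
  # a: pred+obs, b: obs only, c: pred only
  expect_equal(confusionCounts(cmHa), c(tp = 1, fp = 1, fn = 1, tn = 0))
  expect_error(confusionFromRecords(records[0, ], "tenm"), "records")
})

test_that("rank AUC matches hand cases and the all-pairs oracle", {
  expect_equal(rocAuc(c(0.9, 0.7, 0.6, 0.2), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(rocAuc(c(0.7, 0.3, 0.5, 0.2), c(TRUE, TRUE, FALSE, FALSE)),
               0.75)
  expect_equal(rocAuc(rep(0.4, 6), c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE)),
               0.5)
  expect_error(rocAuc(runif(4), rep(TRUE, 4)), "both classes")
  set.seed(8)
  for (i in 1:5) {
    n <- 150
    labels <- runif(n) < 0.3
    if (!any(labels) || all(labels)) next
    scores <- round(runif(n), 2)   # ties present
    expect_equal(rocAuc(scores, labels), pairwiseAuc(scores, labels))
  }
})

test_that("rank AUC agrees with an independent ROC implementation", {
  set.seed(12)
  labels <- runif(300) < 0.25
  scores <- rnorm(300, ifelse(labels, 0.7, 0.3), 0.3)
  ours <- rocAuc(scores, labels)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("cover regression reports OLS and rejects degenerate inputs", {
  x <- c(0, 0.2, 0.4, 1); y <- c(0, 0.1, 0.5, 0.8)
  reg <- coverRegression(x, y)
  expect_equal(reg$r.squared, 0.9216, tolerance = 1e-3)
  exact <- coverRegression(c(0.1, 0.5, 0.9), c(0.1, 0.5, 0.9))
  expect_equal(exact$r.squared, 1)
  expect_equal(exact$slope, 1)
  expect_error(coverRegression(c(0.1, 0.5, 0.9), rep(0.3, 3)), "variance")
  expect_error(coverRegression(c(0.1, 0.2), c(0.1, 0.3)), "3 pairs")
})

test_that("false-positive land-cover chi-square follows the Pearson formula", {
  even <- fpLandcoverChisq(c(50, 50), c(0.5, 0.5))
  expect_equal(even$statistic, 0)
  skewed <- fpLandcoverChisq(c(75, 25), c(0.5, 0.5))
  expect_equal(skewed$statistic, 25)
  expect_identical(skewed$df, 1)
  expect_lt(skewed$p.value, 1e-5)
  four <- fpLandcoverChisq(c(10, 20, 30, 40), c(0.25, 0.25, 0.25, 0.25))
  expect_identical(four$df, 3)
  expect_error(fpLandcoverChisq(c(10, 20), c(1, 0)), "zero")
})

test_that("corrected extent implements both estimator variants", {
  # symmetric case: both variants coincide
  expect_equal(correctedExtent(100, 0.5, 0.5, "standard"), 100)
  expect_equal(correctedExtent(100, 0.5, 0.5, "as_printed"), 100)
  cm <- confusionMetrics(21, 297, 18, 588)
  expect_equal(correctedExtent(54273, cm, variant = "standard"),
               6656.1, tolerance = 1e-4)
  expect_equal(correctedExtent(54273, cm, variant = "as_printed"),
               7765.5, tolerance = 1e-4)
  # monotonicity of the standard estimator
  base <- correctedExtent(1000, 0.3, 0.4, "standard")
  expect_lt(correctedExtent(1000, 0.4, 0.4, "standard"), base)
  expect_gt(correctedExtent(1000, 0.3, 0.5, "standard"), base)
  # boundary behaviour
  expect_equal(correctedExtent(1000, 0.25, 0, "standard"), 750)
  expect_error(correctedExtent(1000, 0.25, 0, "as_printed"), "omission")
  expect_error(correctedExtent(1000, 0.25, 1, "standard"), "omission")
})

test_that("design-based sampling tracks exhaustive map error rates", {
  run <- cleanRun()
  # build a degraded probability map so commission is non-trivial: use the
  # unbalanced forest alone at a permissive threshold
  single <- new("ReedModel", forests = run$model@forests[2],
                featureNames = run$model@featureNames,
                importance = run$model@importance[, 2, drop = FALSE],
                oobCommission = run$model@oobCommission[, 2, drop = FALSE],
                balanced = FALSE, seeds = run$model@seeds[2])
  probMap <- predictProbability(single, run$stack, threshold = 0.05)
  truth <- run$scene@classMap == "reedbed"
  pres <- presenceGrid(probMap)
  ok <- !is.na(pres)
  tp <- sum(pres[ok] == 1 & truth[ok]); fp <- sum(pres[ok] == 1 & !truth[ok])
  exhaustiveCommission <- fp / (tp + fp)
  cover <- aggregateToHectare(probMap)
  est <- vapply(1:6, function(s) {
    rec <- simulateFieldSurvey(truth, run$scene@classMap, probMap, cover,
                               seed = s)
    cm <- confusionFromRecords(rec, "tenm")
    commissionError(cm)[["reedbed"]]
  }, numeric(1))
  expect_lt(abs(mean(est) - exhaustiveCommission), 0.2)
})
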