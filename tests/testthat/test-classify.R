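test_that("training-point sampling dedupes, bounds and reproduces", {
  run <- cleanRun()
  s1 <- sampleTrainingPoints(run$scene@polygons, run$stack, seed = 5L)
  s2 <- sampleTrainingPoints(run$scene@polygons, run$stack, seed = 5L)
  expect_identical(s1@features, s2@features)
  expect_identical(s1@pixels, s2@pixels)
  # retained count per polygon <= min(100, polygon pixel count)
  polySize <- table(run$scene@polygons$polygon)
  for (pid in names(s1@polygonCounts))
    expect_lte(s1@polygonCounts[[pid]], min(100L, polySize[[pid]]))
  # no two points share a pixel within a polygon
  expect_false(any(duplicated(s1@pixels[c("polygon", "row", "col")])))
  # single-pixel polygon retains exactly one point
  one <- data.frame(polygon = "p1", class = "reedbed", row = 5L, col = 5L)
  sOne <- sampleTrainingPoints(one, run$stack, seed = 1L)
  expect_identical(nrow(sOne@features), 1L)
  # polygon outside the raster is named in the error
  bad <- data.frame(polygon = "astray", class = "reedbed",
                    row = 9999L, col = 2L)
  expect_error(sampleTrainingPoints(bad, run$stack), "astray")
})

test_that("separable classes give near-zero out-of-bag error in both forests", {
  for (s in 1:3) {
    sep <- gaussianSample(150L, 450L, separation = 3, seed = s)
    fit <- fitReedModel(sep, nTrees = 300L, varsPerSplit = 2L,
                        seeds = c(s, s + 100L))
    for (rf in fit@forests)
      expect_lt(rf$err.rate[rf$ntree, "OOB"], 0.05)
  }
  model <- cleanRun()$model
  expect_length(model@forests, 2L)
  imp <- variableImportance(model)
  expect_identical(nrow(imp), 16L)   # one importance per feature layer
  expect_identical(ncol(imp), 2L)
  expect_true(all(imp >= 0))
})

test_that("class balancing evens out per-class commission under imbalance", {
  gaps <- vapply(1:5, function(s) {
    sample <- gaussianSample(60L, 600L, separation = 1.1, seed = s)
    fit <- fitReedModel(sample, balanced = c(TRUE, FALSE), nTrees = 300L,
                        varsPerSplit = 2L, seeds = c(s, s))
    omission <- vapply(fit@forests, function(rf)
      rf$confusion[, "class.error"], numeric(2))
    # per-class error gap: balanced forest (col 1) vs unbalanced (col 2)
    abs(diff(omission[, 1])) - abs(diff(omission[, 2]))
  }, numeric(1))
  expect_lt(median(gaps), 0)
  # one class absent -> error
  allNeg <- gaussianSample(0L, 50L, seed = 1L)
  expect_error(fitReedModel(allNeg), "class")
})

test_that("fused prediction is the per-pixel minimum of the two forests", {
  run <- cleanRun()
  probMap <- predictProbability(run$model, run$stack, threshold = 0.5)
  d <- dim(run$stack@layers)
  flat <- matrix(run$stack@layers, d[1] * d[2], d[3])
  colnames(flat) <- layerNames(run$stack)
  ok <- complete.cases(flat)
  p1 <- predict(run$model@forests[[1]], flat[ok, ], type = "prob")[, "reedbed"]
  p2 <- predict(run$model@forests[[2]], flat[ok, ], type = "prob")[, "reedbed"]
  fused <- probabilityGrid(probMap)[ok]
  expect_equal(fused, pmin(p1, p2), ignore_attr = TRUE)
  expect_true(all(fused <= p1 + 1e-12))
  expect_true(all(fused <= p2 + 1e-12))
  expect_true(all(is.na(probabilityGrid(probMap)[!ok])))
  # mismatched feature names are listed
  stackBad <- run$stack
  dimnames(stackBad@layers)[[3]][1] <- "NDVI_spring"
  expect_error(predictProbability(run$model, stackBad), "NDVI_spring")
})

test_that("kappa matches its formula, conventions and symmetries", {
  expect_equal(cohensKappa(10, 0, 0, 10), 1)
  expect_equal(cohensKappa(25, 25, 25, 25), 0)
  expect_equal(cohensKappa(21, 297, 18, 588), 0.0459, tolerance = 1e-3)
  expect_equal(cohensKappa(5, 0, 0, 0), 0)   # degenerate single cell
  # invariance to swapping (tp<->tn, fp<->fn)
  set.seed(1)
  for (i in 1:20) {
    cts <- sample(0:50, 4, replace = TRUE)
    if (sum(cts) == 0) next
    expect_equal(cohensKappa(cts[1], cts[2], cts[3], cts[4]),
                 cohensKappa(cts[4], cts[3], cts[2], cts[1]))
  }
})

test_that("kappa threshold scans candidate midpoints correctly", {
  kt <- kappaThreshold(c(0.2, 0.4, 0.6, 0.9),
                       c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(kt$threshold, 0.5)
  expect_equal(kt$kappa, 1)
  # perfectly inverted scores cannot beat chance
  inv <- kappaThreshold(c(0.9, 0.8, 0.1, 0.2),
                        c(FALSE, FALSE, TRUE, TRUE))
  expect_lte(inv$kappa, 0)
  expect_error(kappaThreshold(rep(0.3, 5), c(TRUE, TRUE, FALSE, FALSE, TRUE)),
               "identical")
  expect_error(kappaThreshold(runif(5), rep(TRUE, 5)), "both classes")
  # thresholding extremes: all presence at 0, none at 1
  p <- c(0.1, 0.5, 0.9)
  expect_true(all(p > 0))
  expect_false(any(p > 1))
})

test_that("kappa threshold agrees with a 0.001-step brute-force scan", {
  set.seed(42)
  for (i in 1:3) {
    n <- 400
    labels <- runif(n) < 0.3
    probs <- round(pmin(pmax(rnorm(n, ifelse(labels, 0.6, 0.4), 0.2), 0), 1), 3)
    if (length(unique(probs)) < 2) next
    kt <- kappaThreshold(probs, labels)
    bf <- bruteKappaThreshold(probs, labels)
    expect_equal(kt$kappa, bf$kappa, tolerance = 1e-9)
    # both thresholds induce the same presence set (tie regions permitting)
    expect_identical(sum(probs > kt$threshold), sum(probs > bf$threshold))
  }
})

test_that("learning curve is consistent with a full fit and well shaped", {
  land <- landscapeSpec(100L, 100L,
                        classFractions = c(water = 0.05, grassland = 0.755,
                                           arable = 0.18, reedbed = 0.015),
                        reedPatchSize = 25, seed = 21L)
  dates <- c("2016-06-20", "2016-08-10", "2016-01-15", "2016-12-10")
  scene <- generateDataset(land, lapply(dates, passSpec))
  composites <- seasonalMedianComposite(scene@passes, scene@seasonWindows)
  stack <- buildFeatureStack(composites, "two_season")
  sample <- sampleTrainingPoints(scene@polygons, stack, seed = 21L)
  reedPolys <- unique(sample@pixels$polygon[sample@labels == "reedbed"])
  expect_gte(length(reedPolys), 2L)
  # balanced forest: reed is predicted often enough for commission to exist
  full <- fitReedModel(sample, balanced = TRUE, nTrees = 200L, seeds = 1L)
  curve <- oobLearningCurve(sample, steps = length(reedPolys),
                            balanced = TRUE, nTrees = 200L, seeds = 1L)
  expect_identical(nrow(curve), 1L)
  expect_equal(curve$commissionReed,
               mean(oobCommissionError(full)["reedbed", ]))
  curve2 <- oobLearningCurve(sample, balanced = TRUE, nTrees = 100L,
                             seeds = 1L)
  expect_identical(nrow(curve2), length(reedPolys))
  expect_identical(curve2$nReedPolygons, seq_along(reedPolys))
  expect_true(all(is.finite(curve2$commissionNonreed)))
})
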