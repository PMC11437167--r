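test_that("dark-object subtraction removes additive haze", {
  land <- generateLandscape(landscapeSpec(200L, 200L, seed = 8L))
  ph <- noiseFreePhenology()
  clean <- simulatePass(land$classMap, land$dem, ph, passSpec("2016-07-01"))$pass
  hazy <- simulatePass(land$classMap, land$dem, ph,
                       passSpec("2016-07-01", offset = 0.05))$pass
  # percentile 0 with known additive offset and a zero-reaching band
  # recovers the true band exactly up to the band's own minimum
  fixedAt0 <- darkObjectSubtract(hazy, percentile = 0)
  for (b in c("B2", "B8", "B12")) {
    shiftTrue <- getBand(clean, b) - min(getBand(clean, b))
    expect_equal(getBand(fixedAt0, b), shiftTrue)
  }
  # 1st percentile on a hazy noise-free scene drives the minimum to ~0
  fixed <- darkObjectSubtract(hazy, percentile = 0.01)
  for (b in S2_BANDS) expect_lte(min(getBand(fixed, b)), 0.005)
  # band already reaching 0 is unchanged at percentile 0
  zeroed <- darkObjectSubtract(fixedAt0, percentile = 0)
  expect_equal(zeroed@bands, fixedAt0@bands)   # idempotence
  expect_identical(validMask(fixed), validMask(hazy))
  # no valid pixels -> error
  none <- hazy
  none@valid[] <- FALSE
  expect_error(darkObjectSubtract(none), "no valid pixels")
})

test_that("cloud model separates synthetic clouds and is deterministic", {
  scene <- testFixture()
  idx <- which(vapply(scene@cloudTruth, any, logical(1)))[1]
  polys <- cloudTrainingPolygons(scene@cloudTruth[[idx]], seed = 1L)
  oobs <- vapply(1:3, function(s)
    oobError(trainCloudModel(scene@passes[[idx]], polys, nTrees = 300L,
                             seed = s)),
    numeric(1))
  expect_true(all(oobs < 0.05))   # reflectance gap >= 0.3: near-perfect
  m1 <- trainCloudModel(scene@passes[[idx]], polys, nTrees = 300L, seed = 7L)
  m2 <- trainCloudModel(scene@passes[[idx]], polys, nTrees = 300L, seed = 7L)
  expect_identical(oobError(m1), oobError(m2))
  # single-class training set is rejected
  expect_error(
    trainCloudModel(scene@passes[[idx]], polys[polys$class == "cloud", ]),
    "two classes")
})

test_that("uninformative features give chance-level out-of-bag error", {
  # single-class scene with ordinary band noise: features vary but carry
  # no information about the (randomly assigned) labels
  flat <- matrix("grassland", 60L, 60L)
  dem <- matrix(10, 60L, 60L)
  pass <- simulatePass(flat, dem, defaultPhenology(bandSd = 0.02),
                       passSpec("2016-07-01", seed = 9L))$pass
  set.seed(9)
  cells <- expand.grid(row = 1:60, col = 1:60)
  pick <- cells[sample(nrow(cells), 400), ]
  polys <- data.frame(polygon = rep(c("a", "b"), each = 200),
                      class = rep(c("cloud", "clear"), each = 200),
                      row = pick$row, col = pick$col)
  mod <- trainCloudModel(pass, polys, nTrees = 300L, seed = 1L)
  expect_gt(oobError(mod), 0.4)
  expect_lt(oobError(mod), 0.6)
})

test_that("cloud masking invalidates predicted cloud and only that", {
  scene <- testFixture()
  idx <- which(vapply(scene@cloudTruth, any, logical(1)))[1]
  pass <- scene@passes[[idx]]
  truth <- scene@cloudTruth[[idx]]
  polys <- cloudTrainingPolygons(truth, seed = 1L)
  model <- trainCloudModel(pass, polys, nTrees = 300L, seed = 1L)
  masked <- maskClouds(pass, model)
  hit <- truth & validMask(pass) & !validMask(masked)
  expect_gte(sum(hit) / sum(truth & validMask(pass)), 0.95)
  expect_identical(masked@bands, pass@bands)
  # masking only removes validity, never adds it
  expect_true(all(validMask(pass) | !validMask(masked)))
})

test_that("co-registration recovers constructed shifts and honours ties", {
  land <- noiseFreeLandscape()
  ph <- noiseFreePhenology()
  ref <- noiseFreePass("2016-07-01", land)
  expect_identical(estimateShift(ref, ref), c(dx = 0L, dy = 0L))
  sec <- simulatePass(land$classMap, land$dem, ph,
                      passSpec("2016-07-01", shift = c(2L, -1L)))$pass
  expect_identical(estimateShift(ref, sec), c(dx = 2L, dy = -1L))
  aligned <- applyShift(sec, c(2L, -1L))
  expect_identical(estimateShift(ref, aligned), c(dx = 0L, dy = 0L))
  # un-shifting exposes a margin of width |dx| on the east edge
  nc <- ncol(validMask(aligned))
  expect_false(any(validMask(aligned)[, (nc - 1L):nc]))
})

test_that("low-valid-fraction passes raise a registration failure", {
  ref <- noiseFreePass()
  thin <- ref
  thin@valid[] <- FALSE
  thin@valid[1:10, 1:12] <- TRUE    # 120 of 6400 pixels ~ 0.019
  expect_error(estimateShift(ref, thin),
               class = "reedmapRegistrationFailure")
  expect_error(estimateShift(ref, thin), "3")
})

test_that("apply_shift with zero shift is the identity", {
  p <- noiseFreePass()
  expect_identical(applyShift(p, c(0L, 0L)), p)
})

test_that("seasonal median composites are medians with coverage tracking", {
  land <- noiseFreeLandscape()
  ph <- defaultPhenology(bandSd = 0.02)
  specs <- lapply(c("2016-06-10", "2016-07-20", "2016-09-01"),
                  function(d) passSpec(d, seed = as.integer(as.Date(d))))
  passes <- lapply(specs, function(s)
    simulatePass(land$classMap, land$dem, ph, s)$pass)
  comp <- seasonalMedianComposite(passes,
                                  list(summer = c(6L, 9L)))$summer
  # per-pixel median over three noisy passes, checked directly
  b4 <- vapply(passes, function(p) as.vector(getBand(p, "B4")),
               numeric(length(land$dem)))
  expect_equal(as.vector(getBand(comp, "B4")), apply(b4, 1, median))
  expect_true(all(coverageGrid(comp) == 3L))
  # even count: mean of the two central values
  comp2 <- seasonalMedianComposite(passes[1:2],
                                   list(summer = c(6L, 9L)))$summer
  expect_equal(getBand(comp2, "B4"),
               (getBand(passes[[1]], "B4") + getBand(passes[[2]], "B4")) / 2)
  # permutation invariance
  compR <- seasonalMedianComposite(rev(passes),
                                   list(summer = c(6L, 9L)))$summer
  expect_equal(comp@bands, compR@bands)
  # missing season errors by name
  expect_error(seasonalMedianComposite(passes, defaultSeasonWindows()),
               "winter")
  # single pass: identity on valid pixels
  comp1 <- seasonalMedianComposite(passes[1],
                                   list(summer = c(6L, 9L)))$summer
  expect_equal(getBand(comp1, "B8"), getBand(passes[[1]], "B8"))
})

test_that("composites never leave the convex hull of contributing values", {
  scene <- testFixture()
  passes <- scene@passes[c(1, 2, 3)]
  comp <- seasonalMedianComposite(passes, list(summer = c(6L, 9L)))$summer
  b8 <- vapply(seq_along(passes), function(i) {
    m <- getBand(passes[[i]], "B8")
    m[!validMask(passes[[i]])] <- NA
    as.vector(m)
  }, numeric(length(scene@dem)))
  lo <- apply(b8, 1, function(v) suppressWarnings(min(v, na.rm = TRUE)))
  hi <- apply(b8, 1, function(v) suppressWarnings(max(v, na.rm = TRUE)))
  med <- as.vector(getBand(comp, "B8"))
  ok <- !is.na(med)
  expect_true(all(med[ok] >= lo[ok] - 1e-12 & med[ok] <= hi[ok] + 1e-12))
  # zero-coverage pixels are invalid
  expect_true(all(is.na(med[!ok])))
  expect_true(all(coverageGrid(comp)[!ok] == 0L))
})
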