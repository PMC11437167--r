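test_that("landscape generation honours class fractions and determinism", {
  spec <- landscapeSpec(500L, 500L, seed = 1L)
  land <- generateLandscape(spec)
  counts <- table(land$classMap)
  # rare-class pixel count lands in the Monte-Carlo band for a 1% target
  expect_gte(counts[["reedbed"]], 2000)
  expect_lte(counts[["reedbed"]], 3000)
  # classes with expected count >= 100 pixels stay within 20% relative
  for (cl in names(spec$classFractions)) {
    target <- spec$classFractions[[cl]] * 500 * 500
    if (target >= 100)
      expect_lt(abs(counts[[cl]] - target) / target, 0.2)
  }
  land2 <- generateLandscape(spec)
  expect_identical(land$classMap, land2$classMap)
  expect_identical(land$dem, land2$dem)
})

test_that("zero reed fraction yields no reed pixels and zero area errors", {
  spec <- landscapeSpec(
    60L, 60L, classFractions = c(water = 0.05, grassland = 0.65,
                                 arable = 0.30, reedbed = 0),
    seed = 2L)
  land <- generateLandscape(spec)
  expect_false(any(land$classMap == "reedbed"))
  expect_error(landscapeSpec(0L, 10L), "zero-area")
  expect_error(landscapeSpec(10L, 10L,
                             classFractions = c(grassland = 0.9,
                                                reedbed = 0.1)),
               "rare-class")
})

test_that("reedbed occurs as contiguous patches", {
  land <- noiseFreeLandscape(seed = 5L, nRows = 150L, nCols = 150L)
  mask <- (land$classMap == "reedbed") * 1
  lab <- EBImage::imageData(EBImage::bwlabel(mask))
  nPatches <- max(lab)
  nReed <- sum(mask)
  expect_gt(nReed, 0)
  # far fewer patches than pixels: mean patch size well above 1 pixel
  expect_gt(nReed / nPatches, 10)
})

test_that("noise-free simulation reproduces class seasonal means exactly", {
  land <- noiseFreeLandscape()
  ph <- noiseFreePhenology()
  pass <- noiseFreePass("2016-07-01", land)
  for (cl in unique(as.vector(land$classMap))) {
    sel <- land$classMap == cl
    for (b in c("B2", "B4", "B8", "B12")) {
      vals <- unique(getBand(pass, b)[sel])
      expect_equal(vals, ph[[cl]]$seasonMeans["summer", b],
                   ignore_attr = TRUE)
    }
  }
  expect_true(all(validMask(pass)))
})

test_that("gain and offset act as an affine reflectance error", {
  land <- generateLandscape(landscapeSpec(200L, 200L, seed = 8L))
  ph <- noiseFreePhenology()
  base <- simulatePass(land$classMap, land$dem, ph, passSpec("2016-07-01"))$pass
  off <- simulatePass(land$classMap, land$dem, ph,
                      passSpec("2016-07-01", offset = c(0, 0.05, rep(0, 11))))$pass
  # offset on band 2 shifts the scene minimum of band 2 by exactly 0.05
  expect_equal(min(getBand(off, "B2")), min(getBand(base, "B2")) + 0.05)
  expect_equal(getBand(off, "B4"), getBand(base, "B4"))
  gained <- simulatePass(land$classMap, land$dem, ph,
                         passSpec("2016-07-01", gain = 1.1))$pass
  expect_equal(getBand(gained, "B8"), 1.1 * getBand(base, "B8"))
})

test_that("cloud saturation, shadows and shift margins behave by construction", {
  land <- noiseFreeLandscape()
  ph <- noiseFreePhenology()
  allCloud <- simulatePass(land$classMap, land$dem, ph,
                           passSpec("2016-07-01", cloudFraction = 1))
  expect_true(all(allCloud$cloudTruth))
  expect_true(all(allCloud$pass@bands >= 0.6))

  sh <- simulatePass(land$classMap, land$dem, ph,
                     passSpec("2016-07-01", shift = c(2L, -1L)))
  m <- validMask(sh$pass)
  expect_false(any(m[, 1:2]))          # dx = 2: west margin exposed
  expect_false(any(m[nrow(m), ]))      # dy = -1: south margin exposed
  # shifting back recovers the unshifted grid on the common valid region
  unshifted <- noiseFreePass("2016-07-01", land)
  back <- applyShift(sh$pass, c(2L, -1L))
  common <- validMask(back)
  for (b in c("B3", "B8"))
    expect_equal(getBand(back, b)[common], getBand(unshifted, b)[common])
})

test_that("dates outside every season window are rejected", {
  land <- noiseFreeLandscape()
  expect_error(
    simulatePass(land$classMap, land$dem, noiseFreePhenology(),
                 passSpec("2016-05-10")),
    "no season")
})

test_that("datasets are deterministic and track their passes", {
  land <- landscapeSpec(60L, 60L, seed = 4L)
  dates <- c("2016-06-20", "2016-07-15", "2016-01-10", "2016-12-05")
  specs <- lapply(dates, passSpec)
  d1 <- generateDataset(land, specs)
  d2 <- generateDataset(land, specs)
  expect_length(d1@passes, 4L)
  expect_identical(d1@classMap, d2@classMap)
  for (i in seq_along(d1@passes))
    expect_identical(d1@passes[[i]]@bands, d2@passes[[i]]@bands)
  # a requested season with zero passes still returns, with a note
  expect_warning(
    d3 <- generateDataset(land, lapply(dates[1:2], passSpec)),
    "winter")
  expect_match(d3@notes, "winter", all = FALSE)
  expect_length(d3@passes, 2L)
})

test_that("truth polygons are eroded off patch boundaries and rasterise back", {
  scene <- testFixture()
  polys <- scene@polygons
  expect_setequal(unique(polys$class),
                  c("water", "grassland", "arable", "reedbed"))
  # every polygon pixel carries its own class in the truth map
  expect_true(all(
    scene@classMap[cbind(polys$row, polys$col)] == polys$class))
  # erosion: no polygon pixel touches a different class (8-neighbourhood)
  cm <- scene@classMap
  pad <- matrix(NA_character_, nrow(cm) + 2, ncol(cm) + 2)
  pad[2:(nrow(cm) + 1), 2:(ncol(cm) + 1)] <- cm
  for (dr in -1:1) for (dc in -1:1) {
    nb <- pad[cbind(polys$row + 1 + dr, polys$col + 1 + dc)]
    expect_true(all(is.na(nb) | nb == polys$class))
  }
})

test_that("a one-pixel-wide patch yields no training polygon", {
  cm <- matrix("grassland", 20L, 20L)
  cm[10, 3:12] <- "reedbed"       # 1 pixel wide: erosion removes it
  polys <- reedmap:::makeTruthPolygons(cm)
  expect_false(any(polys$class == "reedbed"))
})
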