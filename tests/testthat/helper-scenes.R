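# Shared synthetic material, built once per test run.

.cache <- new.env(parent = emptyenv())

# Standard cloudy/shifted fixture scene used by pipeline-level tests.
testFixture <- function() {
  if (is.null(.cache$fixture))
    .cache$fixture <- makeFixture(nRows = 120L, nCols = 120L, seed = 42L)
  .cache$fixture
}

# Small noise-free landscape + phenology for exact-arithmetic tests.
noiseFreeLandscape <- function(seed = 3L, nRows = 80L, nCols = 80L) {
  key <- sprintf("nf_%d_%d_%d", seed, nRows, nCols)
  if (is.null(.cache[[key]]))
    .cache[[key]] <- generateLandscape(landscapeSpec(nRows, nCols, seed = seed))
  .cache[[key]]
}

noiseFreePhenology <- function() defaultPhenology(bandSd = 0)

noiseFreePass <- function(date = "2016-07-01", land = noiseFreeLandscape(),
                          ...) {
  simulatePass(land$classMap, land$dem, noiseFreePhenology(),
               passSpec(date, ...))$pass
}

# Clean two-season run (no clouds, no shift, no reflectance error) on a
# rare-reedbed landscape; cached because several tests reuse the model.
cleanRun <- function() {
  if (is.null(.cache$cleanRun)) {
    land <- landscapeSpec(100L, 100L, seed = 11L)
    dates <- c("2016-06-20", "2016-08-10", "2016-01-15", "2016-12-10")
    scene <- generateDataset(land, lapply(dates, passSpec))
    composites <- seasonalMedianComposite(scene@passes, scene@seasonWindows)
    stack <- buildFeatureStack(composites, "two_season")
    sample <- sampleTrainingPoints(scene@polygons, stack, seed = 11L)
    model <- fitReedModel(sample, nTrees = 200L, seeds = c(11L, 12L))
    .cache$cleanRun <- list(scene = scene, composites = composites,
                            stack = stack, sample = sample, model = model)
  }
  .cache$cleanRun
}

# Synthetic training sample with controllable class overlap and imbalance.
gaussianSample <- function(n1, n0, nFeatures = 6L, separation = 2,
                           seed = 1L) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n1 * nFeatures, separation), n1, nFeatures),
             matrix(rnorm(n0 * nFeatures, 0), n0, nFeatures))
  colnames(X) <- paste0("f", seq_len(nFeatures))
  new("TrainingSample",
      features = X,
      labels = factor(rep(c("reedbed", "nonreedbed"), c(n1, n0)),
                      levels = c("reedbed", "nonreedbed")),
      pixels = data.frame(row = seq_len(n1 + n0), col = 1L,
                          polygon = rep(c("r1", "n1"), c(n1, n0)),
                          landcover = rep(c("reedbed", "grassland"),
                                          c(n1, n0))),
      polygonCounts = c(r1 = n1, n1 = n0))
}

# Brute-force kappa-threshold oracle over a fixed probability grid.
bruteKappaThreshold <- function(probs, labels, step = 0.001) {
  pos <- labels == "reedbed" | labels == TRUE
  cand <- seq(0, 1, by = step)
  ks <- vapply(cand, function(t) {
    pred <- probs > t
    cohensKappa(sum(pred & pos), sum(pred & !pos),
                sum(!pred & pos), sum(!pred & !pos))
  }, numeric(1))
  list(threshold = cand[which.max(ks)], kappa = max(ks))
}

# All-pairs AUC oracle.
pairwiseAuc <- function(scores, labels) {
  pos <- scores[labels == TRUE | labels == "reedbed" | labels == 1]
  neg <- scores[!(labels == TRUE | labels == "reedbed" | labels == 1)]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}
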