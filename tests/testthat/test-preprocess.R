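test_that("cropping is pure slicing with bounds checks", {
  m <- matrix(1:100, 10, 10)
  sp <- GCIMSSpectrum(m)
  # a 3 x 4 window returns exactly those cells
  expect_identical(cropSpectrum(sp, cropWindow(c(3, 5), c(4, 7))),
                   m[3:5, 4:7])
  # full-extent window is the identity
  expect_identical(cropSpectrum(sp, cropWindow(c(1, 10), c(1, 10))), m)
  # empty / inverted window cannot be constructed
  expect_error(cropWindow(c(5, 4), c(1, 2)), "lo <= hi")
  # window beyond the matrix
  expect_error(cropSpectrum(sp, cropWindow(c(1, 11), c(1, 10))), "bounds")
})

test_that("background model is mean + 2 * sample SD, exactly", {
  # constant region: zero variance, threshold equals the constant
  spc <- GCIMSSpectrum(matrix(4.4, 5, 5))
  bg <- estimateBackground(spc, cropWindow(c(1, 5), c(1, 2)))
  expect_identical(bg@threshold, 4.4)

  # two-value region {8, 12}: mean 10, sample SD 2sqrt(2)
  sp <- GCIMSSpectrum(matrix(c(8, 12, 100, 200), 2, 2))
  bg <- estimateBackground(sp, cropWindow(c(1, 2), c(1, 1)))
  expect_equal(bg@mean, 10)
  expect_equal(bg@sd, 2 * sqrt(2))
  expect_equal(bg@threshold, 10 + 4 * sqrt(2))  # 15.6568542...
  expect_equal(bg@threshold, 15.65685424949238, tolerance = 1e-12)

  # single-cell region leaves the SD undefined
  expect_error(estimateBackground(sp, cropWindow(c(1, 1), c(1, 1))),
               ">= 2 cells")

  # Monte-Carlo convergence to mu + 2 sigma on a large Gaussian region
  set.seed(3)
  big <- GCIMSSpectrum(matrix(rnorm(40000, 20, 3), 200, 200))
  bg <- estimateBackground(big, cropWindow(c(1, 200), c(1, 200)))
  expect_equal(bg@threshold, 26, tolerance = 0.01)

  # multiple disjoint windows pool their cells
  bg2 <- estimateBackground(sp, list(cropWindow(c(1, 1), c(1, 1)),
                                     cropWindow(c(2, 2), c(1, 1))))
  expect_equal(bg2@threshold, 10 + 4 * sqrt(2))
})

test_that("thresholding zeroes strictly sub-threshold cells, monotonically", {
  m <- matrix(c(5, 0, 20, 15), 2, 2)
  expect_equal(applyThreshold(m, 14), matrix(c(0, 0, 20, 15), 2, 2))
  # threshold at/below the minimum is the identity
  expect_equal(applyThreshold(m, 0), m)
  expect_equal(applyThreshold(m, min(m)), m)
  # threshold above the maximum empties the matrix
  expect_true(all(applyThreshold(m, 21) == 0))

  # monotone: raising the threshold never adds non-zero cells
  set.seed(8)
  r <- matrix(runif(400, 0, 100), 20, 20)
  nz <- vapply(seq(0, 110, by = 5),
               function(t) sum(applyThreshold(r, t) > 0), numeric(1))
  expect_true(all(diff(nz) <= 0))

  # BackgroundModel objects are accepted directly
  bgm <- estimateBackground(GCIMSSpectrum(matrix(c(8, 12), 2, 1)),
                            cropWindow(c(1, 2), c(1, 1)))
  expect_equal(applyThreshold(matrix(c(10, 16), 1)  , bgm),
               matrix(c(0, 16), 1))
})

test_that("vectorization is a row-major bijection onto the window", {
  m <- matrix(c(1, 2, 3, 4, 5, 6), 2, 3, byrow = TRUE)
  w <- cropWindow(c(2, 3), c(4, 6))
  v <- vectorizeSpectrum(m, w)
  expect_equal(v$values, c(1, 2, 3, 4, 5, 6))
  expect_equal(nrow(v$locations), 6)
  # feature 5 is the (2nd row, 2nd col) cell, offset by the window origin
  expect_equal(v$locations$retention[5], 3)
  expect_equal(v$locations$drift[5], 5)
  # inverse reshaping restores the matrix
  expect_identical(unvectorizeSpectrum(v$values, w), m)
  # identical windows give identical location tables
  v2 <- vectorizeSpectrum(matrix(rnorm(6), 2, 3), w)
  expect_identical(v2$locations, v$locations)
})

test_that("feature matrix construction stacks per-sample processed rows", {
  d <- smallDesign(nPerGroup = c(3, 3), seed = 12)
  coh <- simulateCohort(d)
  w <- defaultCropWindow(d)
  bgr <- defaultBackgroundRegion(d)
  fm <- buildFeatureMatrix(coh$spectra, w, bgr,
                           labels = paste0("G", coh$labels))
  expect_s4_class(fm, "FeatureMatrix")
  expect_equal(dim(featureValues(fm)), c(6, windowSize(w)))
  expect_equal(sampleIds(fm), coh$sampleIds)

  # permuting the input order permutes the rows identically
  perm <- c(4, 1, 6, 2, 5, 3)
  fmp <- buildFeatureMatrix(coh$spectra[perm], w, bgr)
  expect_identical(featureValues(fmp), featureValues(fm)[perm, ])

  # heterogeneous shapes are rejected
  odd <- simulateSpectrum(smallDesign(shape = c(30, 25), seed = 1), 0)
  expect_error(buildFeatureMatrix(c(coh$spectra, odd), w, bgr),
               "heterogeneous")

  # a crop that is entirely sub-threshold yields an all-zero row, retained
  quiet <- GCIMSSpectrum(matrix(c(rep(1, 50), rep(c(0, 1000), 25)), 10, 10))
  fmz <- buildFeatureMatrix(list(quiet), cropWindow(c(1, 5), c(1, 5)),
                            cropWindow(c(1, 10), c(6, 10)))
  expect_equal(nrow(featureValues(fmz)), 1)
  expect_true(all(featureValues(fmz) == 0))
})

test_that("planted effect cells carry the largest group-mean differences", {
  d <- smallDesign(nPerGroup = c(8, 8), seed = 5, effectMultiplier = 4,
                   noiseSd = 5)
  coh <- simulateCohort(d)
  fm <- buildFeatureMatrix(coh$spectra, defaultCropWindow(d),
                           defaultBackgroundRegion(d))
  x <- featureValues(fm)
  dif <- abs(colMeans(x[coh$labels == 1, ]) - colMeans(x[coh$labels == 0, ]))
  loc <- featureLocations(fm)
  ft <- coh$groundTruth
  inFoot <- paste(loc$retention, loc$drift) %in%
    paste(ft$retention, ft$drift)
  top <- order(dif, decreasing = TRUE)[1:20]
  expect_gte(mean(inFoot[top]), 0.8)
})

test_that("mean-pooled binning reduces resolution with centered locations", {
  m <- matrix(as.numeric(1:16), 4, 4)
  sp <- GCIMSSpectrum(m)
  fm <- buildFeatureMatrix(list(sp), cropWindow(c(1, 4), c(1, 4)),
                           cropWindow(c(1, 4), c(1, 1)), binSize = 2)
  # threshold from constant col 1 values {1,2,3,4}: mean 2.5 + 2*sd
  thr <- 2.5 + 2 * sd(1:4)
  pooled <- applyThreshold(m, thr)
  manual <- c(mean(pooled[1:2, 1:2]), mean(pooled[1:2, 3:4]),
              mean(pooled[3:4, 1:2]), mean(pooled[3:4, 3:4]))
  expect_equal(as.vector(featureValues(fm)), manual)
  loc <- featureLocations(fm)
  expect_equal(loc$retention, c(2, 2, 4, 4))
  expect_equal(loc$drift, c(2, 4, 2, 4))
})

test_that("feature replotting maps locations back onto the spectrum", {
  d <- smallDesign(nPerGroup = c(2, 2), seed = 2)
  sp <- simulateCohort(d)$spectra[[1]]
  sel <- data.frame(retention = c(10, 20), drift = c(15, 25))
  ov <- replotFeatures(sp, sel)
  expect_equal(nrow(ov), 2)
  expect_equal(ov$retention_time, retentionAxis(sp)[c(10, 20)])
  expect_equal(ov$drift_time, driftAxis(sp)[c(15, 25)])
  expect_equal(ov$rank, 1:2)
  # empty selection yields an empty overlay
  expect_equal(nrow(replotFeatures(sp, sel[0, ])), 0)
  # out-of-bounds location is rejected
  expect_error(replotFeatures(sp, data.frame(retention = 999, drift = 1)),
               "bounds")
})
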