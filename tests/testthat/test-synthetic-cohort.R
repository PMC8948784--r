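test_that("degenerate designs produce the constructed matrices", {
  # no peaks, no noise, no RIP: constant baseline
  d <- cohortDesign(nPerGroup = c(2, 2), shape = c(20, 15),
                    ripDriftIndex = 4L, ripAmplitude = 0, noiseSd = 0,
                    baseline = 7, sharedPeaks = emptyPeaks(),
                    effectPeaks = emptyPeaks())
  m <- intensities(simulateSpectrum(d, 0))
  expect_true(all(m == 7))

  # with the RIP on, off-ridge columns still sit at baseline
  d2 <- cohortDesign(nPerGroup = c(2, 2), shape = c(20, 15),
                     ripDriftIndex = 4L, ripAmplitude = 100, noiseSd = 0,
                     baseline = 7, sharedPeaks = emptyPeaks(),
                     effectPeaks = emptyPeaks())
  m2 <- intensities(simulateSpectrum(d2, 0))
  expect_equal(m2[, 15], rep(7, 20), tolerance = 1e-6)  # far Gaussian tail
  expect_true(all(m2[, 4] > 100))

  # a single dominant peak puts the argmax at its center
  d3 <- cohortDesign(nPerGroup = c(2, 2), shape = c(30, 25),
                     ripDriftIndex = 5L, ripAmplitude = 0, noiseSd = 0,
                     baseline = 1, sharedPeaks = emptyPeaks(),
                     effectPeaks = peakSpec(17, 14, 500))
  m3 <- intensities(simulateSpectrum(d3, 0))
  expect_equal(which(m3 == max(m3)), 17L + (14L - 1L) * 30L)
})

test_that("cohort simulation is seed-deterministic with stated group sizes", {
  d <- smallDesign(nPerGroup = c(41, 8), shape = c(30, 25), seed = 9)
  c1 <- simulateCohort(d)
  c2 <- simulateCohort(d)
  expect_identical(lapply(c1$spectra, intensities),
                   lapply(c2$spectra, intensities))
  expect_identical(c1$labels, c2$labels)
  # mirrors the biochemical remission cohort sizes: 41 stayed in remission,
  # 8 flared at the second collection
  expect_equal(sum(c1$labels == 0), 41)
  expect_equal(sum(c1$labels == 1), 8)
  expect_equal(length(c1$spectra), 49)
})

test_that("every generated spectrum is non-negative and valid", {
  set.seed(21)
  for (noise in c(0.5, 10, 60)) {
    d <- smallDesign(nPerGroup = c(2, 2), shape = c(25, 20), seed = 31,
                     noiseSd = noise, baseline = 5)
    coh <- simulateCohort(d)
    for (sp in coh$spectra) {
      expect_true(validObject(sp, test = TRUE))
      expect_true(all(intensities(sp) >= 0))
    }
  }
})

test_that("unit effect multiplier makes the two groups exchangeable", {
  # 50 replicate mini-cohorts under the null; a two-sample t-test on mean
  # intensity should reject at about the nominal 5% rate
  d <- smallDesign(nPerGroup = c(6, 6), shape = c(40, 30),
                   effectMultiplier = 1)
  set.seed(404)
  pvals <- vapply(1:50, function(i) {
    g0 <- replicate(6, mean(intensities(simulateSpectrum(d, 0))))
    g1 <- replicate(6, mean(intensities(simulateSpectrum(d, 1))))
    t.test(g0, g1)$p.value
  }, numeric(1))
  expect_lt(mean(pvals < 0.05), 0.15)
  expect_gt(mean(pvals), 0.25)  # roughly uniform, not piled near 0
})

test_that("ground-truth footprint lists exactly the near-peak cells", {
  d <- cohortDesign(nPerGroup = c(2, 2), shape = c(50, 40),
                    ripDriftIndex = 8L, sharedPeaks = emptyPeaks(),
                    effectPeaks = peakSpec(20, 25, 100, 2, 3))
  ft <- effectFootprint(d)
  expect_true(all(((ft$retention - 20) / 2)^2 + ((ft$drift - 25) / 3)^2
                  <= 4 + 1e-12))
  expect_true(nrow(ft) > 10)
  # the center itself is always in
  expect_true(any(ft$retention == 20 & ft$drift == 25))
})

test_that("simulated metadata closes the loop with the labeller", {
  set.seed(77)
  for (code in c("A1", "A2", "A3", "A4", "B1", "B2", "B3", "B4")) {
    subtype <- if (substr(code, 1, 1) == "A" && code %in% c("A2", "A4"))
      "UC" else "CD"  # exercise both score systems
    md <- simulateMetadata(code, nPairs = 6, subtype = subtype)
    fam <- if (substr(code, 1, 1) == "A") "CLINICAL" else "BIOCHEMICAL"
    pairs <- pairSamples(md, fam)
    expect_equal(nrow(pairs), 6)
    expect_true(all(pairs$group == code))
  }

  # B2: biochemical remission first, exacerbation second
  md <- simulateMetadata("B2", nPairs = 20)
  first <- md[md$seq_index == 1, ]
  second <- md[md$seq_index == 2, ]
  expect_true(all(first$fcp < 100))
  expect_true(all(second$fcp >= 250))

  # A1 in CD: both collections in clinical remission (HBI < 4)
  md <- simulateMetadata("A1", nPairs = 15, subtype = "CD")
  expect_true(all(md$hbi < 4))

  # group counts reproduce the requested cohort structure
  md41 <- simulateMetadata("B1", nPairs = 41, prefix = "R")
  md8 <- simulateMetadata("B2", nPairs = 8, prefix = "E")
  counts <- groupCounts(pairSamples(rbind(md41, md8), "BIOCHEMICAL"))
  expect_equal(counts[["B1"]], 41)
  expect_equal(counts[["B2"]], 8)

  expect_error(simulateMetadata("C1", 5), "unknown")
})
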