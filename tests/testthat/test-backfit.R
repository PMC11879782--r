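test_that("peak labels reproduce planted labels on noise-free data", {
  sim <- fixtureSim(K = 4, nChannels = 16, durationS = 5, snr = Inf, seed = 23)
  g <- gfp(sim$recording)
  pk <- findGFPPeaks(g, 500, 10)
  pl <- backfitPeaks(sim$recording, sim$groundTruth$templates, pk)
  truth <- stateLabels(sim$groundTruth$labels)[pk]
  expect_equal(mean(pl == truth), 1)
  # a peak map equal to a template is labelled as that template
  M <- templateMaps(sim$groundTruth$templates)
  one <- EEGRecording(t(M[3, , drop = FALSE]), samplingRate = 500,
                      averageReferenced = TRUE)
  expect_equal(backfitPeaks(one, sim$groundTruth$templates, 1L), 3L)
  expect_error(backfitPeaks(one, sim$groundTruth$templates, integer(0)),
               "insufficient")
})

test_that("peak labelling stays accurate at snr 5", {
  sim <- fixtureSim(K = 4, nChannels = 64, durationS = 20, snr = 5, seed = 29,
                    meanDurationsMs = c(40, 57, 73, 90))
  g <- gfp(sim$recording)
  pk <- findGFPPeaks(g, 500, 10)
  pl <- backfitPeaks(sim$recording, sim$groundTruth$templates, pk)
  truth <- stateLabels(sim$groundTruth$labels)[pk]
  expect_gte(mean(pl == truth), 0.90)
})

test_that("nearest-neighbour interpolation obeys midpoint and boundary rules", {
  # peaks at 0-based samples 10 (class A=1) and 20 (class B=2)
  seq_ <- interpolateLabels(c(1L, 2L), c(11L, 21L), nSamples = 30,
                            samplingRate = 500, nClasses = 2)
  labs <- stateLabels(seq_)
  expect_equal(labs[15], 1L)  # 0-based 14 -> A
  expect_equal(labs[16], 1L)  # 0-based 15, equidistant -> earlier peak
  expect_equal(labs[17], 2L)  # 0-based 16 -> B
  expect_true(all(labs[1:11] == 1L))   # before the first peak
  expect_true(all(labs[22:30] == 2L))  # after the last peak
  # single peak labels everything
  allone <- interpolateLabels(2L, 5L, nSamples = 12, samplingRate = 500,
                              nClasses = 3)
  expect_true(all(stateLabels(allone) == 2L))
})

test_that("segment runs are maximal, half-open and round-trip", {
  s <- LabelSequence(c(1, 1, 2, 2, 2, 1), samplingRate = 500, nClasses = 2)
  runs <- segmentRuns(s)
  expect_equal(runs$class, c(1L, 2L, 1L))
  expect_equal(runs$start_sample, c(0L, 2L, 5L))
  expect_equal(runs$end_sample, c(2L, 5L, 6L))
  const <- LabelSequence(rep(3L, 10), samplingRate = 500, nClasses = 3)
  expect_equal(nrow(segmentRuns(const)), 1L)
  # property: expand(segmentRuns(x)) == x on random sequences
  set.seed(41)
  for (i in 1:10) {
    labs <- sample.int(4, 200, replace = TRUE)
    x <- LabelSequence(labs, samplingRate = 250, nClasses = 4)
    expect_identical(stateLabels(expandRuns(segmentRuns(x), 250, 4)), labs)
  }
})

test_that("features follow the edge-exclusion arithmetic of the worked example", {
  # fs = 500: A x15, B x5, A x10, B x20, A x5 (55 samples, 0.11 s)
  labs <- c(rep(1L, 15), rep(2L, 5), rep(1L, 10), rep(2L, 20), rep(1L, 5))
  f <- computeFeatures(LabelSequence(labs, samplingRate = 500, nClasses = 2))
  tab <- featureTable(f)
  expect_equal(tab$mean_duration_ms[1], 20)          # interior A run: 10 samples
  expect_equal(tab$mean_duration_ms[2], 25)          # B runs 5 and 20 -> 12.5 * 2 ms
  expect_equal(tab$occurrence_hz[2], 2 / 0.11, tolerance = 1e-12)
  expect_equal(tab$occurrence_hz[1], 1 / 0.11, tolerance = 1e-12)
  expect_equal(tab$coverage, c(30 / 55, 25 / 55), tolerance = 1e-12)
  expect_equal(sum(tab$coverage), 1)
  # edge runs can be opted back in
  fAll <- computeFeatures(LabelSequence(labs, 500, 2), includeEdgeRuns = TRUE)
  expect_equal(featureTable(fAll)$occurrence_hz[1], 3 / 0.11, tolerance = 1e-12)
})

test_that("a constant sequence has missing duration, zero occurrence, full coverage", {
  f <- computeFeatures(LabelSequence(rep(2L, 100), samplingRate = 500,
                                     nClasses = 3))
  tab <- featureTable(f)
  expect_true(all(is.na(tab$mean_duration_ms)))
  expect_equal(tab$occurrence_hz, c(0, 0, 0))
  expect_equal(tab$coverage, c(0, 1, 0))
})

test_that("features are equivariant under class relabelling", {
  set.seed(43)
  labs <- sample.int(3, 500, replace = TRUE)
  f1 <- featureTable(computeFeatures(LabelSequence(labs, 500, 3)))
  perm <- c(3L, 1L, 2L)
  f2 <- featureTable(computeFeatures(LabelSequence(perm[labs], 500, 3)))
  # class k of f1 must equal class perm[k] of f2
  for (k in 1:3) {
    expect_equal(f1$mean_duration_ms[k], f2$mean_duration_ms[perm[k]])
    expect_equal(f1$occurrence_hz[k], f2$occurrence_hz[perm[k]])
    expect_equal(f1$coverage[k], f2$coverage[perm[k]])
  }
})

test_that("duration x occurrence approaches coverage x 1000 on long sequences", {
  cfg <- generatorConfig(nClasses = 4L, samplingRate = 500, durationS = 600,
                         nChannels = 8, meanDurationsMs = c(40, 60, 80, 100),
                         seed = 47)
  f <- computeFeatures(simulateLabels(cfg))
  tab <- featureTable(f)
  lhs <- tab$mean_duration_ms * tab$occurrence_hz
  rhs <- tab$coverage * 1000
  expect_true(all(abs(lhs - rhs) / rhs < 0.02))
})
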