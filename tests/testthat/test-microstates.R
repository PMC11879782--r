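test_that("gfp matches the channel standard deviation and scales linearly", {
  rec <- EEGRecording(matrix(c(0, 0, 1, -1, 3, -3), 2, 3),
                      samplingRate = 100, averageReferenced = TRUE)
  expect_equal(gfp(rec), c(0, 1, 3))
  expect_equal(gfp(EEGRecording(3 * eegData(rec), 100,
                                averageReferenced = TRUE)),
               3 * gfp(rec))
  raw <- EEGRecording(matrix(rnorm(40), 4, 10), 100)
  expect_error(gfp(raw), "average-referenced")
  expect_equal(gfp(raw, autoReference = TRUE), gfp(averageReference(raw)))
})

test_that("GFP peak finding keeps strict local maxima with a distance rule", {
  expect_equal(findGFPPeaks(c(0, 1, 0, 2, 0), 1000, minDistanceMs = 0),
               c(2L, 4L))
  expect_equal(findGFPPeaks(1:10, 1000), integer(0))
  expect_equal(findGFPPeaks(c(1, 2), 1000), integer(0))
  # closer than min distance: the larger peak survives
  g <- c(0, 3, 0, 5, 0, 0, 0, 0, 0, 0, 0, 4, 0)
  expect_equal(findGFPPeaks(g, 1000, minDistanceMs = 5), c(4L, 12L))
  # tie in GFP resolves to the earlier index
  g2 <- c(0, 5, 0, 5, 0)
  expect_equal(findGFPPeaks(g2, 1000, minDistanceMs = 5), 2L)
})

test_that("spatial correlation handles polarity, orthogonality and errors", {
  u <- c(1, -1, 2, -2); u <- u - mean(u)
  expect_equal(spatialCorrelation(u, u), 1)
  expect_equal(spatialCorrelation(u, -u, polarityInvariant = TRUE), 1)
  expect_equal(spatialCorrelation(u, -u, polarityInvariant = FALSE), -1)
  M <- orthoMaps(2, 6)
  expect_equal(spatialCorrelation(M[1, ], M[2, ]), 0, tolerance = 1e-12)
  expect_error(spatialCorrelation(u, rep(1, 4)), "zero-variance")
  expect_error(spatialCorrelation(u, c(1, 2, 3)), "equal channel")
})

test_that("gev matches the closed form and its boundary cases", {
  M <- orthoMaps(2, 8)
  # every map proportional to its template -> 1
  maps <- rbind(2 * M[1, ], 5 * M[2, ], -3 * M[1, ])
  expect_equal(gev(maps, M, c(1L, 2L, 1L)), 1, tolerance = 1e-12)
  # every map orthogonal to its assigned template -> 0
  expect_equal(gev(maps, M, c(2L, 1L, 2L)), 0, tolerance = 1e-12)
  # two maps with gfp (1, 2) and correlations (1, 0) -> 1/5
  maps2 <- rbind(M[1, ], 2 * M[2, ])
  g2 <- sqrt(rowMeans(maps2^2))
  expect_equal(gev(maps2, M, c(1L, 1L), gfpValues = g2), 1 / 5,
               tolerance = 1e-12)
  expect_error(gev(matrix(0, 2, 8), M, c(1L, 2L)), "undefined")
})

test_that("modified k-means recovers an exact noise-free mixture", {
  M <- orthoMaps(3, 10)
  set.seed(5)
  amp <- runif(60, 0.5, 2)
  lab <- rep(1:3, 20)
  maps <- M[lab, ] * amp
  res <- modifiedKMeans(maps, 3, nRestarts = 10, seed = 1)
  expect_equal(res@gev, 1, tolerance = 1e-9)
  srt <- sortToTemplates(res@templates, TemplateSet(M))
  expect_equal(srt$sharedVariance, rep(1, 3), tolerance = 1e-9)
})

test_that("clustering is polarity- and scale-invariant and seed-deterministic", {
  set.seed(8)
  sim <- fixtureSim(K = 3, durationS = 3, snr = 10, seed = 21)
  pk <- findGFPPeaks(gfp(sim$recording), 500, 10)
  maps <- t(eegData(sim$recording))[pk, ]
  a <- modifiedKMeans(maps, 3, nRestarts = 5, seed = 4)
  b <- modifiedKMeans(-2.5 * maps, 3, nRestarts = 5, seed = 4)
  expect_identical(a@peakLabels, b@peakLabels)
  expect_equal(a@gev, b@gev, tolerance = 1e-9)
  expect_equal(abs(rowSums(templateMaps(a@templates) *
                           templateMaps(b@templates))),
               rep(1, 3), tolerance = 1e-9, ignore_attr = TRUE)
  c_ <- modifiedKMeans(maps, 3, nRestarts = 5, seed = 4)
  expect_identical(a@peakLabels, c_@peakLabels)
  expect_equal(a@gev, c_@gev)
  expect_error(modifiedKMeans(maps[1:2, ], 3), "at least K")
})

test_that("k-means GEV equals the exhaustive bipartition optimum (8 maps, K = 2)", {
  set.seed(17)
  C <- 10
  maps <- matrix(rnorm(8 * C), 8, C)
  maps <- maps - rowMeans(maps)
  gfpv <- sqrt(rowMeans(maps^2))
  # oracle: enumerate all 127 bipartitions; per side the template is the
  # dominant right singular vector; GEV from the plain formula
  bruteGEV <- function(side) {
    Tm <- matrix(0, 2, C)
    for (k in 1:2) {
      Xk <- maps[side == k, , drop = FALSE]
      v <- if (nrow(Xk) == 1L) Xk[1, ] else svd(Xk, nu = 0, nv = 1)$v[, 1]
      Tm[k, ] <- v / sqrt(sum(v^2))
    }
    r <- vapply(1:8, function(i) {
      x <- maps[i, ]
      abs(sum(x * Tm[side[i], ]) / sqrt(sum(x^2)))
    }, numeric(1))
    sum((gfpv * r)^2) / sum(gfpv^2)
  }
  best <- -Inf
  for (mask in 1:127) {
    side <- as.integer(intToBits(mask)[1:8]) + 1L
    if (length(unique(side)) == 2L) best <- max(best, bruteGEV(side))
  }
  fit <- modifiedKMeans(maps, 2, nRestarts = 100, seed = 3)
  expect_equal(fit@gev, best, tolerance = 1e-9)
})

test_that("individual clustering recovers planted maps and handles degenerate K", {
  sim <- fixtureSim(K = 3, nChannels = 16, durationS = 6, snr = Inf, seed = 13)
  res <- clusterIndividual(sim$recording, 3, nRestarts = 10, seed = 2)
  srt <- sortToTemplates(res@templates, sim$groundTruth$templates)
  expect_true(all(sqrt(srt$sharedVariance) >= 0.999))
  # K = 1: single template equals the dominant eigenvector of the peak maps
  one <- clusterIndividual(sim$recording, 1, nRestarts = 2, seed = 2)
  pk <- attr(res, "peaks")
  X <- t(eegData(sim$recording))[pk, ]
  X <- X - rowMeans(X)
  v <- svd(X, nu = 0, nv = 1)$v[, 1]
  expect_equal(abs(sum(templateMaps(one@templates)[1, ] * v)), 1,
               tolerance = 1e-6)
  # far fewer peaks than K
  tiny <- EEGRecording(matrix(c(0, 1, 0, 1, 0, 0, -1, 0, -1, 0), 2, 5,
                              byrow = TRUE),
                       samplingRate = 500, averageReferenced = TRUE)
  expect_error(clusterIndividual(tiny, 7), "insufficient")
})

test_that("grand-mean clustering pools individual template sets", {
  tpl <- fixtureTemplates(K = 3, n = 16, seed = 31)
  sets <- list(tpl, tpl, tpl)
  res <- clusterGrandMean(sets, 3, nRestarts = 10, seed = 5)
  expect_equal(res@gev, 1, tolerance = 1e-9)
  srt <- sortToTemplates(res@templates, tpl)
  expect_equal(srt$sharedVariance, rep(1, 3), tolerance = 1e-9)
  expect_identical(provenance(res@templates), "grand_mean")
  # channel mismatch is rejected
  other <- fixtureTemplates(K = 3, n = 12, seed = 31)
  expect_error(clusterGrandMean(list(tpl, other), 3), "channel")
})

test_that("sorting recovers a planted permutation with sign flips", {
  ref <- fixtureTemplates(K = 5, n = 16, seed = 51)
  perm <- c(4L, 1L, 5L, 2L, 3L)
  flips <- c(1, -1, 1, -1, 1)
  cand <- TemplateSet(templateMaps(ref)[perm, ] * flips,
                      provenance = "grand_mean")
  out <- sortToTemplates(cand, ref)
  expect_equal(out$assignment, perm)
  expect_equal(out$sharedVariance, rep(1, 5), tolerance = 1e-12)
  expect_equal(templateMaps(out$sorted), templateMaps(ref),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_identical(classNames(out$sorted), classNames(ref))
  # identity case
  idt <- sortToTemplates(ref, ref)
  expect_equal(idt$assignment, 1:5)
})

test_that("assignment total equals the exhaustive permutation optimum (7 x 7)", {
  set.seed(19)
  mon <- fixtureMontage(16, seed = 61)
  cand <- makeTemplates(mon, 7, maxAbsCorr = 0.9, seed = 62)
  ref <- makeTemplates(mon, 7, maxAbsCorr = 0.9, seed = 63)
  R2 <- matrix(0, 7, 7)
  for (i in 1:7) for (j in 1:7)
    R2[i, j] <- spatialCorrelation(templateMaps(cand)[i, ],
                                   templateMaps(ref)[j, ])^2
  best <- -Inf
  for (p in allPermutations(7))
    best <- max(best, sum(R2[cbind(1:7, p)]))
  out <- sortToTemplates(cand, ref)
  expect_equal(sum(out$sharedVariance), best, tolerance = 1e-12)
})

test_that("GEV is non-decreasing in K with sufficient restarts", {
  sim <- fixtureSim(K = 4, durationS = 4, snr = 3, seed = 77)
  pk <- findGFPPeaks(gfp(sim$recording), 500, 10)
  maps <- t(eegData(sim$recording))[pk, ]
  gevs <- vapply(1:5, function(K)
    modifiedKMeans(maps, K, nRestarts = 20, seed = 9)@gev, numeric(1))
  expect_true(all(diff(gevs) >= -1e-9))
  expect_true(all(gevs >= 0 & gevs <= 1))
})
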