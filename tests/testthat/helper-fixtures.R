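# Shared fixtures: small montages, planted templates and tiny recordings
# built in code at test time.

fixtureMontage <- function(n = 16L, seed = 42L) makeMontage(n, seed = seed)

fixtureTemplates <- function(K = 4L, n = 16L, seed = 7L, maxAbsCorr = 0.7) {
  makeTemplates(fixtureMontage(n), K, maxAbsCorr = maxAbsCorr, seed = seed)
}

# short synthetic recording with planted ground truth
fixtureSim <- function(K = 4L, nChannels = 16L, durationS = 5,
                       snr = Inf, seed = 3L, fs = 500,
                       meanDurationsMs = NULL) {
  cfg <- generatorConfig(nChannels = nChannels, nClasses = K,
                         samplingRate = fs, durationS = durationS,
                         meanDurationsMs = meanDurationsMs, snr = snr,
                         seed = seed)
  simulateRecording(cfg)
}

# all permutations of 1..n (for exhaustive assignment oracles)
allPermutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    rest <- allPermutations(n - 1L)
    for (p in rest) out[[length(out) + 1L]] <- c(i, setdiff(seq_len(n), i)[p])
  }
  out
}

# orthonormal zero-mean maps (rows) for exact-mixture tests
orthoMaps <- function(K, C) {
  stopifnot(C >= K + 1)
  M <- matrix(0, K, C)
  for (k in seq_len(K)) {
    M[k, k] <- 1
    M[k, K + 1] <- -1
  }
  M <- M - rowMeans(M)
  # Gram-Schmidt
  for (k in seq_len(K)) {
    v <- M[k, ]
    if (k > 1) for (j in seq_len(k - 1)) v <- v - sum(v * M[j, ]) * M[j, ]
    M[k, ] <- v / sqrt(sum(v^2))
  }
  M
}
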