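# Synthetic resting-state EEG with planted microstate structure.
#
# The generator plants K quasi-stable topographies, switches between them via
# a semi-Markov process with gamma-distributed segment lengths, modulates the
# active map with a rectified alpha-band sinusoid (so GFP peaks occur at about
# twice the alpha frequency, the structure GFP-peak clustering exploits) and
# adds average-referenced white Gaussian sensor noise at a configured SNR.

#' Generate a quasi-uniform electrode montage on the upper hemisphere
#'
#' Places \code{nChannels} unit-norm electrode positions quasi-uniformly on
#' the upper half of the unit head sphere using a Fibonacci lattice with a
#' small seeded random rotation about the vertical axis.
#'
#' @param nChannels number of electrodes (>= 8).
#' @param seed RNG seed (the montage is deterministic given the seed).
#' @return A [Montage-class] object.
#' @examples
#' mon <- makeMontage(64, seed = 1)
#' range(sqrt(rowSums(positions(mon)^2)))
#' @export
makeMontage <- function(nChannels, seed = 1L) {
  if (nChannels < 8L) stop("a montage needs at least 8 channels")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  i <- seq_len(nChannels) - 0.5
  golden <- pi * (3 - sqrt(5))
  # upper hemisphere: z in (0, 1)
  z <- i / nChannels
  r <- sqrt(1 - z^2)
  theta <- golden * i + runif(1, 0, 2 * pi)
  pos <- cbind(x = r * cos(theta), y = r * sin(theta), z = z)
  pos <- pos / sqrt(rowSums(pos^2))
  new("Montage", channelNames = sprintf("E%03d", seq_len(nChannels)),
      positions = pos)
}

# save/restore the global RNG state so generator calls do not perturb the
# caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Generate planted microstate template topographies
#'
#' Each map is the electrode-space potential field of a few randomly placed,
#' randomly oriented current dipoles inside the head sphere (point-dipole
#' potential in a homogeneous medium), average-referenced and unit-normalised.
#' Maps are accepted by rejection sampling until all pairwise
#' polarity-invariant spatial correlations are at most \code{maxAbsCorr}.
#'
#' @param montage a [Montage-class].
#' @param K number of template classes (>= 1).
#' @param maxAbsCorr upper bound in (0, 1) on pairwise |spatial correlation|.
#' @param seed RNG seed.
#' @param nDipoles dipoles per map (default 3).
#' @param maxTries rejection-sampling budget per map.
#' @return A [TemplateSet-class] with provenance \code{"planted"}.
#' @export
makeTemplates <- function(montage, K, maxAbsCorr = 0.7, seed = 1L,
                          nDipoles = 3L, maxTries = 5000L) {
  stopifnot(is(montage, "Montage"))
  if (K < 1L) stop("K must be >= 1")
  if (maxAbsCorr <= 0 || maxAbsCorr >= 1) stop("maxAbsCorr must be in (0, 1)")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  elec <- montage@positions
  maps <- matrix(NA_real_, K, nrow(elec))
  k <- 1L
  tries <- 0L
  while (k <= K) {
    if (tries >= maxTries)
      stop(sprintf("could not satisfy maxAbsCorr = %g within %d rejection rounds",
                   maxAbsCorr, maxTries))
    m <- .dipoleMap(elec, nDipoles)
    ok <- TRUE
    if (k > 1L) {
      cors <- abs(maps[seq_len(k - 1L), , drop = FALSE] %*% m)
      ok <- all(cors <= maxAbsCorr)
    }
    tries <- tries + 1L
    if (ok) {
      maps[k, ] <- m
      k <- k + 1L
      tries <- 0L
    }
  }
  colnames(maps) <- montage@channelNames
  TemplateSet(maps, classNames = make.unique(rep(LETTERS, length.out = K)),
              provenance = "planted")
}

# potential of nDipoles random current dipoles at the electrode positions,
# average-referenced and unit-normalised
.dipoleMap <- function(elec, nDipoles) {
  v <- numeric(nrow(elec))
  for (d in seq_len(nDipoles)) {
    # dipole location within radius 0.8, biased to the upper half (cortex)
    repeat {
      p <- runif(3, -1, 1)
      if (sum(p^2) <= 1) break
    }
    p <- p * 0.8
    p[3] <- abs(p[3])
    q <- rnorm(3)
    q <- q / sqrt(sum(q^2))
    dr <- sweep(elec, 2, p)          # electrode - dipole vectors
    dist3 <- (sqrt(rowSums(dr^2)))^3
    v <- v + as.numeric(dr %*% q) / pmax(dist3, 1e-6)
  }
  v <- v - mean(v)
  v / sqrt(sum(v^2))
}

#' Configuration for the synthetic recording generator
#'
#' @param nChannels electrode count (default 64).
#' @param nClasses number of planted microstate classes K (default 7).
#' @param samplingRate sampling rate in Hz (default 500).
#' @param durationS recording length in seconds (default 300).
#' @param meanDurationsMs per-class target mean segment length in ms; a single
#'   value is recycled. Defaults to K values evenly spaced over 20-120 ms, the
#'   range over which scalp topographies remain quasi-stable.
#' @param durationShape shape of the gamma segment-length law (default 4).
#' @param alphaHz frequency of the rectified-sinusoid amplitude envelope
#'   (default 10 Hz, so GFP peaks arrive at ~2 x 10 per second).
#' @param snr ratio of signal RMS to noise RMS (> 0; \code{Inf} = noise-free).
#' @param maxAbsTemplateCorr bound on pairwise |correlation| of planted maps.
#' @param seed RNG seed driving all generator randomness.
#' @return A validated list of class \code{"generatorConfig"}.
#' @export
generatorConfig <- function(nChannels = 64L, nClasses = 7L, samplingRate = 500,
                            durationS = 300, meanDurationsMs = NULL,
                            durationShape = 4, alphaHz = 10, snr = 5,
                            maxAbsTemplateCorr = 0.7, seed = 1L) {
  if (is.null(meanDurationsMs)) {
    meanDurationsMs <- if (nClasses == 1L) 70 else
      seq(20, 120, length.out = nClasses)
  }
  meanDurationsMs <- rep_len(meanDurationsMs, nClasses)
  if (nClasses < 1L) stop("nClasses must be >= 1")
  if (any(meanDurationsMs <= 0 | meanDurationsMs > 1000))
    stop("meanDurationsMs must lie in (0, 1000]")
  if (!(snr > 0)) stop("snr must be positive (possibly Inf)")
  if (maxAbsTemplateCorr <= 0 || maxAbsTemplateCorr >= 1)
    stop("maxAbsTemplateCorr must be in (0, 1)")
  if (samplingRate <= 0 || durationS <= 0)
    stop("samplingRate and durationS must be positive")
  structure(list(nChannels = as.integer(nChannels),
                 nClasses = as.integer(nClasses),
                 samplingRate = samplingRate, durationS = durationS,
                 meanDurationsMs = meanDurationsMs,
                 durationShape = durationShape, alphaHz = alphaHz, snr = snr,
                 maxAbsTemplateCorr = maxAbsTemplateCorr,
                 seed = as.integer(seed)),
            class = "generatorConfig")
}

#' Simulate a semi-Markov microstate label sequence
#'
#' Segment lengths per class are gamma with the configured class mean and
#' common shape (rounded to >= 1 sample); the successor class is drawn
#' uniformly among the other K - 1 classes (no self-transitions).
#'
#' @param config a [generatorConfig()].
#' @return A [LabelSequence-class] of length
#'   \code{round(samplingRate * durationS)}.
#' @export
simulateLabels <- function(config) {
  stopifnot(inherits(config, "generatorConfig"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed + 1L)
  n <- round(config$samplingRate * config$durationS)
  K <- config$nClasses
  meanSamp <- config$meanDurationsMs / 1000 * config$samplingRate
  shape <- config$durationShape
  labs <- integer(n)
  pos <- 0L
  cur <- sample.int(K, 1L)
  while (pos < n) {
    len <- max(1L, as.integer(round(rgamma(1, shape = shape,
                                           scale = meanSamp[cur] / shape))))
    len <- min(len, n - pos)
    labs[(pos + 1L):(pos + len)] <- cur
    pos <- pos + len
    cur <- if (K == 1L) 1L else sample(seq_len(K)[-cur], 1L)
  }
  LabelSequence(labs, samplingRate = config$samplingRate, nClasses = K)
}

#' Synthesize a noisy multichannel recording from planted structure
#'
#' Sample t is \code{A_t * template[label_t] + noise_t}, where
#' \code{A_t = a * |sin(2*pi*alphaHz*t/fs + phi)|} with a seeded phase and the
#' amplitude \code{a} scaled so that signal RMS / noise RMS equals the
#' configured SNR. Noise is zero-mean white Gaussian per channel, then
#' average-referenced; the returned recording is average-referenced.
#'
#' @param templates planted [TemplateSet-class] (K maps).
#' @param labels a [LabelSequence-class] with values in 1..K.
#' @param config the [generatorConfig()] driving envelope, SNR and seed.
#' @return A list with elements \code{recording} ([EEGRecording-class]) and
#'   \code{groundTruth} (list: \code{templates}, \code{labels},
#'   \code{features} computed from the planted labels).
#' @export
synthesizeRecording <- function(templates, labels, config) {
  stopifnot(is(templates, "TemplateSet"), is(labels, "LabelSequence"))
  if (max(labels@labels) > nrow(templates@maps))
    stop("label sequence refers to classes beyond the template set")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed + 2L)
  n <- length(labels@labels)
  fs <- config$samplingRate
  phi <- runif(1, 0, 2 * pi)
  env <- abs(sin(2 * pi * config$alphaHz * (seq_len(n) - 1L) / fs + phi))
  # channels x samples signal: active template scaled by the envelope
  sig <- t(templates@maps)[, labels@labels, drop = FALSE] *
    rep(env, each = ncol(templates@maps))
  sigRMS <- sqrt(mean(sig^2))
  if (is.infinite(config$snr)) {
    dat <- sig
  } else {
    noise <- matrix(rnorm(length(sig)), nrow(sig), ncol(sig))
    noise <- sweep(noise, 2, colMeans(noise))   # average-reference the noise
    noiseRMS <- sqrt(mean(noise^2))
    dat <- sig + noise * (sigRMS / (config$snr * noiseRMS))
  }
  rec <- EEGRecording(dat, samplingRate = fs,
                      channelNames = colnames(templates@maps),
                      averageReferenced = TRUE)
  list(recording = rec,
       groundTruth = list(templates = templates, labels = labels,
                          features = computeFeatures(labels)))
}

#' One-call synthetic recording with planted ground truth
#'
#' Convenience wrapper chaining [makeMontage()], [makeTemplates()],
#' [simulateLabels()] and [synthesizeRecording()].
#'
#' @param config a [generatorConfig()].
#' @param montage optional pre-built [Montage-class] (shared across subjects).
#' @param templates optional pre-built planted [TemplateSet-class].
#' @return As [synthesizeRecording()], plus \code{montage} and \code{config}.
#' @export
simulateRecording <- function(config = generatorConfig(), montage = NULL,
                              templates = NULL) {
  if (is.null(montage)) montage <- makeMontage(config$nChannels, seed = config$seed)
  if (is.null(templates))
    templates <- makeTemplates(montage, config$nClasses,
                               maxAbsCorr = config$maxAbsTemplateCorr,
                               seed = config$seed)
  labels <- simulateLabels(config)
  out <- synthesizeRecording(templates, labels, config)
  out$montage <- montage
  out$config <- config
  out
}
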