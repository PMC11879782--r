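# Average re-referencing and zero-phase frequency filtering.

#' Re-reference a recording to the channel average
#'
#' Subtracts, at every sample, the instantaneous mean across channels.
#' Idempotent, and removes any common-mode offset shared by all channels.
#'
#' @param rec an [EEGRecording-class] with >= 2 channels.
#' @return The average-referenced [EEGRecording-class] (flag set).
#' @export
averageReference <- function(rec) {
  stopifnot(is(rec, "EEGRecording"))
  if (nChannels(rec) < 2L)
    stop("average reference requires at least 2 channels")
  dat <- rec@data
  dat <- sweep(dat, 2, colMeans(dat))
  EEGRecording(dat, samplingRate = rec@samplingRate,
               channelNames = rec@channelNames, averageReferenced = TRUE)
}

#' Filter specification
#'
#' Corner frequencies of the standard resting-state chain: 0.5 Hz high-pass,
#' 50 Hz low-pass and a 60 Hz power-line notch. Any stage can be disabled by
#' passing \code{NULL}. The high/low-pass stages are 4th-order Butterworth
#' filters applied forward-backward (zero phase); the notch is a 2nd-order
#' IIR biquad with quality factor \code{notchQ}.
#'
#' @param highpass high-pass corner in Hz, or NULL to disable.
#' @param lowpass low-pass corner in Hz, or NULL to disable.
#' @param notch notch centre in Hz, or NULL to disable.
#' @param order Butterworth order for high/low-pass (default 4).
#' @param notchQ notch quality factor (default 30).
#' @return A list of class \code{"filterSpec"}.
#' @export
filterSpec <- function(highpass = 0.5, lowpass = 50, notch = 60,
                       order = 4L, notchQ = 30) {
  if (!is.null(highpass) && !is.null(lowpass) && highpass >= lowpass)
    stop("highpass corner must be below lowpass corner")
  structure(list(highpass = highpass, lowpass = lowpass, notch = notch,
                 order = as.integer(order), notchQ = notchQ),
            class = "filterSpec")
}

# zero-phase (forward-backward) IIR run with reflective padding
.filtfiltPad <- function(b, a, x, npad) {
  n <- length(x)
  npad <- min(npad, n - 1L)
  pre <- 2 * x[1] - x[seq(npad + 1L, 2L)]
  post <- 2 * x[n] - x[seq(n - 1L, n - npad)]
  xp <- c(pre, x, post)
  y <- as.numeric(signal::filter(b, a, xp))
  y <- rev(as.numeric(signal::filter(b, a, rev(y))))
  y[(npad + 1L):(npad + n)]
}

# 2nd-order IIR notch biquad (centre f0, quality Q) at sampling rate fs
.notchCoef <- function(f0, fs, Q) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

#' Apply the filter chain to a recording
#'
#' Each enabled stage is applied forward-backward (zero phase) per channel,
#' with 1 s of reflective padding (configurable) to suppress edge
#' transients. Output length equals input length.
#'
#' @param rec an [EEGRecording-class].
#' @param spec a [filterSpec()].
#' @param padSeconds reflective padding applied before each zero-phase run.
#' @return The filtered [EEGRecording-class].
#' @export
applyFilters <- function(rec, spec = filterSpec(), padSeconds = 1) {
  stopifnot(is(rec, "EEGRecording"), inherits(spec, "filterSpec"))
  fs <- rec@samplingRate
  nyq <- fs / 2
  for (f in c(spec$highpass, spec$lowpass, spec$notch))
    if (!is.null(f) && f >= nyq)
      stop("corner frequency must be below the Nyquist frequency")
  npad <- max(1L, round(padSeconds * fs))
  stages <- list()
  if (!is.null(spec$highpass)) {
    bt <- signal::butter(spec$order, spec$highpass / nyq, type = "high")
    stages <- c(stages, list(list(b = bt$b, a = bt$a)))
  }
  if (!is.null(spec$lowpass)) {
    bt <- signal::butter(spec$order, spec$lowpass / nyq, type = "low")
    stages <- c(stages, list(list(b = bt$b, a = bt$a)))
  }
  if (!is.null(spec$notch))
    stages <- c(stages, list(.notchCoef(spec$notch, fs, spec$notchQ)))
  dat <- rec@data
  for (st in stages)
    dat <- t(apply(dat, 1, function(x) .filtfiltPad(st$b, st$a, x, npad)))
  EEGRecording(dat, samplingRate = fs, channelNames = rec@channelNames,
               averageReferenced = rec@averageReferenced)
}
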