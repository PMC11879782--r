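# Backfitting: relabel a recording with sorted templates at GFP peaks,
# interpolate labels by nearest neighbour, and extract per-class temporal
# features (mean duration, occurrence, coverage).

#' Assign GFP-peak maps to template classes
#'
#' Each peak map is assigned to the template with the largest squared
#' spatial correlation; ties resolve to the lowest class index.
#'
#' @param rec average-referenced [EEGRecording-class].
#' @param templates sorted [TemplateSet-class] (grand-mean or reference).
#' @param peaks integer vector of 1-based GFP-peak sample indices.
#' @return Integer vector of class indices (1..K), one per peak.
#' @export
backfitPeaks <- function(rec, templates, peaks) {
  stopifnot(is(rec, "EEGRecording"), is(templates, "TemplateSet"))
  if (length(peaks) < 1L) stop("insufficient data: empty peak set")
  X <- t(rec@data[, peaks, drop = FALSE])
  R <- .absCorrMatrix(X, templates@maps)
  max.col(R, ties.method = "first")
}

#' Interpolate peak labels to a full-length label sequence
#'
#' Every sample takes the label of its nearest peak (nearest-neighbour
#' criterion); exact midpoints go to the earlier peak, and samples before the
#' first / after the last peak take that terminal peak's label.
#'
#' @param peakLabels class index per peak (1..K).
#' @param peakIndices 1-based, strictly increasing peak sample positions.
#' @param nSamples total number of samples to label.
#' @param samplingRate sampling rate in Hz.
#' @param nClasses K (defaults to \code{max(peakLabels)}).
#' @return A [LabelSequence-class] of length \code{nSamples}.
#' @export
interpolateLabels <- function(peakLabels, peakIndices, nSamples, samplingRate,
                              nClasses = max(peakLabels)) {
  if (length(peakIndices) < 1L) stop("at least one peak is required")
  stopifnot(length(peakLabels) == length(peakIndices))
  # sample s belongs to peak i when s <= midpoint(i, i+1); exact midpoints
  # fall to the earlier peak via floor()
  cuts <- floor((peakIndices[-length(peakIndices)] +
                 peakIndices[-1]) / 2)
  owner <- findInterval(seq_len(nSamples), c(cuts + 1L)) + 1L
  LabelSequence(peakLabels[owner], samplingRate = samplingRate,
                nClasses = nClasses)
}

#' Run-length segmentation of a label sequence
#'
#' Maximal constant-label runs as half-open, 0-based \code{[start, end)}
#' intervals; the concatenation of the runs reproduces the sequence.
#'
#' @param seq a [LabelSequence-class].
#' @return data.frame with columns \code{class}, \code{start_sample},
#'   \code{end_sample}.
#' @export
segmentRuns <- function(seq) {
  stopifnot(is(seq, "LabelSequence"))
  r <- rle(seq@labels)
  ends <- cumsum(r$lengths)
  data.frame(class = r$values, start_sample = ends - r$lengths,
             end_sample = ends)
}

#' Expand a segment table back to a label sequence
#'
#' Inverse of [segmentRuns()].
#'
#' @param segments data.frame as returned by [segmentRuns()].
#' @param samplingRate sampling rate in Hz.
#' @param nClasses K (defaults to the largest class present).
#' @return A [LabelSequence-class].
#' @export
expandRuns <- function(segments, samplingRate, nClasses = max(segments$class)) {
  LabelSequence(rep(segments$class,
                    segments$end_sample - segments$start_sample),
                samplingRate = samplingRate, nClasses = nClasses)
}

#' Temporal microstate features of a label sequence
#'
#' Per class: mean duration (ms) of its runs, occurrence (runs per second)
#' and coverage (fraction of samples). Runs touching either recording edge
#' are truncated by the recording window, so by default they are excluded
#' from duration and occurrence (they would bias durations downward) but
#' still count toward coverage. A class with no interior run gets a missing
#' duration and occurrence 0. Two subject-level overall durations are
#' returned: the unweighted mean of class means (the default summary) and
#' the segment-weighted mean over all interior runs.
#'
#' @param seq a [LabelSequence-class].
#' @param includeEdgeRuns count edge-truncated runs in duration/occurrence
#'   (default FALSE).
#' @return A [MicrostateFeatures-class].
#' @export
computeFeatures <- function(seq, includeEdgeRuns = FALSE) {
  stopifnot(is(seq, "LabelSequence"))
  fs <- seq@samplingRate
  K <- seq@nClasses
  n <- length(seq@labels)
  totalS <- n / fs
  runs <- segmentRuns(seq)
  lens <- runs$end_sample - runs$start_sample
  interior <- rep(TRUE, nrow(runs))
  if (!includeEdgeRuns) {
    interior[1L] <- FALSE
    interior[nrow(runs)] <- FALSE
  }
  dur <- rep(NA_real_, K)
  occ <- numeric(K)
  cov <- numeric(K)
  for (k in seq_len(K)) {
    cov[k] <- sum(lens[runs$class == k]) / n
    sel <- interior & runs$class == k
    if (any(sel)) {
      dur[k] <- mean(lens[sel]) * 1000 / fs
      occ[k] <- sum(sel) / totalS
    }
  }
  intLens <- lens[interior]
  overall <- c(unweighted = mean(dur, na.rm = TRUE),
               segment_weighted = if (length(intLens))
                 mean(intLens) * 1000 / fs else NA_real_)
  tab <- data.frame(class = seq_len(K), mean_duration_ms = dur,
                    occurrence_hz = occ, coverage = cov)
  new("MicrostateFeatures", table = tab, overallDurationMs = overall,
      samplingRate = fs)
}

#' Backfit a recording and extract features in one call
#'
#' GFP-peak detection, peak labelling against the supplied sorted templates,
#' nearest-neighbour interpolation and feature extraction.
#'
#' @param rec average-referenced [EEGRecording-class].
#' @param templates sorted [TemplateSet-class].
#' @param minDistanceMs minimum GFP-peak separation (default 10 ms).
#' @param includeEdgeRuns passed to [computeFeatures()].
#' @return List: \code{labels} ([LabelSequence-class]), \code{features}
#'   ([MicrostateFeatures-class]), \code{peaks}, \code{peakLabels}.
#' @export
backfitRecording <- function(rec, templates, minDistanceMs = 10,
                             includeEdgeRuns = FALSE) {
  g <- gfp(rec)
  peaks <- findGFPPeaks(g, rec@samplingRate, minDistanceMs)
  if (length(peaks) < 1L) stop("insufficient data: no GFP peaks found")
  pl <- backfitPeaks(rec, templates, peaks)
  labs <- interpolateLabels(pl, peaks, nSamples = ncol(rec@data),
                            samplingRate = rec@samplingRate,
                            nClasses = nrow(templates@maps))
  list(labels = labs, features = computeFeatures(labs, includeEdgeRuns),
       peaks = peaks, peakLabels = pl)
}
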