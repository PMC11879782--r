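#' @import methods
NULL

#' EEGRecording: a multichannel voltage time series
#'
#' Container for a channels x samples voltage matrix (microvolts) together
#' with its sampling rate, channel names and reference state. The average
#' reference flag records whether every sample's channel mean has been
#' removed, the precondition for GFP and all topographic operations.
#'
#' @slot data numeric matrix, channels x samples (microvolts).
#' @slot samplingRate sampling rate in Hz.
#' @slot channelNames character vector, one per row of \code{data}.
#' @slot averageReferenced logical flag.
#'
#' @seealso [averageReference()], [gfp()]
#' @export
setClass("EEGRecording",
  representation(
    data = "matrix",
    samplingRate = "numeric",
    channelNames = "character",
    averageReferenced = "logical"
  )
)

setValidity("EEGRecording", function(object) {
  msg <- NULL
  if (!is.numeric(object@data)) msg <- c(msg, "data must be a numeric matrix")
  if (anyNA(object@data)) msg <- c(msg, "data must not contain missing values")
  if (length(object@samplingRate) != 1L || !is.finite(object@samplingRate) ||
      object@samplingRate <= 0)
    msg <- c(msg, "samplingRate must be a single positive number")
  if (length(object@channelNames) != nrow(object@data))
    msg <- c(msg, "channelNames length must equal the number of rows of data")
  if (anyDuplicated(object@channelNames))
    msg <- c(msg, "channelNames must be unique")
  if (length(object@averageReferenced) != 1L)
    msg <- c(msg, "averageReferenced must be a single logical")
  if (is.null(msg)) TRUE else msg
})

#' Construct an EEGRecording
#'
#' @param data channels x samples numeric matrix (microvolts).
#' @param samplingRate sampling rate in Hz.
#' @param channelNames channel labels; defaults to rownames of \code{data}
#'   or \code{Ch1..ChN}.
#' @param averageReferenced whether the data are already average-referenced.
#' @return An [EEGRecording-class] object.
#' @examples
#' rec <- EEGRecording(matrix(rnorm(40), 4, 10), samplingRate = 500)
#' nChannels(rec)
#' @export
EEGRecording <- function(data, samplingRate, channelNames = NULL,
                         averageReferenced = FALSE) {
  data <- as.matrix(data)
  if (is.null(channelNames)) {
    channelNames <- rownames(data)
    if (is.null(channelNames)) channelNames <- paste0("Ch", seq_len(nrow(data)))
  }
  rownames(data) <- channelNames
  new("EEGRecording", data = data, samplingRate = as.numeric(samplingRate),
      channelNames = as.character(channelNames),
      averageReferenced = isTRUE(averageReferenced))
}

#' Montage: electrode positions on a unit head sphere
#'
#' @slot channelNames unique channel labels (>= 8 channels).
#' @slot positions n x 3 matrix of unit-norm 3D positions.
#' @export
setClass("Montage",
  representation(channelNames = "character", positions = "matrix")
)

setValidity("Montage", function(object) {
  msg <- NULL
  if (nrow(object@positions) < 8L) msg <- c(msg, "a montage needs >= 8 channels")
  if (ncol(object@positions) != 3L) msg <- c(msg, "positions must be n x 3")
  if (length(object@channelNames) != nrow(object@positions))
    msg <- c(msg, "one channel name per position required")
  if (anyDuplicated(object@channelNames))
    msg <- c(msg, "channel names must be unique")
  nrm <- sqrt(rowSums(object@positions^2))
  if (any(abs(nrm - 1) > 1e-9))
    msg <- c(msg, "all positions must have unit Euclidean norm")
  if (is.null(msg)) TRUE else msg
})

#' TemplateSet: a set of microstate topographies
#'
#' K zero-mean, unit-norm channel topographies with class labels and a
#' provenance tag recording how they were obtained. The optional \code{gev}
#' slot carries the global explained variance of the clustering run that
#' produced the maps.
#'
#' @slot maps K x channels numeric matrix; each row zero-mean, unit L2 norm.
#' @slot classNames one label per map (the A-G convention when K = 7).
#' @slot provenance one of "individual", "grand_mean", "reference", "planted".
#' @slot gev global explained variance in [0, 1], or NA when not applicable.
#' @export
setClass("TemplateSet",
  representation(maps = "matrix", classNames = "character",
                 provenance = "character", gev = "numeric")
)

setValidity("TemplateSet", function(object) {
  msg <- NULL
  if (nrow(object@maps) < 1L) msg <- c(msg, "at least one map required")
  if (length(object@classNames) != nrow(object@maps))
    msg <- c(msg, "one class name per map required")
  if (!object@provenance %in% c("individual", "grand_mean", "reference", "planted"))
    msg <- c(msg, "provenance must be individual/grand_mean/reference/planted")
  rm_ <- rowMeans(object@maps)
  if (any(abs(rm_) > 1e-8)) msg <- c(msg, "maps must be zero-mean across channels")
  nrm <- sqrt(rowSums(object@maps^2))
  if (any(abs(nrm - 1) > 1e-8)) msg <- c(msg, "maps must have unit L2 norm")
  if (length(object@gev) != 1L ||
      (!is.na(object@gev) && (object@gev < -1e-12 || object@gev > 1 + 1e-12)))
    msg <- c(msg, "gev must be a single value in [0, 1] or NA")
  if (is.null(msg)) TRUE else msg
})

#' Construct a TemplateSet
#'
#' Rows are average-referenced and unit-normalised on construction.
#'
#' @param maps K x channels matrix of topographies (one map per row).
#' @param classNames labels for the maps; defaults to A, B, C, ... in row order.
#' @param provenance provenance tag (see [TemplateSet-class]).
#' @param gev optional global explained variance of the producing run.
#' @return A [TemplateSet-class] object.
#' @export
TemplateSet <- function(maps, classNames = NULL, provenance = "reference",
                        gev = NA_real_) {
  maps <- as.matrix(maps)
  maps <- maps - rowMeans(maps)
  nrm <- sqrt(rowSums(maps^2))
  if (any(nrm == 0)) stop("template maps must be non-zero")
  maps <- maps / nrm
  if (is.null(classNames)) {
    classNames <- make.unique(rep(LETTERS, length.out = nrow(maps)))
  }
  rownames(maps) <- classNames
  new("TemplateSet", maps = maps, classNames = as.character(classNames),
      provenance = provenance, gev = as.numeric(gev))
}

#' LabelSequence: per-sample microstate class assignment
#'
#' @slot labels integer vector of class indices in 1..K (one per sample).
#' @slot samplingRate sampling rate in Hz.
#' @slot nClasses number of classes K.
#' @export
setClass("LabelSequence",
  representation(labels = "integer", samplingRate = "numeric",
                 nClasses = "integer")
)

setValidity("LabelSequence", function(object) {
  msg <- NULL
  if (length(object@labels) < 1L) msg <- c(msg, "label sequence must be non-empty")
  if (anyNA(object@labels)) msg <- c(msg, "labels must not be missing")
  if (length(object@labels) &&
      (min(object@labels) < 1L || max(object@labels) > object@nClasses))
    msg <- c(msg, "labels must lie in 1..nClasses")
  if (object@samplingRate <= 0) msg <- c(msg, "samplingRate must be positive")
  if (is.null(msg)) TRUE else msg
})

#' Construct a LabelSequence
#'
#' @param labels integer class indices in 1..K.
#' @param samplingRate sampling rate in Hz.
#' @param nClasses K; defaults to \code{max(labels)}.
#' @return A [LabelSequence-class] object.
#' @export
LabelSequence <- function(labels, samplingRate, nClasses = max(labels)) {
  new("LabelSequence", labels = as.integer(labels),
      samplingRate = as.numeric(samplingRate), nClasses = as.integer(nClasses))
}

#' ClusterResult: output of modified k-means clustering
#'
#' @slot templates the fitted [TemplateSet-class].
#' @slot peakLabels class assignment of each clustered map (1..K).
#' @slot gev global explained variance of the returned solution.
#' @slot nIterations iterations used by the winning restart.
#' @slot restartIndex which restart won (1-based).
#' @export
setClass("ClusterResult",
  representation(templates = "TemplateSet", peakLabels = "integer",
                 gev = "numeric", nIterations = "integer",
                 restartIndex = "integer")
)

setValidity("ClusterResult", function(object) {
  msg <- NULL
  if (object@gev < -1e-12 || object@gev > 1 + 1e-9)
    msg <- c(msg, "gev must lie in [0, 1]")
  K <- nrow(object@templates@maps)
  if (length(object@peakLabels) &&
      (min(object@peakLabels) < 1L || max(object@peakLabels) > K))
    msg <- c(msg, "peak labels must lie in 1..K")
  if (is.null(msg)) TRUE else msg
})

#' MicrostateFeatures: per-class temporal features of a label sequence
#'
#' Per-class mean duration (ms), occurrence (Hz) and coverage, plus two
#' subject-level overall mean durations (unweighted mean of class means, the
#' default summary, and the segment-weighted mean over all interior runs).
#'
#' @slot table data.frame with columns class, mean_duration_ms,
#'   occurrence_hz, coverage (one row per class).
#' @slot overallDurationMs named numeric: \code{unweighted} and
#'   \code{segment_weighted} overall mean durations in ms.
#' @slot samplingRate sampling rate (Hz) of the underlying sequence.
#' @export
setClass("MicrostateFeatures",
  representation(table = "data.frame", overallDurationMs = "numeric",
                 samplingRate = "numeric")
)

setValidity("MicrostateFeatures", function(object) {
  msg <- NULL
  need <- c("class", "mean_duration_ms", "occurrence_hz", "coverage")
  if (!all(need %in% names(object@table)))
    msg <- c(msg, "table must have class/mean_duration_ms/occurrence_hz/coverage")
  if (abs(sum(object@table$coverage) - 1) > 1e-9)
    msg <- c(msg, "coverage must sum to 1 over classes")
  if (any(object@table$occurrence_hz < 0)) msg <- c(msg, "occurrence must be >= 0")
  if (is.null(msg)) TRUE else msg
})
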