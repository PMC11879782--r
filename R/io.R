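# Plain-text readers and writers for recordings, templates, labels,
# features and generator/pipeline configuration.

#' Write a recording to delimited text
#'
#' Tab-delimited: a comment line carrying the sampling rate, then a header
#' row and one row per channel (first column = channel name, remaining
#' columns = samples).
#'
#' @param rec an [EEGRecording-class].
#' @param path output file path.
#' @export
writeRecordingText <- function(rec, path) {
  stopifnot(is(rec, "EEGRecording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sampling_rate_hz=%.10g average_referenced=%d",
                     rec@samplingRate, as.integer(rec@averageReferenced)), con)
  writeLines(paste(c("channel", paste0("s", seq_len(ncol(rec@data)))),
                   collapse = "\t"), con)
  utils::write.table(cbind(channel = rec@channelNames,
                           format(rec@data, digits = 10, trim = TRUE)),
                     con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
}

#' Read a recording from delimited text
#'
#' @param path file written by [writeRecordingText()].
#' @return An [EEGRecording-class].
#' @export
readRecordingText <- function(path) {
  first <- readLines(path, n = 1L)
  if (!startsWith(first, "#"))
    stop("missing sampling-rate header line")
  fs <- as.numeric(sub(".*sampling_rate_hz=([0-9.eE+-]+).*", "\\1", first))
  avg <- grepl("average_referenced=1", first)
  tab <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                           check.names = FALSE)
  dat <- as.matrix(tab[, -1, drop = FALSE])
  EEGRecording(dat, samplingRate = fs, channelNames = as.character(tab[[1]]),
               averageReferenced = avg)
}

#' Write templates as a channel x class delimited matrix
#'
#' Tab-delimited with a channel-name first column and class-name header;
#' provenance and GEV travel in a comment line.
#'
#' @param templates a [TemplateSet-class].
#' @param path output file path.
#' @export
writeTemplatesTSV <- function(templates, path) {
  stopifnot(is(templates, "TemplateSet"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# provenance=%s gev=%s", templates@provenance,
                     ifelse(is.na(templates@gev), "NA",
                            format(templates@gev, digits = 10))), con)
  chn <- colnames(templates@maps)
  if (is.null(chn)) chn <- paste0("Ch", seq_len(ncol(templates@maps)))
  tab <- cbind(channel = chn,
               format(t(templates@maps), digits = 12, trim = TRUE))
  colnames(tab) <- c("channel", templates@classNames)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read templates from a channel x class delimited matrix
#'
#' @param path file written by [writeTemplatesTSV()] (or any delimited
#'   channel x class matrix with a channel-name first column).
#' @param provenance provenance tag to use when the file carries none.
#' @return A [TemplateSet-class].
#' @export
readTemplatesTSV <- function(path, provenance = "reference") {
  first <- readLines(path, n = 1L)
  gv <- NA_real_
  if (startsWith(first, "#")) {
    provenance <- sub(".*provenance=(\\S+).*", "\\1", first)
    gvs <- sub(".*gev=(\\S+).*", "\\1", first)
    gv <- suppressWarnings(as.numeric(gvs))
  }
  tab <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                           check.names = FALSE)
  maps <- t(as.matrix(tab[, -1, drop = FALSE]))
  colnames(maps) <- as.character(tab[[1]])
  TemplateSet(maps, classNames = rownames(maps), provenance = provenance,
              gev = gv)
}

#' Write a label sequence to CSV
#'
#' Columns \code{sample_index} (0-based) and \code{class_index} (0-based),
#' matching the interchange convention.
#'
#' @param seq a [LabelSequence-class].
#' @param path output file path.
#' @export
writeLabelsCSV <- function(seq, path) {
  stopifnot(is(seq, "LabelSequence"))
  utils::write.csv(data.frame(sample_index = seq_along(seq@labels) - 1L,
                              class_index = seq@labels - 1L),
                   path, row.names = FALSE, quote = FALSE)
}

#' Read a label sequence from CSV
#'
#' @param path file written by [writeLabelsCSV()].
#' @param samplingRate sampling rate in Hz of the labelled recording.
#' @param nClasses K (defaults to the largest class present).
#' @return A [LabelSequence-class].
#' @export
readLabelsCSV <- function(path, samplingRate, nClasses = NULL) {
  tab <- utils::read.csv(path)
  labs <- tab$class_index[order(tab$sample_index)] + 1L
  if (is.null(nClasses)) nClasses <- max(labs)
  LabelSequence(labs, samplingRate = samplingRate, nClasses = nClasses)
}

#' Write per-class features to CSV
#'
#' One row per subject x class plus a subject-level \code{overall} summary
#' row carrying the unweighted overall mean duration.
#'
#' @param features a [MicrostateFeatures-class] or named list of them (names
#'   = subject ids).
#' @param path output file path.
#' @param classNames optional class labels replacing the 1..K indices.
#' @export
writeFeaturesCSV <- function(features, path, classNames = NULL) {
  if (is(features, "MicrostateFeatures")) features <- list(subject1 = features)
  rows <- lapply(names(features), function(id) {
    f <- features[[id]]
    tab <- f@table
    cls <- if (is.null(classNames)) as.character(tab$class) else
      classNames[tab$class]
    rbind(data.frame(subject = id, class = cls,
                     mean_duration_ms = tab$mean_duration_ms,
                     occurrence_hz = tab$occurrence_hz,
                     coverage = tab$coverage),
          data.frame(subject = id, class = "overall",
                     mean_duration_ms = f@overallDurationMs[["unweighted"]],
                     occurrence_hz = NA_real_, coverage = 1))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
}

#' Echo a generator or pipeline configuration to JSON
#'
#' @param config a list-like configuration.
#' @param path output file path.
#' @export
writeConfigJSON <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
}
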