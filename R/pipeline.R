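# End-to-end orchestration: recordings -> preprocessing -> individual
# clustering -> grand-mean clustering -> (optional) sorting to reference ->
# backfitting -> features -> (optional) paired pre/post statistics.

#' Run the full microstate pipeline on a cohort
#'
#' For every recording: optional filtering, average referencing, GFP-peak
#' extraction and individual modified k-means clustering. The individual
#' template sets are then clustered into grand-mean maps, optionally sorted
#' to a reference template set, and backfitted to every recording to yield
#' label sequences and temporal features. When each subject has a
#' \code{pre} and a \code{post} recording, paired t-tests on per-class mean
#' duration and occurrence are computed across subjects.
#'
#' @param recordings named list (one entry per subject); each entry is
#'   either an [EEGRecording-class] or a list with elements \code{pre} and
#'   \code{post}.
#' @param K number of microstate classes (default 7).
#' @param reference optional [TemplateSet-class] to sort the grand-mean maps
#'   to; when NULL the grand-mean maps keep their own (alphabetical) order.
#' @param filter a [filterSpec()], or NULL to skip filtering.
#' @param minDistanceMs GFP-peak separation (default 10 ms).
#' @param nRestarts,maxIter,tol clustering parameters (see
#'   [modifiedKMeans()]).
#' @param seed base RNG seed; per-recording clustering seeds derive from it.
#' @param behavior optional data.frame of paired behavioral scores with
#'   columns subject, measure, pre, post; paired tests are added for each
#'   measure.
#' @param outDir optional directory: when given, templates, labels, features
#'   and stats are written there as delimited text/CSV/JSON.
#' @return List: \code{individual} (per-subject [ClusterResult-class]s),
#'   \code{grandMean} ([ClusterResult-class]), \code{sorted}
#'   ([TemplateSet-class]), \code{backfits} (per subject/timepoint),
#'   \code{features} (long data.frame), \code{stats} (data.frame of paired
#'   tests, or NULL), \code{config}.
#' @export
runPipeline <- function(recordings, K = 7L, reference = NULL, filter = NULL,
                        minDistanceMs = 10, nRestarts = 20L, maxIter = 100L,
                        tol = 1e-6, seed = 1L, behavior = NULL,
                        outDir = NULL) {
  stopifnot(length(recordings) >= 1L)
  if (is.null(names(recordings)))
    names(recordings) <- sprintf("subject%02d", seq_along(recordings))
  paired <- all(vapply(recordings, function(r)
    is.list(r) && all(c("pre", "post") %in% names(r)), logical(1)))
  flat <- list()
  for (id in names(recordings)) {
    r <- recordings[[id]]
    if (is(r, "EEGRecording")) {
      flat[[id]] <- r
    } else {
      for (tp in names(r)) flat[[paste(id, tp, sep = ".")]] <- r[[tp]]
    }
  }
  prep <- function(rec) {
    if (!is.null(filter)) rec <- applyFilters(rec, filter)
    if (!rec@averageReferenced) rec <- averageReference(rec)
    rec
  }
  flat <- lapply(flat, prep)

  individual <- vector("list", length(flat))
  names(individual) <- names(flat)
  for (i in seq_along(flat)) {
    individual[[i]] <- clusterIndividual(flat[[i]], K,
                                         minDistanceMs = minDistanceMs,
                                         nRestarts = nRestarts,
                                         maxIter = maxIter, tol = tol,
                                         seed = seed + i)
  }
  grand <- clusterGrandMean(lapply(individual, function(x) x@templates), K,
                            nRestarts = nRestarts, maxIter = maxIter,
                            tol = tol, seed = seed + length(flat) + 1L)
  sorted <- if (!is.null(reference))
    sortToTemplates(grand@templates, reference)$sorted else grand@templates

  backfits <- lapply(flat, backfitRecording, templates = sorted,
                     minDistanceMs = minDistanceMs)

  featLong <- do.call(rbind, lapply(names(backfits), function(id) {
    f <- backfits[[id]]$features
    parts <- strsplit(id, ".", fixed = TRUE)[[1]]
    data.frame(subject = parts[1],
               timepoint = if (length(parts) > 1) parts[2] else "single",
               class = classNames(sorted)[f@table$class],
               mean_duration_ms = f@table$mean_duration_ms,
               occurrence_hz = f@table$occurrence_hz,
               coverage = f@table$coverage,
               overall_mean_duration_ms = f@overallDurationMs[["unweighted"]])
  }))

  statsTab <- NULL
  if (paired) statsTab <- .pairedFeatureStats(featLong, classNames(sorted))
  if (paired && !is.null(behavior)) {
    bt <- do.call(rbind, lapply(split(behavior, behavior$measure), function(b) {
      res <- pairedTTest(b$pre, b$post)
      data.frame(measure = b$measure[1], feature = "behavior",
                 n = res$n, mean_diff = res$mean_diff, t = res$t,
                 df = res$df, p = res$p_two_sided, cohens_d = res$cohens_d,
                 ci95_low = res$ci95_low, ci95_high = res$ci95_high)
    }))
    statsTab <- rbind(statsTab, bt)
  } else if (!paired && !is.null(behavior)) {
    message("behavior supplied but recordings are not paired; stats stage skipped")
  }

  cfg <- list(K = K, minDistanceMs = minDistanceMs, nRestarts = nRestarts,
              maxIter = maxIter, tol = tol, seed = seed,
              filter = if (is.null(filter)) NULL else unclass(filter),
              sortedToReference = !is.null(reference))
  out <- list(individual = individual, grandMean = grand, sorted = sorted,
              backfits = backfits, features = featLong, stats = statsTab,
              config = cfg)
  if (!is.null(outDir)) .writePipelineOutputs(out, outDir)
  out
}

# paired t-tests on per-class duration and occurrence across subjects
.pairedFeatureStats <- function(featLong, classNames_) {
  rows <- list()
  for (cls in classNames_) {
    for (feat in c("mean_duration_ms", "occurrence_hz")) {
      sub <- featLong[featLong$class == cls, ]
      wide <- merge(sub[sub$timepoint == "pre", c("subject", feat)],
                    sub[sub$timepoint == "post", c("subject", feat)],
                    by = "subject", suffixes = c("_pre", "_post"))
      pre <- wide[[paste0(feat, "_pre")]]
      post <- wide[[paste0(feat, "_post")]]
      ok <- stats::complete.cases(pre, post)
      if (sum(ok) >= 2) {
        res <- pairedTTest(pre[ok], post[ok])
        rows[[paste(cls, feat)]] <-
          data.frame(measure = cls, feature = feat, n = res$n,
                     mean_diff = res$mean_diff, t = res$t, df = res$df,
                     p = res$p_two_sided, cohens_d = res$cohens_d,
                     ci95_low = res$ci95_low, ci95_high = res$ci95_high)
      }
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

.writePipelineOutputs <- function(out, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  writeTemplatesTSV(out$grandMean@templates, file.path(outDir, "grand_mean.tsv"))
  writeTemplatesTSV(out$sorted, file.path(outDir, "sorted_templates.tsv"))
  for (id in names(out$backfits))
    writeLabelsCSV(out$backfits[[id]]$labels,
                   file.path(outDir, sprintf("labels_%s.csv", id)))
  utils::write.csv(out$features, file.path(outDir, "features.csv"),
                   row.names = FALSE)
  if (!is.null(out$stats))
    utils::write.csv(out$stats, file.path(outDir, "stats.csv"),
                     row.names = FALSE)
  writeConfigJSON(out$config, file.path(outDir, "config.json"))
  invisible(NULL)
}
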