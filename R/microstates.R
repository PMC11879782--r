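# GFP, GFP-peak extraction, polarity-invariant modified k-means, GEV,
# two-level clustering and shared-variance sorting to reference templates.

#' Global field power
#'
#' Per-sample standard deviation of voltage across channels of an
#' average-referenced map: \code{sqrt(mean(v^2))} for a zero-mean map.
#'
#' @param rec an average-referenced [EEGRecording-class], or a channels x
#'   samples matrix already average-referenced.
#' @param autoReference re-reference first instead of erroring when the
#'   recording is not average-referenced.
#' @return Numeric vector of per-sample GFP values (>= 0).
#' @export
gfp <- function(rec, autoReference = FALSE) {
  if (is(rec, "EEGRecording")) {
    if (!rec@averageReferenced) {
      if (!autoReference)
        stop("recording must be average-referenced (or set autoReference = TRUE)")
      rec <- averageReference(rec)
    }
    dat <- rec@data
  } else {
    dat <- as.matrix(rec)
  }
  sqrt(colMeans(dat^2))
}

#' Find GFP peaks
#'
#' Strict local maxima of the GFP series. When two maxima fall closer than
#' \code{minDistanceMs}, the one with larger GFP is kept (ties resolved in
#' favour of the earlier index). A monotone series yields an empty peak set.
#'
#' @param gfpValues numeric GFP series (length >= 3 for any peak to exist).
#' @param samplingRate sampling rate in Hz.
#' @param minDistanceMs minimum peak separation in ms (default 10).
#' @return Integer vector of 1-based peak sample indices, strictly increasing.
#' @export
findGFPPeaks <- function(gfpValues, samplingRate, minDistanceMs = 10) {
  n <- length(gfpValues)
  if (n < 3L) return(integer(0))
  g <- as.numeric(gfpValues)
  idx <- which(g[2:(n - 1)] > g[1:(n - 2)] & g[2:(n - 1)] > g[3:n]) + 1L
  if (length(idx) == 0L) return(integer(0))
  minDist <- minDistanceMs / 1000 * samplingRate
  if (minDist <= 1) return(idx)
  # greedy: keep larger-GFP peaks first (earlier index wins ties), then drop
  # any peak within minDist of an already kept one
  ord <- idx[order(-g[idx], idx)]
  keep <- logical(length(g))
  kept <- integer(0)
  for (p in ord) {
    if (!length(kept) || all(abs(kept - p) >= minDist)) {
      kept <- c(kept, p)
      keep[p] <- TRUE
    }
  }
  sort(kept)
}

#' Spatial correlation between two topographic maps
#'
#' Pearson correlation across channels of two average-referenced maps; the
#' absolute value is taken under polarity invariance (the standard
#' resting-state convention, where a map and its sign-flip are the same
#' topography).
#'
#' @param u,v numeric channel vectors of equal length >= 2.
#' @param polarityInvariant take \code{abs()} of the correlation (default TRUE).
#' @return A single correlation value.
#' @export
spatialCorrelation <- function(u, v, polarityInvariant = TRUE) {
  if (length(u) != length(v) || length(u) < 2L)
    stop("maps must have equal channel counts >= 2")
  u <- u - mean(u); v <- v - mean(v)
  su <- sqrt(sum(u^2)); sv <- sqrt(sum(v^2))
  if (su == 0 || sv == 0) stop("correlation undefined for a zero-variance map")
  r <- sum(u * v) / (su * sv)
  if (polarityInvariant) abs(r) else r
}

# polarity-invariant correlation matrix between rows of X (N x C, zero-mean
# rows) and rows of templates T (K x C, zero-mean unit-norm rows)
.absCorrMatrix <- function(X, Tm) {
  Xc <- X - rowMeans(X)
  nrm <- sqrt(rowSums(Xc^2))
  nrm[nrm == 0] <- Inf
  abs((Xc / nrm) %*% t(Tm))
}

#' Global explained variance
#'
#' \code{GEV = sum((gfp_n * r_n)^2) / sum(gfp_n^2)}, where \code{r_n} is the
#' polarity-invariant spatial correlation between map n and its assigned
#' template.
#'
#' @param maps N x channels matrix of topographic maps.
#' @param gfpValues per-map GFP (defaults to the maps' own GFP).
#' @param templates a [TemplateSet-class] or K x channels matrix.
#' @param labels assigned class per map (1..K).
#' @return GEV fraction in [0, 1].
#' @export
gev <- function(maps, templates, labels, gfpValues = NULL) {
  maps <- as.matrix(maps)
  Tm <- if (is(templates, "TemplateSet")) templates@maps else as.matrix(templates)
  if (is.null(gfpValues)) gfpValues <- sqrt(rowMeans((maps - rowMeans(maps))^2))
  if (all(gfpValues == 0)) stop("GEV undefined when all GFP values are zero")
  r <- vapply(seq_len(nrow(maps)), function(i)
    spatialCorrelation(maps[i, ], Tm[labels[i], ]), numeric(1))
  sum((gfpValues * r)^2) / sum(gfpValues^2)
}

# one modified k-means pass from a given template initialisation;
# maps: N x C zero-mean rows; returns labels, templates, gev, iterations
.kmeansOnce <- function(maps, gfpv, Tm, maxIter, tol) {
  N <- nrow(maps)
  K <- nrow(Tm)
  gfpSq <- sum(gfpv^2)
  lastGEV <- -Inf
  iter <- 0L
  labels <- integer(N)
  repeat {
    iter <- iter + 1L
    R <- .absCorrMatrix(maps, Tm)
    labels <- max.col(R, ties.method = "first")
    # re-seed any empty cluster from the worst-explained map
    rbest <- R[cbind(seq_len(N), labels)]
    for (k in seq_len(K)) {
      if (!any(labels == k)) {
        worst <- which.min(rbest)
        labels[worst] <- k
        m <- maps[worst, ] - mean(maps[worst, ])
        Tm[k, ] <- m / sqrt(sum(m^2))
        rbest[worst] <- 1
      }
    }
    # template update: dominant eigenvector of the sum of outer products of
    # the assigned maps (first right singular vector)
    for (k in seq_len(K)) {
      Xk <- maps[labels == k, , drop = FALSE]
      if (nrow(Xk) == 1L) {
        v <- Xk[1, ] - mean(Xk[1, ])
      } else {
        v <- svd(Xk, nu = 0, nv = 1)$v[, 1]
      }
      Tm[k, ] <- v / sqrt(sum(v^2))
    }
    R <- .absCorrMatrix(maps, Tm)
    labels <- max.col(R, ties.method = "first")
    curGEV <- sum((gfpv * R[cbind(seq_len(N), labels)])^2) / gfpSq
    if (iter >= maxIter ||
        abs(curGEV - lastGEV) < tol * max(abs(curGEV), .Machine$double.eps)) {
      return(list(labels = labels, templates = Tm, gev = curGEV,
                  iterations = iter))
    }
    lastGEV <- curGEV
  }
}

#' Polarity-invariant modified k-means clustering of topographic maps
#'
#' Per restart: K distinct input maps seed the templates; iteration
#' alternates (i) assigning every map to the template with the largest
#' squared spatial correlation and (ii) replacing each template by the
#' dominant eigenvector of the outer-product sum of its assigned maps,
#' unit-normalised, until the relative GEV change falls below \code{tol} or
#' \code{maxIter} is reached. The restart with the highest GEV wins. An
#' empty cluster is re-seeded from the currently worst-explained map.
#'
#' @param maps N x channels matrix of average-referenced maps (N >= K).
#' @param K number of classes.
#' @param nRestarts random restarts (default 20).
#' @param maxIter iteration cap per restart (default 100).
#' @param tol relative GEV convergence tolerance (default 1e-6).
#' @param seed RNG seed; fixed seed gives an identical result.
#' @param gfpValues optional per-map GFP weights (default: each map's GFP).
#' @return A [ClusterResult-class].
#' @export
modifiedKMeans <- function(maps, K, nRestarts = 20L, maxIter = 100L,
                           tol = 1e-6, seed = 1L, gfpValues = NULL) {
  maps <- as.matrix(maps)
  N <- nrow(maps)
  if (N < K) stop("need at least K maps to extract K classes")
  maps <- maps - rowMeans(maps)
  if (is.null(gfpValues)) gfpValues <- sqrt(rowMeans(maps^2))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  best <- NULL
  for (r in seq_len(nRestarts)) {
    init <- maps[sample.int(N, K), , drop = FALSE]
    nrm <- sqrt(rowSums(init^2))
    nrm[nrm == 0] <- 1
    fit <- .kmeansOnce(maps, gfpValues, init / nrm, maxIter, tol)
    if (is.null(best) || fit$gev > best$gev) {
      best <- fit
      best$restart <- r
    }
  }
  tmpl <- TemplateSet(best$templates,
                      classNames = make.unique(rep(LETTERS, length.out = K)),
                      provenance = "individual", gev = best$gev)
  if (!is.null(colnames(maps))) colnames(tmpl@maps) <- colnames(maps)
  new("ClusterResult", templates = tmpl,
      peakLabels = as.integer(best$labels), gev = best$gev,
      nIterations = as.integer(best$iterations),
      restartIndex = as.integer(best$restart))
}

#' Individual-level microstate clustering
#'
#' Composition of [gfp()], [findGFPPeaks()] and [modifiedKMeans()] on the
#' GFP-peak maps of one recording.
#'
#' @param rec average-referenced (and typically filtered) [EEGRecording-class].
#' @param K number of microstate classes.
#' @param minDistanceMs minimum GFP-peak separation (default 10 ms).
#' @param ... clustering parameters passed to [modifiedKMeans()].
#' @return A [ClusterResult-class]; the peak indices used are attached as
#'   attribute \code{"peaks"}.
#' @export
clusterIndividual <- function(rec, K, minDistanceMs = 10, ...) {
  g <- gfp(rec)
  peaks <- findGFPPeaks(g, rec@samplingRate, minDistanceMs)
  if (length(peaks) < K)
    stop(sprintf("insufficient data: %d GFP peaks for K = %d", length(peaks), K))
  res <- modifiedKMeans(t(rec@data[, peaks, drop = FALSE]), K, ...)
  attr(res, "peaks") <- peaks
  res
}

#' Grand-mean (group-level) microstate clustering
#'
#' Applies [modifiedKMeans()] to the concatenated individual template maps,
#' each map entering with equal weight (GFP weight 1).
#'
#' @param individualSets list of [TemplateSet-class] objects with equal
#'   channel counts.
#' @param K number of group classes.
#' @param ... clustering parameters passed to [modifiedKMeans()].
#' @return A [ClusterResult-class] whose templates have provenance
#'   \code{"grand_mean"}.
#' @export
clusterGrandMean <- function(individualSets, K, ...) {
  stopifnot(length(individualSets) >= 1L)
  ncs <- vapply(individualSets, function(s) ncol(s@maps), integer(1))
  if (length(unique(ncs)) != 1L)
    stop("all individual template sets must share the channel count")
  allMaps <- do.call(rbind, lapply(individualSets, function(s) s@maps))
  res <- modifiedKMeans(allMaps, K, gfpValues = rep(1, nrow(allMaps)), ...)
  res@templates@provenance <- "grand_mean"
  res
}

# Hungarian algorithm (O(n^3), potentials + augmenting paths) minimising the
# total cost of a square assignment; returns col index assigned to each row.
.hungarian <- function(cost) {
  n <- nrow(cost)
  u <- numeric(n)               # row potentials
  v <- numeric(n + 1L)          # column potentials (index 1 = dummy column)
  p <- integer(n + 1L)          # p[jj]: row matched to column jj-1 (0 = none)
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 1L
    minv <- rep(Inf, n + 1L)
    used <- logical(n + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- Inf; j1 <- 0L
      for (jj in 2L:(n + 1L)) {
        if (!used[jj]) {
          cur <- cost[i0, jj - 1L] - u[i0] - v[jj]
          if (cur < minv[jj]) { minv[jj] <- cur; way[jj] <- j0 }
          if (minv[jj] < delta) { delta <- minv[jj]; j1 <- jj }
        }
      }
      for (jj in 1L:(n + 1L)) {
        if (used[jj]) { u[p[jj]] <- u[p[jj]] + delta; v[jj] <- v[jj] - delta }
        else minv[jj] <- minv[jj] - delta
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  ans <- integer(n)
  for (jj in 2L:(n + 1L)) if (p[jj] > 0L) ans[p[jj]] <- jj - 1L
  ans
}

#' Sort candidate maps to reference templates by shared variance
#'
#' Finds the one-to-one assignment of candidate maps to reference classes
#' that maximises the total shared variance (squared spatial correlation),
#' reorders the candidates to reference order and sign-flips each so its
#' signed correlation with the matched reference is non-negative. Ties in
#' squared correlation resolve to the lowest class index.
#'
#' @param candidate [TemplateSet-class] to be sorted (K <= reference K).
#' @param reference [TemplateSet-class] of reference/normative maps.
#' @return List: \code{sorted} (the reordered, sign-aligned
#'   [TemplateSet-class] carrying the reference class names),
#'   \code{assignment} (reference class index for each candidate map) and
#'   \code{sharedVariance} (squared correlation per sorted map).
#' @export
sortToTemplates <- function(candidate, reference) {
  stopifnot(is(candidate, "TemplateSet"), is(reference, "TemplateSet"))
  if (ncol(candidate@maps) != ncol(reference@maps))
    stop("candidate and reference must share the channel count")
  Kc <- nrow(candidate@maps); Kr <- nrow(reference@maps)
  if (Kc > Kr) stop("candidate cannot have more classes than the reference")
  R2 <- .absCorrMatrix(candidate@maps, reference@maps)^2
  # pad to square with zero gain for unused reference classes
  cost <- matrix(0, Kr, Kr)
  cost[seq_len(Kc), ] <- -R2
  assign_ <- .hungarian(cost)[seq_len(Kc)]
  ord <- order(assign_)
  maps <- candidate@maps[ord, , drop = FALSE]
  refIdx <- assign_[ord]
  for (i in seq_along(refIdx)) {
    s <- sum((maps[i, ] - mean(maps[i, ])) * reference@maps[refIdx[i], ])
    if (s < 0) maps[i, ] <- -maps[i, ]
  }
  sorted <- TemplateSet(maps, classNames = reference@classNames[refIdx],
                        provenance = candidate@provenance, gev = candidate@gev)
  if (!is.null(colnames(reference@maps))) colnames(sorted@maps) <- colnames(reference@maps)
  sv <- R2[cbind(ord, refIdx)]
  list(sorted = sorted, assignment = assign_, sharedVariance = sv)
}
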