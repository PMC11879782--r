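# Paired-design statistics: paired t-tests with paired Cohen's d, 95% CIs,
# CI inversion, Bonferroni-adjusted significance levels, large-effect
# selection and Pearson correlations.

.pairedResult <- function(n, meanDiff, sdDiff, confLevel = 0.95,
                          degenerate = FALSE) {
  df <- n - 1L
  se <- sdDiff / sqrt(n)
  if (sdDiff == 0) {
    tval <- if (meanDiff == 0) 0 else sign(meanDiff) * Inf
    p <- if (meanDiff == 0) 1 else 0
    d <- tval / sqrt(n)
    ci <- c(meanDiff, meanDiff)
    degenerate <- TRUE
  } else {
    tval <- meanDiff / se
    p <- 2 * stats::pt(-abs(tval), df)
    d <- meanDiff / sdDiff
    tcrit <- stats::qt(1 - (1 - confLevel) / 2, df)
    ci <- meanDiff + c(-1, 1) * tcrit * se
  }
  structure(list(n = n, mean_diff = meanDiff, sd_diff = sdDiff, se = se,
                 t = tval, df = df, p_two_sided = p, cohens_d = d,
                 ci95_low = ci[1], ci95_high = ci[2],
                 conf_level = confLevel, degenerate = degenerate),
            class = "pairedTestResult")
}

#' @export
print.pairedTestResult <- function(x, ...) {
  cat(sprintf(paste0("Paired t-test: n = %d, mean diff = %.4g (SD %.4g)\n",
                     "  t(%d) = %.4g, p = %.4g, Cohen's d = %.4g, ",
                     "%d%% CI [%.4g, %.4g]\n"),
              x$n, x$mean_diff, x$sd_diff, x$df, x$t, x$p_two_sided,
              x$cohens_d, round(100 * x$conf_level), x$ci95_low, x$ci95_high))
  invisible(x)
}

#' Paired t-test with paired Cohen's d
#'
#' Differences are \code{post - pre}. The t statistic is
#' \code{mean(d) / (sd(d)/sqrt(n))} with the sample SD (n - 1 denominator),
#' the two-sided p-value comes from the Student-t distribution with n - 1
#' degrees of freedom, the paired effect size is Cohen's
#' \code{d = mean(d)/sd(d)} (so \code{|d| = |t|/sqrt(n)}), and the CI is
#' \code{mean(d) +/- t_crit * se}. All-identical non-zero differences give an
#' infinite t, p -> 0 and a degenerate flag.
#'
#' @param pre,post equal-length paired measurement vectors (n >= 2, matched
#'   subject order, no missing pairs).
#' @param confLevel confidence level of the interval (default 0.95).
#' @return A \code{pairedTestResult} list: n, mean_diff, sd_diff, se, t, df,
#'   p_two_sided, cohens_d, ci95_low, ci95_high, degenerate.
#' @examples
#' pairedTTest(pre = rep(0, 8), post = 1:8)
#' @export
pairedTTest <- function(pre, post, confLevel = 0.95) {
  if (length(pre) != length(post)) stop("pre and post must be paired")
  if (anyNA(pre) || anyNA(post)) stop("missing pairs are not allowed")
  n <- length(pre)
  if (n < 2L) stop("a paired test needs n >= 2")
  d <- post - pre
  .pairedResult(n, mean(d), stats::sd(d), confLevel)
}

#' Recover paired-test statistics from a printed confidence interval
#'
#' Given a reported 95% CI of the mean paired difference and the sample
#' size, recovers \code{se = (hi - lo) / (2 t_crit)}, the mean difference as
#' the CI midpoint, and from them t, the two-sided p and paired Cohen's d
#' (consistent with the [pairedTTest()] identities). This reproduces effect
#' sizes from published summary tables without access to raw data.
#'
#' @param ciLow,ciHigh CI bounds in difference units (ciHigh > ciLow).
#' @param n number of pairs (>= 2).
#' @param confLevel confidence level the interval was printed at.
#' @return A \code{pairedTestResult} (as [pairedTTest()]).
#' @examples
#' invertCI(3.87, 16.75, n = 8)$cohens_d
#' @export
invertCI <- function(ciLow, ciHigh, n, confLevel = 0.95) {
  if (!(ciHigh > ciLow)) stop("degenerate interval: ciHigh must exceed ciLow")
  if (n < 2L) stop("n must be >= 2")
  df <- n - 1L
  tcrit <- stats::qt(1 - (1 - confLevel) / 2, df)
  se <- (ciHigh - ciLow) / (2 * tcrit)
  meanDiff <- (ciHigh + ciLow) / 2
  .pairedResult(n, meanDiff, se * sqrt(n), confLevel)
}

#' Bonferroni-adjusted significance level
#'
#' The familywise level divided by the number of comparisons, reported both
#' at full precision and rounded to 3 decimals (the convention used when
#' quoting adjusted levels such as 0.017 for 3 tests or 0.007 for 7).
#'
#' @param alpha familywise significance level in (0, 1).
#' @param m number of comparisons (>= 1).
#' @return List: \code{adjusted} (alpha/m) and \code{printed} (3-decimal
#'   rounding).
#' @examples
#' bonferroniAlpha(0.05, 3)$printed  # 0.017
#' @export
bonferroniAlpha <- function(alpha, m) {
  if (m < 1L) stop("m must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  adj <- alpha / m
  list(adjusted = adj, printed = round(adj, 3))
}

#' Select measures with a large effect size
#'
#' Returns, in stable input order, the names whose paired effect size
#' satisfies \code{|d| >= threshold} (0.8 being the conventional
#' "large-effect" cut).
#'
#' @param results named list of \code{pairedTestResult}s, or a named numeric
#'   vector of d values.
#' @param threshold effect-size threshold (> 0; default 0.8).
#' @return Character vector of selected names.
#' @export
selectLargeEffects <- function(results, threshold = 0.8) {
  if (threshold < 0) stop("threshold must be non-negative")
  d <- if (is.numeric(results)) results
       else vapply(results, function(r) r$cohens_d, numeric(1))
  names(d)[abs(d) >= threshold]
}

#' Pearson correlation with a two-sided t-based p-value
#'
#' Standard product-moment correlation; the p-value uses
#' \code{t = r * sqrt((n - 2) / (1 - r^2))} with n - 2 degrees of freedom.
#'
#' @param x,y equal-length numeric vectors (n >= 3, non-zero variance).
#' @return List of class \code{"correlationResult"}: r, n, t, df,
#'   p_two_sided.
#' @export
pearsonCorrelation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stop("correlation test needs n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for zero-variance input")
  dx <- x - mean(x); dy <- y - mean(y)
  r <- sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
  df <- n - 2L
  if (abs(r) >= 1) {
    tval <- sign(r) * Inf
    p <- 0
  } else {
    tval <- r * sqrt(df / (1 - r^2))
    p <- 2 * stats::pt(-abs(tval), df)
  }
  structure(list(r = r, n = n, t = tval, df = df, p_two_sided = p),
            class = "correlationResult")
}

#' @export
print.correlationResult <- function(x, ...) {
  cat(sprintf("Pearson correlation: r = %.4g, n = %d, t(%d) = %.4g, p = %.4g\n",
              x$r, x$n, x$df, x$t, x$p_two_sided))
  invisible(x)
}
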