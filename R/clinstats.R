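## Supporting clinical statistics: descriptive summaries and paired
## before/after comparison of blood-gas parameters.

#' Descriptive summary of one clinical series
#'
#' Minimum, maximum, range, mean, sample standard deviation (n-1
#' denominator), adjusted Fisher-Pearson skewness and its standard
#' error `sqrt(6 n (n-1) / ((n-2)(n+1)(n+3)))` (0.34 at n = 51).
#'
#' @param values numeric vector, `n >= 2` (`n >= 3` for skewness).
#' @return Named list with `n`, `min`, `max`, `range`, `mean`, `sd`,
#'   `skewness`, `seSkewness`.
#' @export
#' @examples
#' describeSeries(c(7.01, 7.20, 7.23, 7.30, 7.35))
describeSeries <- function(values) {
  values <- as.numeric(values)
  if (anyNA(values) || any(!is.finite(values)))
    stop("values must be finite and non-missing")
  n <- length(values)
  if (n < 2L) stop("need at least 2 values")
  out <- list(n = n, min = min(values), max = max(values),
              range = max(values) - min(values), mean = mean(values),
              sd = stats::sd(values))
  if (n >= 3L) {
    out$skewness <- e1071::skewness(values, type = 2L)
    out$seSkewness <- sqrt(6 * n * (n - 1) / ((n - 2) * (n + 1) * (n + 3)))
  } else {
    out$skewness <- NA_real_
    out$seSkewness <- NA_real_
  }
  out
}

#' Before-minus-after mean difference
#'
#' Signed difference on the before-minus-after convention (so a
#' parameter that improves upward, like pH, has a negative difference).
#'
#' @param meanBefore,meanAfter finite numbers (vectorized).
#' @return `meanBefore - meanAfter`.
#' @export
#' @examples
#' meanDifference(7.23, 7.38)  # -0.15
meanDifference <- function(meanBefore, meanAfter) {
  if (any(!is.finite(meanBefore)) || any(!is.finite(meanAfter)))
    stop("inputs must be finite")
  meanBefore - meanAfter
}

#' Paired before/after comparison
#'
#' Two-tailed paired t-test on the before-minus-after differences
#' (via [stats::t.test()]), the Pearson correlation between the two
#' phases (via [stats::cor.test()]), and the `1 - alpha` confidence
#' interval of the mean difference from the t distribution with
#' `n - 1` degrees of freedom. If the differences have zero variance the
#' t statistic is undefined and reported as such (`degenerate = TRUE`).
#'
#' @param before,after equal-length numeric vectors, `n >= 2`.
#' @param alpha two-sided significance level (default 0.05).
#' @return Named list: `n`, `meanDiff`, `sdDiff`, `seDiff`, `ciLow`,
#'   `ciHigh`, `t`, `df`, `p`, `correlation`, `correlationP`,
#'   `degenerate`.
#' @export
#' @examples
#' pairedCompare(c(7.2, 7.3, 7.1), c(7.4, 7.45, 7.3))
pairedCompare <- function(before, after, alpha = 0.05) {
  before <- as.numeric(before); after <- as.numeric(after)
  if (length(before) != length(after))
    stop("before and after must have equal length")
  n <- length(before)
  if (n < 2L) stop("need at least 2 pairs")
  if (anyNA(before) || anyNA(after))
    stop("values must be non-missing")
  d <- before - after
  sdD <- stats::sd(d)
  seD <- sdD / sqrt(n)
  degenerate <- sdD == 0
  if (degenerate) {
    tval <- if (mean(d) == 0) 0 else NA_real_
    p <- if (mean(d) == 0) 1 else NA_real_
    ci <- c(mean(d), mean(d))
  } else {
    tt <- stats::t.test(before, after, paired = TRUE,
                        conf.level = 1 - alpha)
    tval <- unname(tt$statistic)
    p <- tt$p.value
    ci <- as.numeric(tt$conf.int)
  }
  corP <- NA_real_
  corr <- if (sdD == 0 && stats::sd(before) == 0) NA_real_ else
    suppressWarnings(stats::cor(before, after))
  if (is.finite(corr) && stats::sd(before) > 0 && stats::sd(after) > 0 &&
      n >= 3L) {
    corP <- suppressWarnings(
      stats::cor.test(before, after)$p.value)
  }
  list(n = n, meanDiff = mean(d), sdDiff = sdD, seDiff = seD,
       ciLow = ci[1L], ciHigh = ci[2L], t = tval, df = n - 1L, p = p,
       correlation = corr, correlationP = corP, degenerate = degenerate)
}

#' Paired comparison table for several parameters
#'
#' Convenience wrapper running [pairedCompare()] per parameter of a
#' long-format table and returning one row per parameter, shaped like a
#' paired-differences results table. In the formatted view p-values below
#' 0.005 print as "0.00" while full precision is kept in the returned
#' data.
#'
#' @param data data.frame with columns `parameter`, `phase`
#'   (`"before"`/`"after"`), `value`, and a subject identifier column
#'   `subject`.
#' @return data.frame, one row per parameter: `meanDiff`, `sdDiff`,
#'   `seDiff`, `ciLow`, `ciHigh`, `t`, `df`, `p`, `correlation`.
#' @export
pairedTable <- function(data) {
  need <- c("subject", "parameter", "phase", "value")
  if (!all(need %in% names(data)))
    stop("data must have columns ", paste(need, collapse = ", "))
  if (!all(data$phase %in% c("before", "after")))
    stop("phase must be \"before\" or \"after\"")
  params <- unique(data$parameter)
  rows <- lapply(params, function(p) {
    sub <- data[data$parameter == p, ]
    wide <- merge(sub[sub$phase == "before", c("subject", "value")],
                  sub[sub$phase == "after", c("subject", "value")],
                  by = "subject", suffixes = c("Before", "After"))
    r <- pairedCompare(wide$valueBefore, wide$valueAfter)
    data.frame(parameter = p, n = r$n, meanDiff = r$meanDiff,
               sdDiff = r$sdDiff, seDiff = r$seDiff, ciLow = r$ciLow,
               ciHigh = r$ciHigh, t = r$t, df = r$df, p = r$p,
               correlation = r$correlation)
  })
  do.call(rbind, rows)
}
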