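# Descriptive and comparative statistics in the layout used for the report
# tables: mean +- SD, median, IQR, CV, variance, skewness; nonparametric
# group comparisons; squared-correlation bands and Fisher's r-to-z.

#' Descriptive summary of a sample
#'
#' Sample SD (n - 1 denominator), type-7 (linear interpolation) quantiles
#' for the median and IQR, CV = sd/mean, and the adjusted Fisher-Pearson
#' sample skewness `g1 * sqrt(n(n-1))/(n-2)`. Skewness is NaN for constant
#' data or n < 3 rather than an error.
#'
#' @param x numeric vector, n >= 1
#' @return object of class `summary_stats`
#' @export
describe <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 1 || anyNA(x)) stop("describe: need n >= 1 complete values")
  m <- mean(x)
  s <- if (n > 1) stats::sd(x) else 0
  q <- stats::quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
  skew <- if (n >= 3 && s > 0) {
    g1 <- sum((x - m)^3) / n / (sum((x - m)^2) / n)^1.5
    g1 * sqrt(n * (n - 1)) / (n - 2)
  } else NaN
  structure(list(n = n, mean = m, sd = s, median = stats::median(x),
                 iqr = q[2] - q[1],
                 cv = if (m != 0) s / m else NaN,
                 skewness = skew, variance = s^2),
            class = "summary_stats")
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf(paste0("<summary_stats> n=%d  mean=%.4g sd=%.4g median=%.4g ",
                     "IQR=%.4g CV=%.4g var=%.4g skew=%.4g\n"),
              x$n, x$mean, x$sd, x$median, x$iqr, x$cv, x$variance,
              x$skewness))
  invisible(x)
}

#' Pooled layer mean from two sublaminar means
#'
#' The layer-level rows of the report are the unweighted arithmetic mean of
#' the two sublaminar means, rounded half-up to two decimals (the display
#' precision of the tables).
#'
#' @param l1a_mean,l1b_mean sublaminar means
#' @return pooled mean, 2 decimals
#' @export
pooled_layer_summary <- function(l1a_mean, l1b_mean) {
  stopifnot(is.finite(l1a_mean), is.finite(l1b_mean))
  round_half_up((l1a_mean + l1b_mean) / 2, 2)
}

#' Fold difference between two means
#'
#' Reported to one decimal, rounding toward zero (so 4.57 reports as
#' "~4.5-fold").
#'
#' @param a,b means to compare; `b` must be nonzero
#' @return a/b truncated to 1 decimal
#' @export
fold_difference <- function(a, b) {
  if (b == 0) stop("fold_difference: b must be nonzero")
  trunc(a / b * 10) / 10
}

#' Nonparametric two-group comparison
#'
#' Kruskal-Wallis H-test followed by a two-sided Mann-Whitney U-test, both
#' tie-corrected. The U-test is evaluated exactly (full null enumeration)
#' when both samples have n <= 20 and there are no ties, otherwise by the
#' normal approximation.
#'
#' @param a,b numeric samples, each n >= 2
#' @param alpha significance level for the `significant` flag (default 0.05)
#' @return object of class `comparison_result` with `kw_h, kw_p, mwu_u,
#'   mwu_p, significant`
#' @export
compare_groups <- function(a, b, alpha = 0.05) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  pooled <- c(a, b)
  if (length(unique(pooled)) == 1) {
    res <- list(kw_h = 0, kw_p = 1, mwu_u = length(a) * length(b) / 2,
                mwu_p = 1, significant = FALSE)
    return(structure(res, class = "comparison_result"))
  }
  kw <- stats::kruskal.test(list(a, b))
  exact <- length(a) <= 20 && length(b) <= 20 && !any(duplicated(pooled))
  mwu <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = !exact))
  structure(list(kw_h = unname(kw$statistic), kw_p = kw$p.value,
                 mwu_u = unname(mwu$statistic), mwu_p = mwu$p.value,
                 significant = mwu$p.value < alpha),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  stars <- if (x$mwu_p < 0.01) "**" else if (x$mwu_p < 0.05) "*" else ""
  cat(sprintf("<comparison> KW H=%.4g p=%.4g | MWU U=%.4g p=%.4g %s\n",
              x$kw_h, x$kw_p, x$mwu_u, x$mwu_p, stars))
  invisible(x)
}

#' Squared Pearson correlation with interpretation band
#'
#' R^2 bands: exactly 0 -> "none"; (0, 0.5) -> "weak"; [0.5, 0.8) -> "good";
#' [0.8, 1] -> "strong".
#'
#' @param x,y equal-length numeric vectors, n >= 3, both with nonzero
#'   variance
#' @return object of class `correlation_result` with `r`, `r2`, `band`, `n`
#' @export
correlate <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlate: zero variance in x or y")
  r <- stats::cor(x, y)
  r2 <- r^2
  band <- if (r2 == 0) "none" else if (r2 < 0.5) "weak" else
    if (r2 < 0.8) "good" else "strong"
  structure(list(r = r, r2 = r2, band = band, n = length(x)),
            class = "correlation_result")
}

#' Fisher's r-to-z test for two correlations
#'
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`, two-sided
#' normal p-value; used to compare correlation strengths between groups.
#'
#' @param r1,r2 Pearson correlations, |r| < 1
#' @param n1,n2 sample sizes, >= 4
#' @return list with `z` and `p`
#' @export
fisher_r_to_z <- function(r1, n1, r2, n2) {
  if (abs(r1) >= 1 || abs(r2) >= 1)
    stop("fisher_r_to_z: |r| must be < 1")
  stopifnot(n1 >= 4, n2 >= 4)
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Build a report table of descriptive statistics
#'
#' One row per parameter x group with the columns of the summary tables
#' (Mean, SD, Median, IQR, CV, Variance, Skewness, all rounded half-up to
#' two decimals) plus a non-normality flag for skewness > 3. When the
#' grouping contains both "L1a" and "L1b", a pooled "L1" row per parameter
#' is added via [pooled_layer_summary()] (mean column only; the remaining
#' statistics of pooled rows are computed on the pooled raw values).
#'
#' @param measurements data.frame with columns `parameter`, `group`, `value`
#' @return data.frame report table
#' @export
build_report <- function(measurements) {
  stopifnot(all(c("parameter", "group", "value") %in% names(measurements)),
            nrow(measurements) >= 1)
  row_of <- function(parameter, group, v, mean_override = NULL) {
    s <- describe(v)
    data.frame(parameter = parameter, group = group, n = s$n,
               mean = round_half_up(mean_override %||% s$mean, 2),
               sd = round_half_up(s$sd, 2),
               median = round_half_up(s$median, 2),
               iqr = round_half_up(s$iqr, 2),
               cv = round_half_up(s$cv, 2),
               variance = round_half_up(s$variance, 2),
               skewness = round_half_up(s$skewness, 2),
               nonnormal = is.finite(s$skewness) && s$skewness > 3,
               stringsAsFactors = FALSE)
  }
  out <- list()
  for (param in unique(measurements$parameter)) {
    sub <- measurements[measurements$parameter == param, ]
    groups <- split(sub$value, sub$group)
    for (g in names(groups))
      out[[length(out) + 1L]] <- row_of(param, g, groups[[g]])
    if (all(c("L1a", "L1b") %in% names(groups))) {
      pooled_mean <- pooled_layer_summary(mean(groups[["L1a"]]),
                                          mean(groups[["L1b"]]))
      out[[length(out) + 1L]] <- row_of(param, "L1",
                                        c(groups[["L1a"]], groups[["L1b"]]),
                                        mean_override = pooled_mean)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
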