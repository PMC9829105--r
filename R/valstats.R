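#' Paired measurement series
#'
#' Two equal-length sequences of the same quantity (mm) measured by two
#' methods, examiners or sessions; the unit of analysis of the paired
#' t-test and Bland-Altman comparisons.
#'
#' @param values_a,values_b numeric vectors of equal length >= 2, no
#'   missing entries.
#' @param label text label.
#' @return object of class `paired_series`.
#' @export
paired_series <- function(values_a, values_b, label = "series") {
  a <- as.numeric(values_a)
  b <- as.numeric(values_b)
  if (length(a) != length(b)) stop("paired series must have equal length")
  if (length(a) < 2L) stop("paired series needs length >= 2")
  if (anyNA(a) || anyNA(b)) stop("paired series must not contain NA")
  structure(list(values_a = a, values_b = b, label = label),
            class = "paired_series")
}

#' Two-sided paired t-test
#'
#' Standard paired t on the differences d = a - b with n - 1 degrees of
#' freedom. Zero-variance differences with nonzero mean are reported as
#' degenerate (`t_infinite = TRUE`, p = 0) rather than raising; all-zero
#' differences give t = 0, p = 1.
#'
#' @param series a [paired_series()].
#' @param conf_level confidence level for the mean-difference interval.
#' @return list: `n`, `mean`, `sd`, `se`, `ci_low`, `ci_high`, `t`, `p`,
#'   `df`, `t_infinite`.
#' @export
paired_t <- function(series, conf_level = 0.95) {
  d <- series$values_a - series$values_b
  n <- length(d)
  m <- mean(d)
  s <- stats::sd(d)
  df <- n - 1L
  tcrit <- stats::qt(1 - (1 - conf_level) / 2, df)
  if (s == 0) {
    degenerate <- m != 0
    return(list(n = n, mean = m, sd = 0, se = 0, ci_low = m, ci_high = m,
                t = if (degenerate) sign(m) * Inf else 0,
                p = if (degenerate) 0 else 1, df = df,
                t_infinite = degenerate))
  }
  se <- s / sqrt(n)
  tval <- m / se
  list(n = n, mean = m, sd = s, se = se,
       ci_low = m - tcrit * se, ci_high = m + tcrit * se,
       t = tval, p = 2 * stats::pt(-abs(tval), df), df = df,
       t_infinite = FALSE)
}

#' Shapiro-Wilk normality test
#'
#' @param values numeric vector, 3 <= n <= 5000, not constant.
#' @return list with `W` and `p`.
#' @export
shapiro_normality <- function(values) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 3L || n > 5000L)
    stop("Shapiro-Wilk requires 3 <= n <= 5000, got ", n)
  if (stats::sd(values) == 0) stop("Shapiro-Wilk undefined for constant input")
  sw <- stats::shapiro.test(values)
  list(W = unname(sw$statistic), p = sw$p.value)
}

#' Intraclass correlation coefficient, absolute agreement
#'
#' ICC(A,1): two-way random-effects, absolute-agreement, single-measurement
#' intraclass correlation, from the standard two-way ANOVA mean squares
#'
#' \deqn{ICC(A,1) = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E +
#'   \frac{k}{n}(MS_C - MS_E)}}
#'
#' with \eqn{MS_R} the between-subject, \eqn{MS_C} the between-rater and
#' \eqn{MS_E} the residual mean square. Absolute agreement (rather than
#' consistency) is the relevant form when asking whether two examiners'
#' measurements are interchangeable as absolute values. The estimate is
#' clipped to the reporting range \[-1, 1\].
#'
#' @param ratings numeric matrix, subjects in rows, raters in columns
#'   (n >= 2, k >= 2, complete).
#' @return list: `icc`, `ms_rows`, `ms_cols`, `ms_error`, `n`, `k`,
#'   `degenerate` (`TRUE` when between-subject variance is zero and the
#'   coefficient is undefined; `icc` is then `NA`).
#' @export
icc_agreement <- function(ratings) {
  x <- as.matrix(ratings)
  if (anyNA(x)) stop("ratings table must be complete")
  n <- nrow(x)
  k <- ncol(x)
  if (n < 2L || k < 2L) stop("need at least 2 subjects and 2 raters")
  grand <- mean(x)
  row_m <- rowMeans(x)
  col_m <- colMeans(x)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((x - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  ms_rows <- ss_rows / (n - 1)
  ms_cols <- ss_cols / (k - 1)
  ms_err <- ss_err / ((n - 1) * (k - 1))
  denom <- ms_rows + (k - 1) * ms_err + k / n * (ms_cols - ms_err)
  degenerate <- ss_rows <= .Machine$double.eps * ss_tot || denom <= 0
  icc <- if (degenerate) NA_real_
         else max(-1, min(1, (ms_rows - ms_err) / denom))
  list(icc = icc, ms_rows = ms_rows, ms_cols = ms_cols, ms_error = ms_err,
       n = n, k = k, degenerate = degenerate)
}

#' Bland-Altman agreement analysis
#'
#' Differences d = a - b, their mean, the 95 percent limits of agreement
#' mean(d) +/- 1.96 SD(d), the fraction of differences inside the limits,
#' and the (mean, difference) pairs for plotting.
#'
#' @param series a [paired_series()].
#' @return list of class `bland_altman`: `mean_diff`, `loa_low`,
#'   `loa_high`, `coverage`, `sd_diff`, `n`, `plot_data` (data frame with
#'   `mean` and `difference`).
#' @export
bland_altman <- function(series) {
  a <- series$values_a
  b <- series$values_b
  d <- a - b
  m <- mean(d)
  s <- stats::sd(d)
  loa <- c(m - 1.96 * s, m + 1.96 * s)
  structure(list(mean_diff = m, loa_low = loa[1], loa_high = loa[2],
                 coverage = mean(d >= loa[1] & d <= loa[2]),
                 sd_diff = s, n = length(d),
                 plot_data = data.frame(mean = (a + b) / 2, difference = d),
                 label = series$label),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(paste0("Bland-Altman (%s, n=%d): mean difference %.4f mm, ",
                     "95%% LoA [%.4f, %.4f] mm, coverage %.3f\n"),
              x$label, x$n, x$mean_diff, x$loa_low, x$loa_high, x$coverage))
  invisible(x)
}

#' Sample size for a paired design
#'
#' Smallest number of pairs n such that a two-sided one-sample t-test on
#' the differences, at level `alpha`, reaches the requested power when the
#' true mean difference is `delta` and the SD of differences is `sd`.
#' Power is evaluated exactly through the noncentral t distribution
#' (noncentrality `delta / (sd / sqrt(n))`) rather than the normal
#' approximation, since the n of interest is small.
#'
#' @param delta smallest mean difference to detect, mm (> 0).
#' @param sd SD of the paired differences, mm (> 0).
#' @param power requested power, in (0, 1).
#' @param alpha two-sided significance level, in (0, 1).
#' @return integer n.
#' @export
required_n_paired <- function(delta, sd, power = 0.95, alpha = 0.05) {
  stopifnot(delta > 0, sd > 0, power > 0, power < 1, alpha > 0, alpha < 1)
  for (n in 2:100000) {
    df <- n - 1
    tcrit <- stats::qt(1 - alpha / 2, df)
    ncp <- delta / (sd / sqrt(n))
    pw <- 1 - stats::pt(tcrit, df, ncp = ncp) +
          stats::pt(-tcrit, df, ncp = ncp)
    if (pw >= power) return(n)
  }
  stop("no n up to 100000 reaches the requested power")
}
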