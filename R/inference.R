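#' Paired one-tailed t test on per-reader differences
#'
#' Tests whether the per-reader metric changed between sessions, treating
#' readers as the sampling unit. Differences are `d = b - a`; the test
#' statistic is `t = mean(d) / (sd(d) / sqrt(n))` on `n - 1` degrees of
#' freedom, with the one-sided tail given by `direction` (`"greater"`: b
#' exceeds a). The confidence interval reported for the mean difference is
#' the usual two-sided 95% Student-t interval, matching how such studies
#' tabulate a mean increase with a symmetric CI next to a one-tailed p.
#'
#' @param a,b Numeric vectors of per-reader values, paired by position
#'   (e.g. sensitivity without and with augmentation).
#' @param direction `"greater"` (alternative: mean(b - a) > 0) or `"less"`.
#' @param confidence Coverage of the two-sided interval (default 0.95).
#' @return An object of class `"paired_test"`: `mean_diff`, `ci_lower`,
#'   `ci_upper`, `t_stat`, `df`, `p_one_tailed`, `direction`, `n`.
#' @export
paired_one_tailed_t <- function(a, b, direction = c("greater", "less"),
                                confidence = 0.95) {
  direction <- match.arg(direction)
  if (length(a) != length(b)) {
    stop("`a` and `b` must be paired (equal length)", call. = FALSE)
  }
  n <- length(a)
  if (n < 2) stop("at least 2 pairs are required", call. = FALSE)
  d <- b - a
  if (stats::sd(d) == 0) {
    stop("degenerate-variance error: all per-reader differences are equal (sd = 0)",
         call. = FALSE)
  }
  one <- stats::t.test(b, a, paired = TRUE, alternative = direction)
  two <- stats::t.test(b, a, paired = TRUE, alternative = "two.sided",
                       conf.level = confidence)
  structure(
    list(mean_diff = mean(d),
         ci_lower = two$conf.int[1],
         ci_upper = two$conf.int[2],
         t_stat = unname(one$statistic),
         df = unname(one$parameter),
         p_one_tailed = one$p.value,
         direction = direction,
         confidence = confidence,
         n = n),
    class = "paired_test"
  )
}

#' Per-case diagnosis durations from entry timestamps
#'
#' Readers enter one label per case; the logging records each entry's time.
#' The time to diagnose a case is the difference between consecutive entry
#' times in reading order, so n entries yield n - 1 durations (the first
#' case has no predecessor). Input order is irrelevant: entries are sorted
#' by time first. Tied or non-increasing timestamps are an error.
#'
#' @param entry_times_s Numeric vector of entry times (seconds since session
#'   start) for one reader-session, in any order.
#' @return Numeric vector of n - 1 positive durations.
#' @export
diagnosis_durations <- function(entry_times_s) {
  t <- as.numeric(entry_times_s)
  if (length(t) < 2) {
    stop("at least 2 entry times are needed to form a duration", call. = FALSE)
  }
  if (anyNA(t)) stop("entry times contain NA", call. = FALSE)
  t <- sort(t)
  d <- diff(t)
  if (any(d <= 0)) {
    stop("entry times must be strictly increasing (tied timestamps found)",
         call. = FALSE)
  }
  d
}

#' Symmetric trimming of a duration sequence
#'
#' Removes the `k` largest and `k` smallest values (default 5 and 5),
#' guarding the timing summaries against interruptions and logging errors.
#' Ties at the cut are broken by stable original order; the remaining values
#' keep their original sequence order.
#'
#' @param durations Numeric vector, length strictly greater than `2k`.
#' @param k Number trimmed from each end.
#' @return Numeric vector of length `length(durations) - 2k`.
#' @export
trim_durations <- function(durations, k = 5) {
  n <- length(durations)
  if (k < 0) stop("`k` must be >= 0", call. = FALSE)
  if (k == 0) return(durations)
  if (n <= 2 * k) {
    stop("cannot trim ", k, " from each end of ", n, " durations (need > ",
         2 * k, ")", call. = FALSE)
  }
  ord <- order(durations)  # stable for ties
  keep <- sort(ord[(k + 1):(n - k)])
  durations[keep]
}

#' Mean duration with a Student-t confidence interval
#'
#' @param durations Numeric vector (length >= 2), typically already trimmed.
#' @param confidence Coverage (default 0.95).
#' @return A list of class `"timing_summary"`: `n`, `mean_s`, `sd_s`,
#'   `ci_lower_s`, `ci_upper_s`, `confidence`. Constant durations give a
#'   zero-width interval.
#' @export
mean_time_ci <- function(durations, confidence = 0.95) {
  n <- length(durations)
  if (n < 2) stop("at least 2 durations are required", call. = FALSE)
  m <- mean(durations)
  s <- stats::sd(durations)
  half <- stats::qt((1 + confidence) / 2, df = n - 1) * s / sqrt(n)
  structure(
    list(n = n, mean_s = m, sd_s = s,
         ci_lower_s = m - half, ci_upper_s = m + half,
         confidence = confidence),
    class = "timing_summary"
  )
}

#' Benjamini-Hochberg step-up adjusted p values
#'
#' Standard FDR step-up adjustment over the registered hypothesis family:
#' sort ascending, `p_adj(i) = min_{j >= i} (m * p(j) / j)` capped at 1,
#' original order restored. Thin validated wrapper around
#' `stats::p.adjust(method = "BH")`.
#'
#' @param p Numeric vector of unadjusted p values in [0, 1].
#' @return Numeric vector of adjusted p values, same order and names.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) stop("empty p-value family", call. = FALSE)
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop("domain error: p values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' @export
print.paired_test <- function(x, ...) {
  cat(sprintf("paired t: mean diff %.4f (%d%% CI %.4f to %.4f), t(%d) = %.3f, one-tailed [%s] p = %s\n",
              x$mean_diff, round(100 * x$confidence), x$ci_lower, x$ci_upper,
              x$df, x$t_stat, x$direction, format_p(x$p_one_tailed)))
  invisible(x)
}

#' @export
print.timing_summary <- function(x, ...) {
  cat(sprintf("mean time %.2f s (%d%% t CI, %.2f-%.2f s; n = %d)\n",
              x$mean_s, round(100 * x$confidence), x$ci_lower_s,
              x$ci_upper_s, x$n))
  invisible(x)
}

# Journal-style p formatting: two decimals, three when p < .01, "<.001"
# floor, no leading zero. Display only; machine-readable outputs keep full
# precision.
format_p <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) return(NA_character_)
    if (pi < 0.001) return("<.001")
    digits <- if (pi < 0.01) 3 else 2
    sub("^0", "", sprintf(paste0("%.", digits, "f"), pi))
  }, character(1))
}
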