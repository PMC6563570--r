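#' Binarize a voxel-probability segmentation volume
#'
#' A case-level prediction from a segmentation model is positive when at
#' least one voxel's predicted probability strictly exceeds the threshold.
#' The inequality is strict: a voxel at exactly 0.5 does not trigger a
#' positive call at the default threshold.
#'
#' @param volume Numeric array (any shape) of voxel probabilities in [0, 1].
#' @param threshold Probability threshold (default 0.5).
#' @return Integer 0 or 1.
#' @export
binarize_prediction <- function(volume, threshold = 0.5) {
  if (!is.numeric(volume) || length(volume) == 0) {
    stop("`volume` must be a non-empty numeric array", call. = FALSE)
  }
  if (any(!is.finite(volume))) {
    stop("domain error: volume contains non-finite values", call. = FALSE)
  }
  if (any(volume < 0 | volume > 1)) {
    stop("domain error: voxel probabilities must lie in [0, 1]", call. = FALSE)
  }
  as.integer(any(volume > threshold))
}

#' Confusion counts for one reader (or one pooled set of reads)
#'
#' @param labels Either an integer 0/1 vector named by case id, or a data
#'   frame with columns `case_id` and `label`.
#' @param cases Case-record data frame with `case_id` and `truth`.
#' @return An object of class `"confusion_counts"`: a named integer vector
#'   `(tp, fp, tn, fn)`.
#' @export
confusion <- function(labels, cases) {
  if (nrow(cases) == 0) stop("empty case list", call. = FALSE)
  if (is.data.frame(labels)) {
    lab <- labels$label
    names(lab) <- labels$case_id
    labels <- lab
  }
  if (is.null(names(labels))) {
    stop("alignment error: labels must be named by case_id", call. = FALSE)
  }
  idx <- match(cases$case_id, names(labels))
  if (anyNA(idx)) {
    stop("alignment error: no label for case(s) ",
         paste(utils::head(cases$case_id[is.na(idx)], 5), collapse = ", "),
         call. = FALSE)
  }
  lab <- as.integer(labels[idx])
  if (!all(lab %in% c(0L, 1L))) {
    stop("value error: labels must be 0 or 1", call. = FALSE)
  }
  truth <- as.integer(cases$truth)
  counts <- c(
    tp = sum(lab == 1L & truth == 1L),
    fp = sum(lab == 1L & truth == 0L),
    tn = sum(lab == 0L & truth == 0L),
    fn = sum(lab == 0L & truth == 1L)
  )
  structure(as.integer(counts), names = names(counts),
            class = "confusion_counts")
}

as_confusion <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0)) stop("confusion counts must be >= 0", call. = FALSE)
  structure(as.integer(counts), names = names(counts),
            class = "confusion_counts")
}

#' Classification metrics from confusion counts
#'
#' `metric()` computes sensitivity = tp/(tp+fn), specificity = tn/(tn+fp) or
#' accuracy = (tp+tn)/n. A zero denominator raises an error rather than
#' returning `NaN`, so degenerate inputs cannot silently propagate into the
#' downstream t tests.
#'
#' @param counts A `"confusion_counts"` object.
#' @param which One of `"sensitivity"`, `"specificity"`, `"accuracy"`.
#' @return A single number in [0, 1].
#' @export
metric <- function(counts, which = c("sensitivity", "specificity", "accuracy")) {
  which <- match.arg(which)
  stopifnot(inherits(counts, "confusion_counts"))
  num_den <- switch(which,
    sensitivity = c(counts[["tp"]], counts[["tp"]] + counts[["fn"]]),
    specificity = c(counts[["tn"]], counts[["tn"]] + counts[["fp"]]),
    accuracy = c(counts[["tp"]] + counts[["tn"]], sum(counts))
  )
  if (num_den[2] == 0) {
    stop("undefined-metric error: ", which, " has a zero denominator",
         call. = FALSE)
  }
  num_den[1] / num_den[2]
}

# numerator/denominator pair used for Wilson intervals on pooled metrics
metric_fraction <- function(counts, which) {
  switch(which,
    sensitivity = c(successes = counts[["tp"]],
                    n = counts[["tp"]] + counts[["fn"]]),
    specificity = c(successes = counts[["tn"]],
                    n = counts[["tn"]] + counts[["fp"]]),
    accuracy = c(successes = counts[["tp"]] + counts[["tn"]],
                 n = sum(counts))
  )
}

#' Microaverage (pool) confusion counts across readers
#'
#' The microaverage of a metric across readers is the metric of the summed
#' confusion counts, i.e. every read is weighted equally; with a complete
#' design of R readers and N cases the pooled accuracy denominator is R*N.
#'
#' @param per_reader A list of `"confusion_counts"` objects.
#' @return A single pooled `"confusion_counts"` object.
#' @export
microaverage <- function(per_reader) {
  if (length(per_reader) == 0) {
    stop("microaverage of an empty collection", call. = FALSE)
  }
  stopifnot(all(vapply(per_reader, inherits, logical(1), "confusion_counts")))
  total <- Reduce(`+`, lapply(per_reader, unclass))
  structure(as.integer(total), names = c("tp", "fp", "tn", "fn"),
            class = "confusion_counts")
}

#' Wilson score confidence interval for a binomial proportion
#'
#' Inverts the normal score test: the interval for k successes out of n at
#' confidence 1 - alpha is centred at (p + z^2/2n) / (1 + z^2/n) with
#' half-width z * sqrt(p(1-p)/n + z^2/4n^2) / (1 + z^2/n), where
#' z is the standard-normal quantile at 1 - alpha/2 (the exact quantile,
#' 1.959964... at 95%, not 1.96). Bounds are clipped to [0, 1].
#'
#' @param successes Non-negative integer count.
#' @param n Positive integer number of trials, `successes <= n`.
#' @param confidence Coverage level (default 0.95).
#' @return An object of class `"proportion_ci"` with fields `estimate`,
#'   `lower`, `upper`, `n`, `confidence`, `method = "wilson"`.
#' @examples
#' wilson_ci(857, 920)   # 0.932 (0.913-0.946)
#' @export
wilson_ci <- function(successes, n, confidence = 0.95) {
  if (n < 1) stop("domain error: n must be >= 1", call. = FALSE)
  if (successes < 0 || successes > n) {
    stop("domain error: need 0 <= successes <= n", call. = FALSE)
  }
  if (confidence <= 0 || confidence >= 1) {
    stop("domain error: confidence must lie in (0, 1)", call. = FALSE)
  }
  z <- stats::qnorm((1 + confidence) / 2)
  p <- successes / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  structure(
    list(estimate = p,
         lower = max(0, centre - half),
         upper = min(1, centre + half),
         n = as.integer(n),
         confidence = confidence,
         method = "wilson"),
    class = "proportion_ci"
  )
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("confusion counts: TP=%d FP=%d TN=%d FN=%d (n=%d)\n",
              x[["tp"]], x[["fp"]], x[["tn"]], x[["fn"]], sum(x)))
  invisible(x)
}

#' @export
print.proportion_ci <- function(x, ...) {
  cat(sprintf("%.3f (%d%% Wilson CI, %.3f-%.3f; n = %d)\n",
              x$estimate, round(100 * x$confidence), x$lower, x$upper, x$n))
  invisible(x)
}
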