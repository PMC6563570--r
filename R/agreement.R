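#' Fleiss kappa for multiple raters, exact (Conger) or classic form
#'
#' Chance-corrected agreement among R raters each labelling N cases. The
#' observed agreement is the proportion of concordant rater pairs,
#' `P_o = sum_c sum_j n_cj (n_cj - 1) / (N R (R - 1))`, where `n_cj` counts
#' raters assigning category j to case c. The expected agreement depends on
#' the variant:
#'
#' * `exact = TRUE` (Conger's kappa, the default): rater-specific marginal
#'   rates `p_rj`, with `P_e = 2 / (R (R - 1)) * sum_{r<r'} sum_j p_rj p_r'j`
#'   — the average chance agreement over all rater pairs. For R = 2 this is
#'   exactly Cohen's kappa.
#' * `exact = FALSE` (classic Fleiss kappa): pooled marginals
#'   `P_e = sum_j p_j^2`.
#'
#' @param mat Cases-by-raters matrix of categorical labels (any atomic type;
#'   binary 0/1 in this package's studies).
#' @param exact Use rater-specific marginals (Conger) rather than pooled.
#' @return An object of class `"kappa_result"` with fields `kappa`, `P_o`,
#'   `P_e`, `n_cases`, `n_raters`, `method`.
#' @references Conger, A. J. (1980). Integration and generalization of kappas
#'   for multiple raters. Psychological Bulletin, 88, 322-328.
#' @export
fleiss_kappa <- function(mat, exact = TRUE) {
  if (!is.matrix(mat)) mat <- as.matrix(mat)
  N <- nrow(mat)
  R <- ncol(mat)
  if (R < 2) stop("at least 2 raters are required", call. = FALSE)
  if (N < 1) stop("at least 1 case is required", call. = FALSE)
  if (anyNA(mat)) stop("labels must be complete (no NA)", call. = FALSE)
  cats <- sort(unique(as.vector(mat)))
  # n_cj: per-case category counts; p_rj: per-rater marginal rates
  ncj <- vapply(cats, function(k) rowSums(mat == k), numeric(N))
  if (N == 1) ncj <- matrix(ncj, nrow = 1)
  P_o <- sum(ncj * (ncj - 1)) / (N * R * (R - 1))
  prj <- vapply(cats, function(k) colMeans(mat == k), numeric(R))
  if (R == 1) prj <- matrix(prj, nrow = 1)
  if (exact) {
    # sum over unordered rater pairs of sum_j p_rj p_r'j, via the identity
    # 2 * sum_{r<r'} x_r x_r' = (sum_r x_r)^2 - sum_r x_r^2
    P_e <- sum(colSums(prj)^2 - colSums(prj^2)) / (R * (R - 1))
  } else {
    pj <- colMeans(prj)
    P_e <- sum(pj^2)
  }
  if (P_e >= 1 - 1e-12) {
    stop("degenerate agreement: all raters used a single category for every ",
         "case, so expected agreement is 1 and kappa is undefined",
         call. = FALSE)
  }
  structure(
    list(kappa = (P_o - P_e) / (1 - P_e),
         P_o = P_o, P_e = P_e,
         n_cases = N, n_raters = R,
         method = if (exact) "exact (Conger)" else "classic (Fleiss)"),
    class = "kappa_result"
  )
}

#' Permutation test for a between-session difference in Fleiss kappa
#'
#' Tests whether interrater agreement is higher in session A than in session
#' B. The observed statistic is `kappa(a) - kappa(b)`. Under the null that
#' the session labels are exchangeable, each permutation independently swaps
#' — with probability 1/2 per case — that case's complete row of rater labels
#' between the two matrices, then recomputes the kappa difference. Swapping
#' whole case rows preserves the within-case inter-rater correlation; an
#' alternative cell-level swap (each reader-by-case label swapped
#' independently) is available via `unit = "cell"`.
#'
#' The one-sided p value is the proportion of permuted differences strictly
#' greater than the observed difference. With `smoothed = TRUE` the
#' (count + 1)/(B + 1) estimator is used instead, which cannot return 0.
#'
#' @param a,b Cases-by-raters label matrices with identical case and rater
#'   ordering (session A, e.g. augmented, and session B, e.g. unaugmented).
#' @param B Number of permutations (default 10000).
#' @param seed Optional integer seed for the permutation stream.
#' @param exact Passed on to [fleiss_kappa()].
#' @param unit `"case"` (default) or `"cell"` swap granularity.
#' @param smoothed Use the add-one p-value estimator.
#' @return An object of class `"permutation_result"` with fields
#'   `observed_diff`, `kappa_a`, `kappa_b`, `B`, `null_exceed_count`,
#'   `p_value`, `null_diffs`, `unit`, `seed`.
#' @export
kappa_permutation_test <- function(a, b, B = 10000, seed = NULL,
                                   exact = TRUE,
                                   unit = c("case", "cell"),
                                   smoothed = FALSE) {
  unit <- match.arg(unit)
  if (!is.matrix(a)) a <- as.matrix(a)
  if (!is.matrix(b)) b <- as.matrix(b)
  if (!all(dim(a) == dim(b))) {
    stop("session matrices must have identical dimensions", call. = FALSE)
  }
  if (B < 1) stop("B must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  ka <- fleiss_kappa(a, exact = exact)
  kb <- fleiss_kappa(b, exact = exact)
  observed <- ka$kappa - kb$kappa
  N <- nrow(a)
  null_diffs <- vapply(seq_len(B), function(i) {
    if (unit == "case") {
      swap <- stats::runif(N) < 0.5
      a2 <- a; b2 <- b
      a2[swap, ] <- b[swap, , drop = FALSE]
      b2[swap, ] <- a[swap, , drop = FALSE]
    } else {
      swap <- matrix(stats::runif(length(a)) < 0.5, nrow = N)
      a2 <- a; b2 <- b
      a2[swap] <- b[swap]
      b2[swap] <- a[swap]
    }
    fleiss_kappa(a2, exact = exact)$kappa - fleiss_kappa(b2, exact = exact)$kappa
  }, numeric(1))
  exceed <- sum(null_diffs > observed)
  p <- if (smoothed) (exceed + 1) / (B + 1) else exceed / B
  if (all(null_diffs == observed)) {
    warning("degenerate permutation null: every permuted difference equals ",
            "the observed difference; the strict-inequality p value is 0",
            call. = FALSE)
  }
  structure(
    list(observed_diff = observed,
         kappa_a = ka$kappa, kappa_b = kb$kappa,
         B = as.integer(B),
         null_exceed_count = as.integer(exceed),
         p_value = p,
         null_diffs = null_diffs,
         unit = unit,
         smoothed = smoothed,
         seed = seed),
    class = "permutation_result"
  )
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("Fleiss kappa [%s]: %.4f  (P_o = %.4f, P_e = %.4f; %d cases, %d raters)\n",
              x$method, x$kappa, x$P_o, x$P_e, x$n_cases, x$n_raters))
  invisible(x)
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("kappa difference: %.4f (A = %.4f, B = %.4f)\n",
              x$observed_diff, x$kappa_a, x$kappa_b))
  cat(sprintf("permutation test: %d/%d permuted diffs exceeded observed, p %s %s (%s-level swaps)\n",
              x$null_exceed_count, x$B,
              if (x$smoothed) "[add-one] =" else "=",
              format_p(x$p_value), x$unit))
  invisible(x)
}
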