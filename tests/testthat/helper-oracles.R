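# Independent oracles used to cross-check the package's statistics. These are
# deliberately written from first principles (textbook formulas, brute-force
# enumeration) and share no code with the implementation under test.

# Cohen's kappa for two raters, straight from the 2-category contingency table.
oracle_cohen_kappa <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  cats <- sort(unique(c(x, y)))
  po <- mean(x == y)
  pe <- sum(vapply(cats, function(k) mean(x == k) * mean(y == k), numeric(1)))
  (po - pe) / (1 - pe)
}

# Multi-rater exact kappa by brute force: average observed and expected
# agreement over every unordered rater pair, then chance-correct.
oracle_pairwise_kappa <- function(mat) {
  R <- ncol(mat)
  cats <- sort(unique(as.vector(mat)))
  po <- c(); pe <- c()
  for (r in seq_len(R - 1)) {
    for (s in (r + 1):R) {
      po <- c(po, mean(mat[, r] == mat[, s]))
      pe <- c(pe, sum(vapply(cats, function(k) {
        mean(mat[, r] == k) * mean(mat[, s] == k)
      }, numeric(1))))
    }
  }
  (mean(po) - mean(pe)) / (1 - mean(pe))
}

# Random binary rating matrix that is not agreement-degenerate (some
# disagreement somewhere, so expected agreement < 1).
random_rating_matrix <- function(n_cases, n_raters, p = runif(1, 0.2, 0.8)) {
  repeat {
    m <- matrix(rbinom(n_cases * n_raters, 1, p), nrow = n_cases)
    if (length(unique(as.vector(m))) > 1) return(m)
  }
}

# A small complete synthetic study for IO/pipeline tests.
tiny_study <- function(n_cases = 12, n_readers = 4, seed = 42,
                       n_permutations = 50, trim_k = 0) {
  cfg <- study_config(n_cases = n_cases, n_readers = n_readers,
                      n_radiologists = max(2, n_readers - 2),
                      n_permutations = n_permutations, trim_k = trim_k,
                      seed = seed)
  simulate_study(cfg)
}
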