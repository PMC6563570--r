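test_that("perfect agreement across mixed categories gives kappa = 1", {
  m <- cbind(c(1, 0, 1, 0, 1), c(1, 0, 1, 0, 1), c(1, 0, 1, 0, 1))
  k <- fleiss_kappa(m)
  expect_equal(k$kappa, 1)
  expect_equal(k$P_o, 1)
  expect_lt(k$P_e, 1)
})

test_that("two raters in perfect balanced opposition give kappa = -1", {
  m <- cbind(c(1, 1, 0, 0), c(0, 0, 1, 1))  # marginals both 0.5, P_o = 0
  k <- fleiss_kappa(m)
  expect_equal(k$P_o, 0)
  expect_equal(k$P_e, 0.5)
  expect_equal(k$kappa, -1)
})

test_that("exact kappa equals the brute-force pairwise oracle", {
  set.seed(101)
  for (i in 1:200) {
    m <- random_rating_matrix(sample(3:20, 1), sample(2:6, 1))
    expect_equal(fleiss_kappa(m, exact = TRUE)$kappa,
                 oracle_pairwise_kappa(m), tolerance = 1e-12)
  }
})

test_that("for two raters the exact form reduces to Cohen's kappa", {
  set.seed(102)
  for (i in 1:50) {
    m <- random_rating_matrix(sample(4:30, 1), 2)
    expect_equal(fleiss_kappa(m, exact = TRUE)$kappa,
                 oracle_cohen_kappa(m[, 1], m[, 2]), tolerance = 1e-12)
  }
})

test_that("classic (pooled-marginal) variant matches its textbook formula", {
  set.seed(103)
  m <- random_rating_matrix(12, 4)
  k <- fleiss_kappa(m, exact = FALSE)
  pj <- c(mean(m == 0), mean(m == 1))
  expect_equal(k$P_e, sum(pj^2), tolerance = 1e-12)
  expect_match(k$method, "classic")
})

test_that("kappa is invariant to joint case and rater permutations", {
  set.seed(104)
  m <- random_rating_matrix(15, 5)
  k0 <- fleiss_kappa(m)$kappa
  for (i in 1:10) {
    perm <- m[sample.int(nrow(m)), sample.int(ncol(m))]
    expect_equal(fleiss_kappa(perm)$kappa, k0, tolerance = 1e-12)
  }
})

test_that("independent label noise degrades agreement monotonically", {
  set.seed(105)
  base <- matrix(rep(rbinom(60, 1, 0.5), 6), ncol = 6)  # perfect agreement
  kappas <- vapply(c(0, 0.1, 0.25, 0.45), function(noise) {
    mean(replicate(40, {
      flip <- matrix(runif(length(base)) < noise, nrow = nrow(base))
      m <- ifelse(flip, 1 - base, base)
      if (length(unique(as.vector(m))) == 1) return(NA_real_)
      fleiss_kappa(m)$kappa
    }), na.rm = TRUE)
  }, numeric(1))
  expect_equal(kappas[1], 1)
  expect_true(all(diff(kappas) < 0))
})

test_that("degenerate inputs raise informative errors", {
  expect_error(fleiss_kappa(matrix(1, 5, 1)), "2 raters")
  expect_error(fleiss_kappa(matrix(1L, 5, 3)), "degenerate agreement")
  expect_error(fleiss_kappa(matrix(integer(0), 0, 3)), "1 case")
})

test_that("permutation test is deterministic given a seed", {
  set.seed(106)
  a <- random_rating_matrix(20, 4)
  b <- random_rating_matrix(20, 4)
  r1 <- kappa_permutation_test(a, b, B = 300, seed = 7)
  r2 <- kappa_permutation_test(a, b, B = 300, seed = 7)
  expect_identical(r1$null_diffs, r2$null_diffs)
  expect_identical(r1$p_value, r2$p_value)
  expect_equal(r1$observed_diff,
               fleiss_kappa(a)$kappa - fleiss_kappa(b)$kappa)
  expect_equal(r1$p_value, r1$null_exceed_count / r1$B)
})

test_that("identical sessions give a degenerate null and p = 0", {
  set.seed(107)
  a <- random_rating_matrix(15, 4)
  expect_warning(res <- kappa_permutation_test(a, a, B = 50, seed = 1),
                 "degenerate permutation null")
  expect_equal(res$observed_diff, 0)
  expect_true(all(res$null_diffs == 0))
  expect_equal(res$p_value, 0)
  smooth <- suppressWarnings(
    kappa_permutation_test(a, a, B = 50, seed = 1, smoothed = TRUE))
  expect_equal(smooth$p_value, 1 / 51)
})

test_that("permutation test validates its inputs", {
  a <- random_rating_matrix(10, 3)
  expect_error(kappa_permutation_test(a, a[1:5, ], B = 10), "dimensions")
  expect_error(kappa_permutation_test(a, a, B = 0), "B must be")
})

test_that("case-level swaps preserve within-case rows; cell-level need not", {
  set.seed(108)
  a <- random_rating_matrix(12, 4)
  b <- random_rating_matrix(12, 4)
  # every permuted matrix row must come from a or b intact under unit="case"
  res <- kappa_permutation_test(a, b, B = 5, seed = 3, unit = "case")
  expect_s3_class(res, "permutation_result")
  set.seed(3)
  swap <- runif(nrow(a)) < 0.5
  a2 <- a; a2[swap, ] <- b[swap, ]
  rows_ok <- vapply(seq_len(nrow(a2)), function(i) {
    identical(a2[i, ], a[i, ]) || identical(a2[i, ], b[i, ])
  }, logical(1))
  expect_true(all(rows_ok))
})
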