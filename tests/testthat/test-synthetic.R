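test_that("simulate_truth builds a deterministic stratified cohort", {
  truth <- simulate_truth(115, 0.5, seed = 1)
  expect_equal(nrow(truth), 115)
  expect_equal(sum(truth$truth == 1), 58)  # round-half-up, not Bernoulli
  expect_equal(sum(truth$truth == 0), 57)
  expect_true(all(truth$max_diameter_mm[truth$truth == 1] > 3))
  expect_true(all(truth$max_diameter_mm[truth$truth == 1] < 40))
  expect_true(all(truth$n_lesions[truth$truth == 1] >= 1))
  expect_true(all(truth$n_lesions[truth$truth == 0] == 0))
  expect_identical(truth, simulate_truth(115, 0.5, seed = 1))
  expect_false(identical(truth, simulate_truth(115, 0.5, seed = 2)))
})

test_that("simulate_truth enforces its domain", {
  expect_error(simulate_truth(0, 0.5), ">= 1")
  expect_error(simulate_truth(10, 0), "strictly between 0 and 1")
  expect_error(simulate_truth(10, 1), "strictly between 0 and 1")
  # deterministic positive count at other sizes
  expect_equal(sum(simulate_truth(10, 0.35, seed = 1)$truth), 4)  # 3.5 -> 4
})

test_that("assign_crossover balances groups and reverses half the orders", {
  roster <- default_roster(8, 6)
  truth <- simulate_truth(20, 0.5, seed = 5)
  des <- assign_crossover(roster, truth$case_id, seed = 9)
  expect_equal(as.vector(table(des$roster$group)), c(4, 4))
  for (g in 1:2) {
    ids <- des$roster$reader_id[des$roster$group == g]
    orders <- des$case_order[ids]
    expect_identical(orders[[1]], orders[[2]])          # forward half shared
    expect_identical(orders[[3]], rev(orders[[1]]))     # reversed half
    expect_identical(orders[[4]], orders[[3]])
  }
  expect_equal(unname(des$first_session), c("unaugmented", "augmented"))
  des2 <- assign_crossover(roster, truth$case_id, seed = 9)
  expect_identical(des$case_order, des2$case_order)
})

test_that("assign_crossover handles two readers and rejects odd rosters", {
  roster2 <- default_roster(2, 2)
  des <- assign_crossover(roster2, sprintf("c%d", 1:5), seed = 1)
  expect_equal(sort(des$roster$group), c(1, 2))
  expect_error(assign_crossover(default_roster(4, 3)[1:3, ], sprintf("c%d", 1:5)),
               "odd reader count")
  expect_error(assign_crossover(roster2[1, , drop = FALSE], "c1"),
               "at least 2 readers")
})

test_that("simulate_annotations is complete, binary and seed-stable", {
  cfg <- study_config(n_cases = 30, n_readers = 4, n_radiologists = 2, seed = 11)
  truth <- simulate_truth(30, 0.5, seed = 12)
  des <- assign_crossover(default_roster(4, 2), truth$case_id, seed = 13)
  ann <- simulate_annotations(truth, des, cfg, seed = 14)
  expect_equal(nrow(ann), 30 * 4 * 2)
  expect_true(all(ann$label %in% 0:1))
  expect_identical(ann, simulate_annotations(truth, des, cfg, seed = 14))
  empty <- des
  empty$roster <- des$roster[0, ]
  expect_error(simulate_annotations(truth, empty, cfg), "empty reader roster")
})

test_that("a null augmentation effect leaves session performance equal", {
  cfg <- study_config(
    n_cases = 60, n_readers = 4, n_radiologists = 2,
    target_sensitivity = c(unaugmented = 0.85, augmented = 0.85),
    target_specificity = c(unaugmented = 0.95, augmented = 0.95), seed = 21)
  diffs <- vapply(1:60, function(i) {
    truth <- simulate_truth(60, 0.5, seed = 1000 + i)
    des <- assign_crossover(default_roster(4, 2), truth$case_id, seed = 2000 + i)
    ann <- simulate_annotations(truth, des, cfg, seed = 3000 + i)
    pos <- truth$case_id[truth$truth == 1]
    sens <- vapply(c("unaugmented", "augmented"), function(s) {
      mean(ann$label[ann$session == s & ann$case_id %in% pos])
    }, numeric(1))
    sens[["augmented"]] - sens[["unaugmented"]]
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 3 * stats::sd(diffs) / sqrt(length(diffs)))
})

test_that("zero case coupling decorrelates reader errors on negatives", {
  cfg <- study_config(n_cases = 4, n_readers = 2, n_radiologists = 2,
                      case_coupling = 0, seed = 31)
  truth <- data.frame(case_id = sprintf("n%04d", 1:4000), truth = 0L,
                      n_lesions = 0L, max_diameter_mm = NA_real_)
  des <- assign_crossover(default_roster(2, 2), truth$case_id, seed = 32)
  ann <- simulate_annotations(truth, des, cfg, seed = 33)
  m <- build_matrix(ann, "unaugmented", des$roster, truth)
  expect_lt(abs(stats::cor(m[, 1], m[, 2])), 0.05)
})

test_that("positive case coupling induces positive label correlation", {
  cfg <- study_config(n_cases = 4, n_readers = 2, n_radiologists = 2,
                      case_coupling = 1.6, seed = 41)
  truth <- data.frame(case_id = sprintf("n%04d", 1:4000), truth = 0L,
                      n_lesions = 0L, max_diameter_mm = NA_real_)
  des <- assign_crossover(default_roster(2, 2), truth$case_id, seed = 42)
  ann <- simulate_annotations(truth, des, cfg, seed = 43)
  m <- build_matrix(ann, "unaugmented", des$roster, truth)
  expect_gt(stats::cor(m[, 1], m[, 2]), 0.15)
})

test_that("simulated marginals track the configured session targets", {
  cfg <- study_config(seed = 51)
  reps <- 60
  sens <- matrix(NA_real_, reps, 2, dimnames = list(NULL, c("unaugmented", "augmented")))
  spec <- sens
  for (i in seq_len(reps)) {
    truth <- simulate_truth(cfg$n_cases, cfg$prevalence, seed = 5000 + i)
    des <- assign_crossover(default_roster(8, 6), truth$case_id, seed = 6000 + i)
    ann <- simulate_annotations(truth, des, cfg, seed = 7000 + i)
    pos <- truth$case_id[truth$truth == 1]
    for (s in c("unaugmented", "augmented")) {
      lab <- ann[ann$session == s, ]
      sens[i, s] <- mean(lab$label[lab$case_id %in% pos])
      spec[i, s] <- mean(1 - lab$label[!lab$case_id %in% pos])
    }
  }
  for (s in c("unaugmented", "augmented")) {
    expect_lt(abs(mean(sens[, s]) - cfg$target_sensitivity[[s]]),
              3 * stats::sd(sens[, s]) / sqrt(reps) + 0.003)
    expect_lt(abs(mean(spec[, s]) - cfg$target_specificity[[s]]),
              3 * stats::sd(spec[, s]) / sqrt(reps) + 0.003)
  }
})

test_that("simulate_times produces increasing timestamps along reading order", {
  study <- tiny_study(n_cases = 20, n_readers = 4)
  ann <- study$annotations
  for (r in study$roster$reader_id) {
    for (s in c("unaugmented", "augmented")) {
      rows <- ann[ann$reader_id == r & ann$session == s, ]
      entry <- rows$entry_time_s[match(study$design$case_order[[r]],
                                       rows$case_id)]
      expect_true(all(diff(entry) > 0))
      expect_true(all(entry > 0))
    }
  }
})

test_that("degenerate time noise collapses to the configured median", {
  cfg <- study_config(n_cases = 10, n_readers = 2, n_radiologists = 2,
                      time_median_s = 50, time_mean_s = 50,  # sdlog = 0
                      p_interruption = 0, seed = 61)
  study_data <- simulate_study(cfg)
  ann <- study_data$annotations
  one <- ann[ann$reader_id == "reader_1" & ann$session == "unaugmented", ]
  d <- diagnosis_durations(one$entry_time_s)
  expect_equal(d, rep(50, 9), tolerance = 1e-9)
})

test_that("toy segmentation volumes binarize back to the truth", {
  pos_case <- data.frame(case_id = "p", truth = 1L, n_lesions = 1L,
                         max_diameter_mm = 8)
  neg_case <- data.frame(case_id = "n", truth = 0L, n_lesions = 0L,
                         max_diameter_mm = NA_real_)
  vp <- simulate_segmentation(pos_case, shape = c(16, 32, 32), seed = 71)
  vn <- simulate_segmentation(neg_case, shape = c(16, 32, 32), seed = 72)
  expect_equal(dim(vp), c(16, 32, 32))
  expect_true(all(vp >= 0 & vp <= 1))
  expect_identical(binarize_prediction(vp), 1L)
  expect_identical(binarize_prediction(vn), 0L)
  expect_identical(vp, simulate_segmentation(pos_case, shape = c(16, 32, 32),
                                             seed = 71))
  expect_error(simulate_segmentation(pos_case, shape = c(0, 4, 4)),
               "positive extents")
  # a tiny lesion still yields at least one supra-threshold voxel
  tiny <- data.frame(case_id = "t", truth = 1L, n_lesions = 1L,
                     max_diameter_mm = 3.2)
  expect_identical(binarize_prediction(simulate_segmentation(tiny, seed = 73)), 1L)
})

test_that("simulate_study is reproducible end to end from the master seed", {
  cfg <- study_config(n_cases = 15, n_readers = 4, n_radiologists = 2,
                      seed = 81, n_permutations = 10)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$annotations, s2$annotations)
})
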