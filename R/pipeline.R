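#' Analyze a crossover reader study
#'
#' Runs the complete statistical analysis on annotation data from the two
#' sessions of a crossover MRMC study: per-reader and pooled (microaveraged)
#' sensitivity/specificity/accuracy with Wilson score intervals, paired
#' one-tailed t tests on cross-reader differences (all readers and the
#' board-certified-radiologist subset), time-to-diagnosis summaries from
#' consecutive entry times with symmetric trimming and t intervals, exact
#' Fleiss kappa per session with a case-level permutation test for the kappa
#' difference, and Benjamini-Hochberg adjustment over the registered
#' hypothesis family.
#'
#' @param annotations Annotation data frame covering both sessions.
#' @param truth Case-record data frame.
#' @param roster Reader roster data frame (with `specialty`).
#' @param config A [study_config()]; supplies the permutation count, trimming
#'   depth, BH family and analysis seed.
#' @param seed Seed for the permutation stream; defaults to
#'   `config$seed + 5` so analysis randomness is decoupled from simulation.
#' @return An object of class `"reader_study_results"`; see Details.
#' @details The result bundles: `per_reader` (metrics per reader-session),
#'   `microaverage` (pooled metrics with Wilson CIs), `tests` (paired-test
#'   objects by hypothesis id), `timing` (per reader-session summaries and
#'   pooled per-session summaries), `agreement` (kappa per session, subset
#'   kappas, permutation result), `hypotheses` (the BH family table with
#'   unadjusted and adjusted p), and `manifest`.
#' @export
analyze_study <- function(annotations, truth, roster, config = study_config(),
                          seed = config$seed + 5L) {
  annotations <- validate_annotations(annotations)
  truth <- validate_truth(truth)
  mats <- lapply(stats::setNames(SESSIONS, SESSIONS), function(s) {
    build_matrix(annotations, s, roster, truth)
  })

  # ---- per-reader and pooled confusion counts --------------------------------
  metrics <- c("sensitivity", "specificity", "accuracy")
  counts <- lapply(mats, function(m) {
    lapply(stats::setNames(colnames(m), colnames(m)), function(r) {
      confusion(stats::setNames(m[, r], rownames(m)), truth)
    })
  })
  per_reader <- do.call(rbind, lapply(SESSIONS, function(s) {
    do.call(rbind, lapply(roster$reader_id, function(r) {
      cc <- counts[[s]][[r]]
      data.frame(reader_id = r, session = s,
                 tp = cc[["tp"]], fp = cc[["fp"]],
                 tn = cc[["tn"]], fn = cc[["fn"]],
                 sensitivity = metric(cc, "sensitivity"),
                 specificity = metric(cc, "specificity"),
                 accuracy = metric(cc, "accuracy"),
                 stringsAsFactors = FALSE)
    }))
  }))
  micro_counts <- lapply(counts, microaverage)
  microaverage_tab <- do.call(rbind, lapply(SESSIONS, function(s) {
    do.call(rbind, lapply(metrics, function(w) {
      fr <- metric_fraction(micro_counts[[s]], w)
      ci <- wilson_ci(fr[["successes"]], fr[["n"]])
      data.frame(session = s, metric = w,
                 successes = fr[["successes"]], n = fr[["n"]],
                 estimate = ci$estimate, ci_lower = ci$lower,
                 ci_upper = ci$upper, stringsAsFactors = FALSE)
    }))
  }))

  # ---- paired cross-reader tests --------------------------------------------
  radiologists <- roster$reader_id[roster$specialty == "radiologist"]
  populations <- list(all = roster$reader_id, radiologists = radiologists)
  tests <- list()
  for (pop in names(populations)) {
    ids <- populations[[pop]]
    if (length(ids) < 2) {
      stop("subgroup '", pop, "' has fewer than 2 readers", call. = FALSE)
    }
    for (w in metrics) {
      a <- per_reader[per_reader$session == "unaugmented" &
                        per_reader$reader_id %in% ids, w]
      b <- per_reader[per_reader$session == "augmented" &
                        per_reader$reader_id %in% ids, w]
      tests[[paste(w, pop, sep = "_")]] <-
        paired_one_tailed_t(a, b, direction = "greater")
    }
  }

  # ---- time to diagnosis -----------------------------------------------------
  timing <- NULL
  have_times <- !anyNA(annotations$entry_time_s)
  if (have_times) {
    per_rs <- do.call(rbind, lapply(SESSIONS, function(s) {
      do.call(rbind, lapply(roster$reader_id, function(r) {
        tt <- annotations$entry_time_s[annotations$reader_id == r &
                                         annotations$session == s]
        d <- diagnosis_durations(tt)
        trimmed <- trim_durations(d, k = config$trim_k)
        ci <- mean_time_ci(trimmed)
        data.frame(reader_id = r, session = s,
                   n_raw = length(d), n_used = length(trimmed),
                   mean_s = ci$mean_s, ci_lower_s = ci$ci_lower_s,
                   ci_upper_s = ci$ci_upper_s, stringsAsFactors = FALSE)
      }))
    }))
    pooled <- lapply(stats::setNames(SESSIONS, SESSIONS), function(s) {
      all_trimmed <- unlist(lapply(roster$reader_id, function(r) {
        tt <- annotations$entry_time_s[annotations$reader_id == r &
                                         annotations$session == s]
        trim_durations(diagnosis_durations(tt), k = config$trim_k)
      }))
      mean_time_ci(all_trimmed)
    })
    a <- per_rs$mean_s[per_rs$session == "unaugmented"]
    b <- per_rs$mean_s[per_rs$session == "augmented"]
    tests[["time_all"]] <- paired_one_tailed_t(a, b, direction = "less")
    timing <- list(per_reader_session = per_rs, pooled = pooled)
  }

  # ---- interrater agreement --------------------------------------------------
  kappas <- lapply(mats, fleiss_kappa, exact = TRUE)
  kappa_subset <- if (length(radiologists) >= 2) {
    lapply(mats, function(m) fleiss_kappa(m[, radiologists, drop = FALSE],
                                          exact = TRUE))
  } else NULL
  perm <- kappa_permutation_test(mats$augmented, mats$unaugmented,
                                 B = config$n_permutations, seed = seed,
                                 exact = TRUE)
  agreement <- list(kappa = kappas, kappa_radiologists = kappa_subset,
                    permutation = perm)

  # ---- hypothesis family and BH adjustment ----------------------------------
  rows <- lapply(config$bh_family, function(id) {
    if (id == "kappa_all") {
      data.frame(id = id, metric = "kappa", population = "all",
                 direction = "greater", mean_diff = perm$observed_diff,
                 ci_lower = NA_real_, ci_upper = NA_real_,
                 t_stat = NA_real_, df = NA_integer_,
                 p_unadjusted = perm$p_value, stringsAsFactors = FALSE)
    } else if (!is.null(tests[[id]])) {
      tst <- tests[[id]]
      parts <- strsplit(id, "_", fixed = TRUE)[[1]]
      data.frame(id = id, metric = parts[1],
                 population = paste(parts[-1], collapse = "_"),
                 direction = tst$direction, mean_diff = tst$mean_diff,
                 ci_lower = tst$ci_lower, ci_upper = tst$ci_upper,
                 t_stat = tst$t_stat, df = tst$df,
                 p_unadjusted = tst$p_one_tailed, stringsAsFactors = FALSE)
    } else {
      stop("BH family names hypothesis '", id,
           "' but the analysis produced no such test", call. = FALSE)
    }
  })
  hypotheses <- do.call(rbind, rows)
  hypotheses$p_adjusted <- bh_adjust(hypotheses$p_unadjusted)
  hypotheses$significant <- hypotheses$p_adjusted <= config$alpha

  manifest <- list(
    package = "readerstudy",
    version = as.character(utils::packageVersion("readerstudy")),
    seed = config$seed,
    analysis_seed = seed,
    n_permutations = config$n_permutations,
    bh_family = config$bh_family,
    n_cases = nrow(truth),
    n_readers = nrow(roster),
    config_hash = config_hash(config)
  )

  structure(
    list(per_reader = per_reader,
         microaverage = microaverage_tab,
         tests = tests,
         timing = timing,
         agreement = agreement,
         hypotheses = hypotheses,
         roster = roster,
         config = config,
         manifest = manifest),
    class = "reader_study_results"
  )
}

#' Simulate and analyze a full study in one call
#'
#' @param config A [study_config()].
#' @return A `"reader_study_results"` object with the generated
#'   `"reader_study_data"` attached as `$data`.
#' @examples
#' \donttest{
#' res <- run_full_study(study_config(n_permutations = 200))
#' res$hypotheses[, c("id", "mean_diff", "p_unadjusted", "p_adjusted")]
#' }
#' @export
run_full_study <- function(config = study_config()) {
  data <- simulate_study(config)
  res <- analyze_study(data$annotations, data$truth, data$roster, config)
  res$data <- data
  res
}

#' Write analysis reports
#'
#' Emits machine-readable CSV tables (`hypotheses.csv`, `microaverages.csv`,
#' `readers.csv`, `timing.csv`, `agreement.csv`), a JSON run manifest and a
#' human-readable `summary.md`. Machine-readable files carry full precision
#' and are byte-identical across reruns with the same config and seed; the
#' summary rounds proportions to 3 decimals and prints p values in journal
#' style (`<.001` floor).
#'
#' @param results A `"reader_study_results"` object.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_report <- function(results, dir) {
  if (!inherits(results, "reader_study_results") ||
      is.null(results$hypotheses) || nrow(results$hypotheses) == 0) {
    stop("empty or invalid results bundle; nothing to report", call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create report directory ", dir, call. = FALSE)
  wr <- function(x, name) {
    utils::write.csv(x, file.path(dir, name), row.names = FALSE, quote = FALSE)
  }
  wr(results$hypotheses, "hypotheses.csv")
  wr(results$microaverage, "microaverages.csv")
  wr(results$per_reader, "readers.csv")
  if (!is.null(results$timing)) {
    pooled <- do.call(rbind, lapply(SESSIONS, function(s) {
      ci <- results$timing$pooled[[s]]
      data.frame(session = s, n = ci$n, mean_s = ci$mean_s,
                 ci_lower_s = ci$ci_lower_s, ci_upper_s = ci$ci_upper_s,
                 stringsAsFactors = FALSE)
    }))
    wr(results$timing$per_reader_session, "timing.csv")
    wr(pooled, "timing_pooled.csv")
  }
  ag <- results$agreement
  agreement_tab <- data.frame(
    session = SESSIONS,
    kappa_all = vapply(SESSIONS, function(s) ag$kappa[[s]]$kappa, numeric(1)),
    kappa_radiologists = if (!is.null(ag$kappa_radiologists)) {
      vapply(SESSIONS, function(s) ag$kappa_radiologists[[s]]$kappa, numeric(1))
    } else NA_real_,
    stringsAsFactors = FALSE
  )
  wr(agreement_tab, "agreement.csv")
  jsonlite::write_json(results$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(render_summary(results), file.path(dir, "summary.md"))
  invisible(dir)
}

# Markdown summary mirroring the usual presentation: one row per pooled
# metric with both sessions, mean increase with CI, and both p values.
render_summary <- function(results) {
  mm <- results$microaverage
  hy <- results$hypotheses
  fmt_ci <- function(e, lo, hi) sprintf("%.3f (%.3f to %.3f)", e, lo, hi)
  line_for <- function(w) {
    un <- mm[mm$session == "unaugmented" & mm$metric == w, ]
    au <- mm[mm$session == "augmented" & mm$metric == w, ]
    h <- hy[hy$id == paste0(w, "_all"), ]
    sprintf("| %s | %s | %s | %s | %s | %s |",
            tools::toTitleCase(w),
            fmt_ci(un$estimate, un$ci_lower, un$ci_upper),
            fmt_ci(au$estimate, au$ci_lower, au$ci_upper),
            fmt_ci(h$mean_diff, h$ci_lower, h$ci_upper),
            format_p(h$p_unadjusted), format_p(h$p_adjusted))
  }
  out <- c(
    "# Crossover reader-study analysis",
    "",
    sprintf("%d readers x %d cases; seed %d; B = %d permutations; BH family of %d.",
            results$manifest$n_readers, results$manifest$n_cases,
            results$manifest$seed, results$manifest$n_permutations,
            length(results$manifest$bh_family)),
    "",
    "| Metric | Microaverage without (95% CI) | With (95% CI) | Mean increase (95% CI) | P | Adjusted P |",
    "|---|---|---|---|---|---|",
    vapply(c("sensitivity", "specificity", "accuracy"), line_for, character(1)),
    ""
  )
  ag <- results$agreement
  out <- c(out, sprintf(
    "Exact Fleiss kappa: %.3f without vs %.3f with augmentation (difference %.3f, permutation P %s, adjusted P %s).",
    ag$kappa$unaugmented$kappa, ag$kappa$augmented$kappa,
    ag$permutation$observed_diff, format_p(ag$permutation$p_value),
    format_p(hy$p_adjusted[hy$id == "kappa_all"])))
  if (!is.null(ag$kappa_radiologists)) {
    out <- c(out, sprintf(
      "Radiologist subset kappa: %.3f without vs %.3f with augmentation.",
      ag$kappa_radiologists$unaugmented$kappa,
      ag$kappa_radiologists$augmented$kappa))
  }
  if (!is.null(results$timing)) {
    pu <- results$timing$pooled$unaugmented
    pa <- results$timing$pooled$augmented
    h <- hy[hy$id == "time_all", ]
    out <- c(out, "", sprintf(
      "Mean diagnosis time: %.2f s (95%% CI, %.2f-%.2f) without vs %.2f s (%.2f-%.2f) with augmentation; change %.2f s, adjusted P %s.",
      pu$mean_s, pu$ci_lower_s, pu$ci_upper_s,
      pa$mean_s, pa$ci_lower_s, pa$ci_upper_s,
      if (nrow(h) == 1) h$mean_diff else NA,
      if (nrow(h) == 1) format_p(h$p_adjusted) else "NA"))
  }
  out
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(unclass(config)), f)
  unname(tools::md5sum(f))
}

#' @export
print.reader_study_results <- function(x, ...) {
  cat(paste(render_summary(x), collapse = "\n"), "\n")
  invisible(x)
}
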