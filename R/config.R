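#' Study design configuration
#'
#' Builds the configuration object that drives both the synthetic cohort
#' generator and the analysis pipeline. Defaults reproduce the design of an
#' 8-reader, 115-case crossover study at 50% prevalence with a 14-day washout,
#' with generator calibration targets matching pooled performance of roughly
#' 0.83 -> 0.89 sensitivity and 0.96 -> 0.975 specificity under augmentation,
#' and reading times of about a minute per examination.
#'
#' @param n_cases Number of test cases each reader labels per session.
#' @param prevalence Proportion of truth-positive cases, in (0, 1). The
#'   positive count is deterministic (`round_half_up(n_cases * prevalence)`),
#'   mirroring stratified test-set construction, not Bernoulli sampling.
#' @param n_readers Number of readers; must be even so the two crossover
#'   groups are balanced.
#' @param n_radiologists Number of board-certified radiologists in the roster
#'   (the subgroup used for the sensitivity analysis); defaults to all but two
#'   readers, the remaining two being a neurosurgeon and a resident.
#' @param washout_days Washout period between the two reading sessions.
#' @param target_sensitivity,target_specificity Length-2 named numeric vectors
#'   (`unaugmented`, `augmented`): the pooled per-session probabilities the
#'   generator is calibrated to reproduce in expectation.
#' @param case_coupling Non-negative latent case-difficulty scale (probit
#'   units). Larger values make readers miss the same cases, raising
#'   inter-reader agreement; 0 gives independent reader errors.
#' @param reader_sd_sens,reader_sd_spec Standard deviation of per-reader
#'   propensities on the probit scale (reader heterogeneity).
#' @param time_median_s,time_mean_s Median and mean of the lognormal per-case
#'   reading-time distribution, in seconds. `time_mean_s >= time_median_s`.
#' @param p_interruption Probability that a given case's reading time is
#'   contaminated by an interruption.
#' @param interruption_range_s Length-2 range (seconds) of the uniform
#'   interruption added to a contaminated reading time.
#' @param trim_k Number of longest and of shortest per-case times dropped from
#'   each reader-session before timing summaries (the 5/5 trimming rule).
#' @param n_permutations Number of permutations for the kappa-difference test.
#' @param seed Integer master seed; all simulation and permutation substreams
#'   are derived from it by fixed offsets.
#' @param bh_family Character vector of hypothesis ids forming the
#'   Benjamini-Hochberg family for a full run. The default registers eight
#'   hypotheses: the three metrics for all readers and for the radiologist
#'   subset, the time decrease, and the agreement increase.
#' @param alpha Significance level applied to BH-adjusted p values.
#'
#' @return A list of class `"study_config"`.
#' @examples
#' cfg <- study_config(n_cases = 20, n_readers = 4, n_permutations = 200)
#' cfg$prevalence
#' @export
study_config <- function(n_cases = 115,
                         prevalence = 0.5,
                         n_readers = 8,
                         n_radiologists = if (n_readers >= 4) n_readers - 2L else n_readers,
                         washout_days = 14,
                         target_sensitivity = c(unaugmented = 0.831, augmented = 0.890),
                         target_specificity = c(unaugmented = 0.960, augmented = 0.975),
                         case_coupling = 1.6,
                         reader_sd_sens = 0.3,
                         reader_sd_spec = 0.3,
                         time_median_s = 50,
                         time_mean_s = 57,
                         p_interruption = 0.02,
                         interruption_range_s = c(300, 1200),
                         trim_k = 5,
                         n_permutations = 10000,
                         seed = 20190607L,
                         bh_family = c("sensitivity_all", "specificity_all",
                                       "accuracy_all",
                                       "sensitivity_radiologists",
                                       "specificity_radiologists",
                                       "accuracy_radiologists",
                                       "time_all", "kappa_all"),
                         alpha = 0.05) {
  if (!is.numeric(n_cases) || n_cases < 1) {
    stop("`n_cases` must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(prevalence) || prevalence <= 0 || prevalence >= 1) {
    stop("`prevalence` must lie strictly between 0 and 1", call. = FALSE)
  }
  if (n_readers < 2 || n_readers %% 2 != 0) {
    stop("`n_readers` must be even and >= 2 for a balanced two-group crossover",
         call. = FALSE)
  }
  if (n_radiologists > n_readers) {
    stop("`n_radiologists` cannot exceed `n_readers`", call. = FALSE)
  }
  for (nm in c("target_sensitivity", "target_specificity")) {
    v <- get(nm)
    if (length(v) != 2 || !all(c("unaugmented", "augmented") %in% names(v))) {
      stop("`", nm, "` must be named c(unaugmented=, augmented=)", call. = FALSE)
    }
    if (any(v <= 0) || any(v >= 1)) {
      stop("`", nm, "` entries must lie strictly between 0 and 1", call. = FALSE)
    }
  }
  if (case_coupling < 0) stop("`case_coupling` must be >= 0", call. = FALSE)
  if (p_interruption < 0 || p_interruption > 1) {
    stop("`p_interruption` must lie in [0, 1]", call. = FALSE)
  }
  if (time_mean_s < time_median_s || time_median_s <= 0) {
    stop("need 0 < time_median_s <= time_mean_s (lognormal mean >= median)",
         call. = FALSE)
  }
  if (length(interruption_range_s) != 2 ||
      interruption_range_s[1] > interruption_range_s[2]) {
    stop("`interruption_range_s` must be an increasing length-2 range",
         call. = FALSE)
  }
  if (n_permutations < 1) stop("`n_permutations` (B) must be >= 1", call. = FALSE)
  if (trim_k < 0) stop("`trim_k` must be >= 0", call. = FALSE)

  cfg <- list(
    n_cases = as.integer(n_cases),
    prevalence = prevalence,
    n_readers = as.integer(n_readers),
    n_radiologists = as.integer(n_radiologists),
    washout_days = washout_days,
    target_sensitivity = target_sensitivity[c("unaugmented", "augmented")],
    target_specificity = target_specificity[c("unaugmented", "augmented")],
    case_coupling = case_coupling,
    reader_sd_sens = reader_sd_sens,
    reader_sd_spec = reader_sd_spec,
    time_median_s = time_median_s,
    time_mean_s = time_mean_s,
    p_interruption = p_interruption,
    interruption_range_s = as.numeric(interruption_range_s),
    trim_k = as.integer(trim_k),
    n_permutations = as.integer(n_permutations),
    seed = as.integer(seed),
    bh_family = bh_family,
    alpha = alpha
  )
  class(cfg) <- "study_config"
  cfg
}

#' Read a study configuration from YAML or JSON
#'
#' Flat keys matching the arguments of [study_config()]; unknown keys are an
#' error so typos do not silently fall back to defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `"study_config"` object.
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = ,
    yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("unsupported config extension '", ext, "' (use yaml or json)",
         call. = FALSE)
  )
  known <- names(formals(study_config))
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  for (nm in c("target_sensitivity", "target_specificity")) {
    if (!is.null(raw[[nm]])) raw[[nm]] <- unlist(raw[[nm]])
  }
  do.call(study_config, raw)
}

#' Default reader roster
#'
#' Readers are labelled `reader_1 ... reader_n`; the first `n_radiologists`
#' are board-certified radiologists with experience evenly spread over 3-12
#' years, followed by a neurosurgeon and a radiology resident (2 years each).
#' Crossover group membership is assigned later by [assign_crossover()].
#'
#' @param n_readers Total readers (even).
#' @param n_radiologists Number of radiologists among them.
#' @return A data frame with columns `reader_id`, `specialty`,
#'   `years_experience` and a placeholder `group` column (`NA`).
#' @export
default_roster <- function(n_readers = 8, n_radiologists = 6) {
  if (n_radiologists > n_readers) {
    stop("`n_radiologists` cannot exceed `n_readers`", call. = FALSE)
  }
  n_other <- n_readers - n_radiologists
  specialty <- c(rep("radiologist", n_radiologists),
                 if (n_other >= 1) "neurosurgeon",
                 if (n_other >= 2) rep("resident", n_other - 1))
  years <- c(if (n_radiologists > 0)
               round(seq(3, 12, length.out = n_radiologists), 1),
             rep(2, n_other))
  data.frame(
    reader_id = sprintf("reader_%d", seq_len(n_readers)),
    specialty = specialty,
    years_experience = years,
    group = NA_integer_,
    stringsAsFactors = FALSE
  )
}

# Probit-scale generative parameters implied by a config. The marginal hit
# rate of Phi(a_r - tau * d_c) over reader effects a_r ~ N(a0, sd^2) and case
# latents d_c ~ N(0, 1) is Phi(a0 / s) with s = sqrt(1 + tau^2 + sd^2), so
# the intercepts and session shifts below reproduce the configured targets in
# expectation, exactly.
generative_params <- function(config) {
  tau <- config$case_coupling
  s_sens <- sqrt(1 + tau^2 + config$reader_sd_sens^2)
  s_spec <- sqrt(1 + tau^2 + config$reader_sd_spec^2)
  ts <- config$target_sensitivity
  fp <- 1 - config$target_specificity   # false-positive rates per session
  list(
    a0 = stats::qnorm(ts[["unaugmented"]]) * s_sens,
    delta_sens = (stats::qnorm(ts[["augmented"]]) -
                  stats::qnorm(ts[["unaugmented"]])) * s_sens,
    b0 = stats::qnorm(fp[["unaugmented"]]) * s_spec,
    delta_fp = (stats::qnorm(fp[["augmented"]]) -
                stats::qnorm(fp[["unaugmented"]])) * s_spec,
    tau = tau,
    sd_sens = config$reader_sd_sens,
    sd_spec = config$reader_sd_spec,
    meanlog = log(config$time_median_s),
    sdlog = sqrt(2 * log(config$time_mean_s / config$time_median_s)),
    p_interruption = config$p_interruption,
    interruption_range_s = config$interruption_range_s
  )
}

#' @export
print.study_config <- function(x, ...) {
  cat("Crossover reader-study configuration\n")
  cat(sprintf("  %d cases (prevalence %.2f), %d readers (%d radiologists), washout %s days\n",
              x$n_cases, x$prevalence, x$n_readers, x$n_radiologists,
              format(x$washout_days)))
  cat(sprintf("  sensitivity targets %.3f -> %.3f, specificity targets %.3f -> %.3f\n",
              x$target_sensitivity[["unaugmented"]],
              x$target_sensitivity[["augmented"]],
              x$target_specificity[["unaugmented"]],
              x$target_specificity[["augmented"]]))
  cat(sprintf("  case coupling tau = %.2f, reader SDs (%.2f, %.2f)\n",
              x$case_coupling, x$reader_sd_sens, x$reader_sd_spec))
  cat(sprintf("  times: lognormal median %.0f s / mean %.0f s, %.0f%% interruptions, trim %d/%d\n",
              x$time_median_s, x$time_mean_s, 100 * x$p_interruption,
              x$trim_k, x$trim_k))
  cat(sprintf("  B = %d permutations, seed = %d, BH family of %d\n",
              x$n_permutations, x$seed, length(x$bh_family)))
  invisible(x)
}

# Sessions are a closed two-level enum throughout the package.
SESSIONS <- c("unaugmented", "augmented")

check_session <- function(session) {
  if (length(session) != 1 || !session %in% SESSIONS) {
    stop("`session` must be one of ", paste(sQuote(SESSIONS), collapse = ", "),
         call. = FALSE)
  }
  session
}
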