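#' Simulate a case truth table
#'
#' Builds a stratified truth table: the number of positive cases is
#' deterministic — `round_half_up(n_cases * prevalence)` — mirroring
#' stratified test-set construction rather than Bernoulli sampling, and the
#' case order is shuffled by the seed. Positive cases draw a largest-lesion
#' diameter from four size strata, 3-7, 7-12, 12-24 and >= 24 mm, with
#' weights 148:108:61:11 (the size distribution of the aneurysm cohort the
#' defaults emulate), uniform within each stratum; a second lesion is present
#' with probability 20/328.
#'
#' @param n_cases Positive integer.
#' @param prevalence Proportion of positives, strictly inside (0, 1).
#' @param seed Optional integer seed.
#' @return A case-record data frame: `case_id`, `truth`, `n_lesions`,
#'   `max_diameter_mm` (`NA` for negatives).
#' @examples
#' simulate_truth(115, 0.5, seed = 1)  # 58 positives, 57 negatives
#' @export
simulate_truth <- function(n_cases, prevalence = 0.5, seed = NULL) {
  if (n_cases < 1) stop("`n_cases` must be >= 1", call. = FALSE)
  if (prevalence <= 0 || prevalence >= 1) {
    stop("domain error: prevalence must lie strictly between 0 and 1",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  n_pos <- floor(n_cases * prevalence + 0.5)  # round half up
  n_neg <- n_cases - n_pos
  strata <- matrix(c(3, 7, 7, 12, 12, 24, 24, 40), ncol = 2, byrow = TRUE)
  w <- c(148, 108, 61, 11) / 328
  stratum <- sample.int(4, n_pos, replace = TRUE, prob = w)
  diam <- stats::runif(n_pos, strata[stratum, 1], strata[stratum, 2])
  diam <- pmax(diam, 3 + 1e-6)  # clinical significance is strictly > 3 mm
  lesions <- 1L + stats::rbinom(n_pos, 1L, 20 / 328)
  cases <- data.frame(
    case_id = sprintf("case_%03d", seq_len(n_cases)),
    truth = c(rep(1L, n_pos), rep(0L, n_neg)),
    n_lesions = c(lesions, rep(0L, n_neg)),
    max_diameter_mm = c(diam, rep(NA_real_, n_neg)),
    stringsAsFactors = FALSE
  )
  ord <- sample.int(n_cases)
  cases <- cases[ord, , drop = FALSE]
  # ids name positions in the final (shuffled) presentation order
  cases$case_id <- sprintf("case_%03d", seq_len(n_cases))
  rownames(cases) <- NULL
  validate_truth(cases)
}

#' Assign readers to the two-group crossover design
#'
#' Readers are split randomly and equally into groups 1 and 2. Group 1 reads
#' the unaugmented session first, group 2 the augmented session first; the
#' washout between sessions is part of the configuration, not the data.
#' Within each group, a fixed random case order is drawn; half of the group
#' (the first `ceiling(m/2)` members) reads in that order and the other half
#' in its exact reversal.
#'
#' @param roster Reader roster data frame (see [default_roster()]).
#' @param case_ids Character vector of case ids defining the order domain.
#' @param seed Optional integer seed.
#' @return An object of class `"crossover_design"`: a list with `roster`
#'   (group column filled), `case_order` (named list: reader id -> case-id
#'   reading order, identical across the reader's two sessions) and
#'   `first_session` (named by group).
#' @export
assign_crossover <- function(roster, case_ids, seed = NULL) {
  n <- nrow(roster)
  if (n < 2) stop("at least 2 readers are required", call. = FALSE)
  if (n %% 2 != 0) {
    stop("odd reader count: the crossover design needs equal groups",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  roster$group <- sample(rep(1:2, each = n / 2))
  case_order <- vector("list", n)
  names(case_order) <- roster$reader_id
  for (g in 1:2) {
    members <- which(roster$group == g)
    base <- sample(case_ids)
    m <- length(members)
    n_forward <- ceiling(m / 2)
    for (i in seq_along(members)) {
      case_order[[members[i]]] <- if (i <= n_forward) base else rev(base)
    }
  }
  structure(
    list(roster = roster,
         case_order = case_order,
         first_session = c(`1` = "unaugmented", `2` = "augmented")),
    class = "crossover_design"
  )
}

#' Simulate reader annotations for both sessions
#'
#' Labels follow a probit latent-trait model. Each case carries a latent
#' difficulty `z_c ~ N(0, 1)`, shared by all readers and both sessions (the
#' same hard cases are missed in both arms of the crossover). Each reader r
#' has propensities `a_r ~ N(a0, sd_sens^2)` (true positives) and
#' `b_r ~ N(b0, sd_spec^2)` (false positives), fixed across sessions. Then,
#' with `aug = 1` in the augmented session:
#'
#' * positive case: `P(label = 1) = Phi(a_r + delta_sens * aug - tau * z_c)`
#' * negative case: `P(label = 1) = Phi(b_r + delta_fp * aug + tau * z_c)`
#'
#' where `delta_fp <= 0` when augmentation raises specificity. Intercepts and
#' shifts are derived from the config's target rates by
#' `qnorm(target) * sqrt(1 + tau^2 + sd^2)`, so the configured pooled
#' sensitivities/specificities are reproduced in expectation, exactly.
#' Reader draws are independent given the latents; `tau` controls how
#' strongly reader errors cluster on the same cases.
#'
#' @param cases Case-record data frame from [simulate_truth()].
#' @param design `"crossover_design"` from [assign_crossover()].
#' @param config A [study_config()].
#' @param seed Optional integer seed.
#' @return Annotation data frame (both sessions, `entry_time_s = NA`; fill
#'   with [simulate_times()]).
#' @export
simulate_annotations <- function(cases, design, config, seed = NULL) {
  roster <- design$roster
  if (nrow(roster) == 0) stop("empty reader roster", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  pars <- generative_params(config)
  R <- nrow(roster)
  N <- nrow(cases)
  a_r <- stats::rnorm(R, pars$a0, pars$sd_sens)
  b_r <- stats::rnorm(R, pars$b0, pars$sd_spec)
  z_c <- stats::rnorm(N)
  pos <- cases$truth == 1L
  out <- vector("list", 2L * R)
  k <- 0L
  for (session in SESSIONS) {
    aug <- as.numeric(session == "augmented")
    for (r in seq_len(R)) {
      p <- numeric(N)
      p[pos] <- stats::pnorm(a_r[r] + pars$delta_sens * aug - pars$tau * z_c[pos])
      p[!pos] <- stats::pnorm(b_r[r] + pars$delta_fp * aug + pars$tau * z_c[!pos])
      k <- k + 1L
      out[[k]] <- data.frame(
        reader_id = roster$reader_id[r],
        case_id = cases$case_id,
        session = session,
        label = stats::rbinom(N, 1L, p),
        entry_time_s = NA_real_,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}

#' Simulate per-case reading times and fill entry timestamps
#'
#' Per-case reading durations are lognormal with configured median and mean
#' (`meanlog = log(median)`, `sdlog = sqrt(2 log(mean/median))`). With
#' probability `p_interruption` a duration is contaminated by a uniform
#' interruption (default 300-1200 s), which is what the downstream 5/5
#' trimming rule exists to remove. Entry timestamps are the cumulative sums
#' of durations along each reader's reading order; the two sessions use the
#' same order and independent durations.
#'
#' @param annotations Annotation data frame (both sessions).
#' @param design `"crossover_design"` providing per-reader reading orders.
#' @param config A [study_config()].
#' @param seed Optional integer seed.
#' @return The annotations with `entry_time_s` filled (strictly increasing
#'   along each reader-session's reading order).
#' @export
simulate_times <- function(annotations, design, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pars <- generative_params(config)
  for (reader in design$roster$reader_id) {
    order_ids <- design$case_order[[reader]]
    if (is.null(order_ids)) {
      stop("no reading order for reader '", reader, "'", call. = FALSE)
    }
    n <- length(order_ids)
    for (session in SESSIONS) {
      durations <- stats::rlnorm(n, pars$meanlog, pars$sdlog)
      hit <- stats::runif(n) < pars$p_interruption
      if (any(hit)) {
        durations[hit] <- durations[hit] +
          stats::runif(sum(hit), pars$interruption_range_s[1],
                       pars$interruption_range_s[2])
      }
      entry <- cumsum(durations)
      rows <- which(annotations$reader_id == reader &
                      annotations$session == session)
      idx <- match(order_ids, annotations$case_id[rows])
      if (anyNA(idx)) {
        stop("annotations incomplete for reader '", reader, "', session '",
             session, "'", call. = FALSE)
      }
      annotations$entry_time_s[rows[idx]] <- entry
    }
  }
  annotations
}

#' Simulate a toy voxel-probability segmentation volume
#'
#' Geometric stand-in for a segmentation model's output on one case, built so
#' the at-least-one-voxel binarization rule recovers the truth by
#' construction: a negative case is background noise with every voxel
#' probability below 0.5; a positive case additionally contains one
#' contiguous spherical blob whose peak exceeds 0.5 and whose diameter (in
#' voxels) scales with the case's `max_diameter_mm`.
#'
#' @param case A single case record (one row of a truth table).
#' @param shape Integer length-3 volume shape (slices, rows, cols); keep it
#'   small, e.g. `c(16, 32, 32)`.
#' @param seed Optional integer seed.
#' @param voxel_mm Isotropic voxel size in mm used to scale the blob.
#' @return A numeric array of voxel probabilities in [0, 1].
#' @export
simulate_segmentation <- function(case, shape = c(16, 32, 32), seed = NULL,
                                  voxel_mm = 1.0) {
  if (length(shape) != 3 || any(shape < 1)) {
    stop("`shape` must be 3 positive extents", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  vol <- array(stats::runif(prod(shape), 0, 0.45), dim = shape)
  if (case$truth == 1L) {
    radius <- max(1.0, (case$max_diameter_mm / 2) / voxel_mm)
    radius <- min(radius, (min(shape) - 1) / 2)
    centre <- vapply(shape, function(d) {
      lo <- min(max(1, ceiling(radius)), d)
      hi <- max(lo, d - ceiling(radius) + 1)
      if (hi > lo) sample(lo:hi, 1) else lo
    }, numeric(1))
    grid <- expand.grid(i = seq_len(shape[1]), j = seq_len(shape[2]),
                        k = seq_len(shape[3]))
    dist <- sqrt((grid$i - centre[1])^2 + (grid$j - centre[2])^2 +
                   (grid$k - centre[3])^2)
    # radial profile: 0.95 at the centre, exactly 0.5 at the blob radius
    blob <- 0.95 * exp(-log(0.95 / 0.5) * (dist / radius)^2)
    vol <- array(pmax(as.vector(vol), blob * (dist <= 1.5 * radius)),
                 dim = shape)
    vol[centre[1], centre[2], centre[3]] <- 0.95
  }
  vol
}

#' Simulate a complete crossover reader study
#'
#' Runs the whole generator under a single master seed: truth table, roster,
#' crossover assignment, annotations for both sessions, and reading times.
#' Substreams use fixed offsets from the master seed (+1 truth, +2 crossover,
#' +3 annotations, +4 times), so any stage can be reproduced independently.
#'
#' @param config A [study_config()].
#' @return An object of class `"reader_study_data"`: list with `truth`,
#'   `roster`, `design`, `annotations`, `config`.
#' @export
simulate_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  truth <- simulate_truth(config$n_cases, config$prevalence,
                          seed = config$seed + 1L)
  roster <- default_roster(config$n_readers, config$n_radiologists)
  design <- assign_crossover(roster, truth$case_id, seed = config$seed + 2L)
  ann <- simulate_annotations(truth, design, config, seed = config$seed + 3L)
  ann <- simulate_times(ann, design, config, seed = config$seed + 4L)
  structure(
    list(truth = truth, roster = design$roster, design = design,
         annotations = ann, config = config),
    class = "reader_study_data"
  )
}

#' @export
print.reader_study_data <- function(x, ...) {
  cat(sprintf("synthetic reader study: %d cases (%d positive), %d readers, %d annotations\n",
              nrow(x$truth), sum(x$truth$truth), nrow(x$roster),
              nrow(x$annotations)))
  invisible(x)
}
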