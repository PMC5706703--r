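#' Build a blocked trial schedule
#'
#' Trials are blocked by prior condition: the prior alternates from block
#' to block starting from `start_prior` (chosen at random per subject in
#' the experiment), while within each block the likelihood conditions are
#' presented equally often in shuffled order.
#'
#' @param design A [task_design()].
#' @param start_prior Label of the prior condition of block 1 (one of
#'   `names(design$prior_sds)`), or `"random"` to draw it.
#' @param seed Optional integer seed.
#' @return A data frame with one row per trial: `block`, `trial_index`
#'   (within block), `prior`, `likelihood`, `prior_sd`, `likelihood_sd`.
#' @examples
#' sched <- build_schedule(task_design(), start_prior = "Narrow", seed = 1)
#' table(sched$prior, sched$likelihood)  # 6 x 80 for the default design
#' @export
build_schedule <- function(design = task_design(),
                           start_prior = "random", seed = NULL) {
  stopifnot(inherits(design, "task_design"))
  lk <- names(design$likelihood_sds)
  if (design$trials_per_block %% length(lk) != 0L)
    stop("'trials_per_block' (", design$trials_per_block,
         ") is not divisible by the number of likelihood conditions (",
         length(lk), ")", call. = FALSE)
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_rng(old), add = TRUE)
    set.seed(seed)
  }
  priors <- names(design$prior_sds)
  if (identical(start_prior, "random"))
    start_prior <- sample(priors, 1L)
  if (!start_prior %in% priors)
    stop("'start_prior' must be one of: ", paste(priors, collapse = ", "),
         call. = FALSE)
  # alternate the prior across blocks, starting from start_prior
  rot <- c(priors[match(start_prior, priors):length(priors)],
           priors[seq_len(match(start_prior, priors) - 1L)])
  block_prior <- rep_len(rot, design$n_blocks)
  per_lk <- design$trials_per_block %/% length(lk)
  blocks <- lapply(seq_len(design$n_blocks), function(b) {
    lks <- sample(rep(lk, per_lk))
    data.frame(block = b,
               trial_index = seq_len(design$trials_per_block),
               prior = block_prior[b],
               likelihood = lks,
               stringsAsFactors = FALSE)
  })
  sched <- do.call(rbind, blocks)
  sched$prior_sd <- unname(design$prior_sds[sched$prior])
  sched$likelihood_sd <- unname(design$likelihood_sds[sched$likelihood])
  sched
}

#' Draw the stimuli for one or more trials
#'
#' The hidden target is drawn from the prior, the splash dots i.i.d. from
#' the likelihood centred on the target, and the net's initial position
#' uniformly on the screen. Stimuli are not truncated at the screen edges;
#' with the default SDs the off-screen mass is negligible.
#'
#' @param prior_sd,likelihood_sd Condition SDs (vectorised over trials).
#' @param design A [task_design()] (supplies prior mean and splash size).
#' @param n Number of trials to draw (default: length of `prior_sd`).
#' @return A list with `target` (length n), `splash` (n x n_samples
#'   matrix) and `net_init` (length n).
#' @export
sample_trial <- function(prior_sd, likelihood_sd, design = task_design(),
                         n = length(prior_sd)) {
  stopifnot(inherits(design, "task_design"))
  prior_sd <- rep_len(prior_sd, n)
  likelihood_sd <- rep_len(likelihood_sd, n)
  check_positive_sd(prior_sd, "prior_sd")
  check_positive_sd(likelihood_sd, "likelihood_sd")
  target <- stats::rnorm(n, design$prior_mean, prior_sd)
  k <- design$n_samples
  splash <- matrix(stats::rnorm(n * k, mean = rep(target, k),
                                sd = rep(likelihood_sd, k)),
                   nrow = n, ncol = k)
  list(target = target, splash = splash, net_init = stats::runif(n))
}

#' Simulate an observer's responses
#'
#' Non-lapse responses follow the linear readout
#' `w * centroid + (1 - w) * prior_mean + noise`, with `w` the observer's
#' reliance weight for the trial's condition. On lapse trials the subject
#' either leaves the net at its initial position or times out (no
#' response), according to the observer's `lapse_mode`.
#'
#' @param obs An [observer()].
#' @param splash n x n_samples matrix of splash positions.
#' @param net_init Initial net positions (used by `"net_init"` lapses).
#' @param condition Condition label per trial (as in
#'   `conditions(design)$condition`).
#' @param design A [task_design()].
#' @return Numeric vector of responses; `NA` marks a timeout.
#' @export
simulate_response <- function(obs, splash, net_init, condition,
                              design = task_design()) {
  stopifnot(inherits(obs, "observer"))
  cen <- splash_centroid(splash)
  n <- length(cen)
  w <- observer_weight(obs, condition)
  resp <- w * cen + (1 - w) * design$prior_mean +
    stats::rnorm(n, 0, obs$motor_noise_sd)
  if (obs$lapse_rate > 0) {
    lapse <- stats::runif(n) < obs$lapse_rate
    resp[lapse] <- if (obs$lapse_mode == "timeout") NA_real_ else
      net_init[lapse]
  }
  resp
}

#' Simulate one subject's full session
#'
#' Builds a blocked schedule, draws stimuli, and simulates responses,
#' returning the subject's trials as one data frame in the package's
#' trial-table layout.
#'
#' @param obs An [observer()].
#' @param design A [task_design()].
#' @param seed Integer seed for this subject's randomness.
#' @param start_prior Passed to [build_schedule()].
#' @return A trial data frame (one row per trial) with columns
#'   `subject_id`, `group`, `age`, `match_id`, `block`, `trial_index`,
#'   `prior`, `likelihood`, `prior_sd`, `likelihood_sd`, `target`,
#'   `splash_1..splash_n`, `net_init`, `response` (`NA` = timeout) and
#'   `caught`.
#' @export
simulate_subject <- function(obs, design = task_design(), seed = NULL,
                             start_prior = "random") {
  stopifnot(inherits(obs, "observer"))
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_rng(old), add = TRUE)
    set.seed(seed)
  }
  sched <- build_schedule(design, start_prior = start_prior)
  stim <- sample_trial(sched$prior_sd, sched$likelihood_sd, design)
  condition <- paste(sched$prior, sched$likelihood, sep = "-")
  resp <- simulate_response(obs, stim$splash, stim$net_init, condition,
                            design)
  splash <- stim$splash
  colnames(splash) <- paste0("splash_", seq_len(ncol(splash)))
  out <- data.frame(subject_id = obs$subject_id,
                    group = obs$group,
                    age = obs$age,
                    match_id = obs$match_id,
                    sched[, c("block", "trial_index", "prior", "likelihood",
                              "prior_sd", "likelihood_sd")],
                    target = stim$target,
                    splash,
                    net_init = stim$net_init,
                    response = resp,
                    stringsAsFactors = FALSE)
  out$caught <- ifelse(is.na(out$response), NA,
                       abs(out$response - out$target) <= design$net_halfwidth)
  rownames(out) <- NULL
  out
}

#' Specification of an observer group's parameter distribution
#'
#' Describes how a group's observers are drawn. Each subject receives a
#' reliance level `b` ~ N(`weight_scale`, `weight_scale_sd`) (truncated to
#' [0, 1.25]). Under the default `"scaled_optimal"` rule the subject's
#' weight in each condition is `clamp(b * optimal + jitter, 0, 1)` — a
#' Bayesian subject whose reliance tracks the condition's uncertainties;
#' under `"constant"` the weight is `clamp(b + jitter, 0, 1)` in every
#' condition — a heuristic subject that ignores the condition. Jitter is
#' independent per condition, ~ N(0, `weight_jitter_sd`). Motor-noise SDs
#' are |N(`motor_noise_mean`, `motor_noise_sd_sd`)|; lapse rates are
#' fixed at `lapse_rate`. Setting both SD hyperparameters and the jitter
#' to zero gives identical observers.
#'
#' @param weight_scale Mean reliance level (a multiplier on the optimal
#'   weight for `"scaled_optimal"`, the weight itself for `"constant"`).
#' @param weight_scale_sd Between-subject SD of that level.
#' @param weight_jitter_sd Per-condition weight jitter SD.
#' @param motor_noise_mean,motor_noise_sd_sd Motor-noise distribution.
#' @param lapse_rate,lapse_mode Lapse behaviour (see [observer()]).
#' @param weight_rule `"scaled_optimal"` or `"constant"` (see above).
#' @return A list of class `group_spec`.
#' @export
group_spec <- function(weight_scale = 0.9, weight_scale_sd = 0.15,
                       weight_jitter_sd = 0.05,
                       motor_noise_mean = 0.04, motor_noise_sd_sd = 0.01,
                       lapse_rate = 0.05,
                       lapse_mode = c("net_init", "timeout"),
                       weight_rule = c("scaled_optimal", "constant")) {
  lapse_mode <- match.arg(lapse_mode)
  weight_rule <- match.arg(weight_rule)
  spec <- list(weight_scale = weight_scale,
               weight_scale_sd = weight_scale_sd,
               weight_jitter_sd = weight_jitter_sd,
               motor_noise_mean = motor_noise_mean,
               motor_noise_sd_sd = motor_noise_sd_sd,
               lapse_rate = lapse_rate,
               lapse_mode = lapse_mode,
               weight_rule = weight_rule)
  bad <- names(spec)[!vapply(spec[1:6], function(x)
    is.numeric(x) && length(x) == 1L && is.finite(x), logical(1))]
  if (length(bad))
    stop("invalid group_spec fields: ", paste(bad, collapse = ", "),
         call. = FALSE)
  class(spec) <- "group_spec"
  spec
}

clamp01 <- function(x) pmin(1, pmax(0, x))

# Deterministic, extendable per-subject seed stream: subject k of a cohort
# always receives the same seed for a given master seed, so adding subjects
# never reshuffles existing ones.
subject_seed <- function(master_seed, k) {
  as.integer((as.numeric(master_seed) %% 2^31 + 97561 * k) %% (2^31 - 1)) + 1L
}

#' Simulate an age-matched two-group cohort
#'
#' Draws `n_per_group` observers per group from the group specifications,
#' age-matches each patient with a control (equal ages, shared
#' `match_id`), simulates every subject's full session, and returns the
#' pooled trial table. The default group parameters emulate the study
#' population: 9 children with cerebral palsy (CP) and 9 age-matched
#' typically-developing (TD) controls, ages ~ N(8.22, 1.80) years, with CP
#' subjects relying somewhat less on the likelihood, carrying more motor
#' noise and lapsing more often.
#'
#' All randomness is derived from `seed`; each subject gets a private seed
#' from a deterministic counter, so enlarging the cohort leaves existing
#' subjects' data unchanged.
#'
#' @param n_per_group Subjects per group.
#' @param design A [task_design()].
#' @param cp_spec,td_spec [group_spec()]s for the two groups.
#' @param age_mean,age_sd Age distribution (years) for the matched pairs.
#' @param seed Master integer seed.
#' @return A trial data frame (rows = subjects x trials, columns as in
#'   [simulate_subject()]), with attribute `"manifest"`: a data frame of
#'   each observer's ground-truth parameters (one row per subject x
#'   condition, with `weight_true`, `motor_noise_sd`, `lapse_rate`) for
#'   recovery tests, and attribute `"design"`.
#' @examples
#' trials <- simulate_cohort(n_per_group = 2, seed = 1)
#' nrow(trials)  # 4 subjects x 480 trials
#' @export
simulate_cohort <- function(n_per_group = 9,
                            design = task_design(),
                            cp_spec = group_spec(weight_scale = 0.7,
                                                 motor_noise_mean = 0.06,
                                                 lapse_rate = 0.08),
                            td_spec = group_spec(weight_scale = 0.9,
                                                 motor_noise_mean = 0.04,
                                                 lapse_rate = 0.03),
                            age_mean = 8.22, age_sd = 1.80,
                            seed = 1L) {
  stopifnot(inherits(design, "task_design"))
  n_per_group <- as.integer(n_per_group)
  if (is.na(n_per_group) || n_per_group < 1L)
    stop("'n_per_group' must be >= 1", call. = FALSE)
  for (sp in list(cp_spec, td_spec))
    if (!inherits(sp, "group_spec"))
      stop("group specifications must be built with group_spec()",
           call. = FALSE)
  cond <- conditions(design)
  specs <- list(CP = cp_spec, TD = td_spec)
  all_trials <- vector("list", 2L * n_per_group)
  manifest <- vector("list", 2L * n_per_group)
  idx <- 0L
  for (k in seq_len(n_per_group)) {
    # one age per matched pair, drawn from the pair's own seed stream
    set.seed(subject_seed(seed, 10000L + k))
    age <- round(pmin(12, pmax(5, stats::rnorm(1, age_mean, age_sd))))
    for (g in c("CP", "TD")) {
      idx <- idx + 1L
      sp <- specs[[g]]
      sseed <- subject_seed(seed, idx)
      set.seed(sseed)
      b <- pmin(1.25, pmax(0, stats::rnorm(1, sp$weight_scale,
                                           sp$weight_scale_sd)))
      base_w <- if (identical(sp$weight_rule, "constant"))
        rep(b, nrow(cond)) else b * cond$optimal
      w <- clamp01(base_w + stats::rnorm(nrow(cond), 0,
                                         sp$weight_jitter_sd))
      names(w) <- cond$condition
      noise <- abs(stats::rnorm(1, sp$motor_noise_mean, sp$motor_noise_sd_sd))
      obs <- observer(subject_id = sprintf("%s%02d", g, k),
                      group = g, age = age, weights = w,
                      motor_noise_sd = noise, lapse_rate = sp$lapse_rate,
                      lapse_mode = sp$lapse_mode,
                      match_id = sprintf("pair%02d", k))
      all_trials[[idx]] <- simulate_subject(obs, design,
                                            seed = subject_seed(seed, 20000L + idx))
      manifest[[idx]] <- data.frame(subject_id = obs$subject_id,
                                    group = g, age = age,
                                    match_id = obs$match_id,
                                    condition = cond$condition,
                                    weight_true = unname(w),
                                    motor_noise_sd = noise,
                                    lapse_rate = sp$lapse_rate,
                                    lapse_mode = sp$lapse_mode,
                                    stringsAsFactors = FALSE)
    }
  }
  trials <- do.call(rbind, all_trials)
  rownames(trials) <- NULL
  attr(trials, "manifest") <- do.call(rbind, manifest)
  attr(trials, "design") <- design
  trials
}
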