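#' Simulation configuration
#'
#' Bundles the generating parameters of the trial simulator. Defaults are
#' plausible values loosely matched to the aggregate statistics the
#' transsaccadic experiment reports (a grand median saccadic latency near
#' 213 ms, roughly 15% of trials lost to censoring, reaction-time condition
#' effects of a few tens of ms, near-ceiling accuracy); they are configuration,
#' not empirical claims.
#'
#' Saccadic latencies follow a shifted lognormal (right-skewed, as latency
#' distributions are), with an additive per-condition shift. Landing positions
#' are 2D normal with a condition-dependent horizontal undershoot bias and
#' isotropic spread. Manual reaction times are lognormal plus an additive
#' per-condition effect (ms), a linear dependence on landing error, and a
#' refixation penalty on trials whose target localization required a slow
#' second additional saccade. Correctness is Bernoulli on a logit scale with
#' per-condition offsets.
#'
#' @param n_subjects Number of subjects (default 7).
#' @param trials_per_condition Trials per subject and condition (default 100).
#' @param latency_shift_base_ms Shift of the shifted-lognormal latency (ms).
#' @param latency_mu_log,latency_sigma_log Lognormal latency parameters.
#' @param latency_shift_ms Named per-condition additive latency shifts (ms).
#' @param saccade_duration_mean_ms,saccade_duration_sd_ms Saccade duration
#'   normal parameters (ms, truncated at 20).
#' @param landing_bias_deg Named per-condition horizontal undershoot bias
#'   (deg; applied as a negative x offset).
#' @param landing_sd_deg Named per-condition isotropic landing sd (deg).
#' @param rt_mu_log,rt_sigma_log Lognormal base reaction-time parameters.
#' @param condition_effect_ms Named per-condition additive RT effects (ms).
#' @param landing_slope_ms_per_deg Linear RT dependence on landing error.
#' @param p_extra_saccades Probabilities of 0, 1, 2, 3 additional saccades
#'   (must sum to 1).
#' @param final_fixation_mu_log,final_fixation_sigma_log Lognormal final
#'   fixation duration parameters.
#' @param slow_refix_penalty_ms Extra RT on trials with two additional
#'   saccades and a final fixation at or above 240 ms, or more than two
#'   additional saccades.
#' @param initial_fixation_mean_ms,initial_fixation_sd_ms Initial postsaccadic
#'   fixation duration normal parameters.
#' @param accuracy_logit Named vector: `intercept` plus per-condition
#'   log-odds offsets for a correct response.
#' @param intrafixation When `TRUE`, emulates the fixation-control experiment:
#'   exposure durations replace latencies, landing structure and condition RT
#'   effects are zeroed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(
    n_subjects = 7,
    trials_per_condition = 100,
    latency_shift_base_ms = 157,
    latency_mu_log = log(53), latency_sigma_log = 0.68,
    latency_shift_ms = c(uniform = 7, random = 7, localized = 0,
                         same = 0, different = 0),
    saccade_duration_mean_ms = 48, saccade_duration_sd_ms = 10,
    landing_bias_deg = c(uniform = 0.15, random = 0.15, localized = 0.05,
                         same = 0.04, different = 0.04),
    landing_sd_deg = c(uniform = 0.50, random = 0.48, localized = 0.35,
                       same = 0.33, different = 0.33),
    rt_mu_log = log(600), rt_sigma_log = 0.25,
    condition_effect_ms = c(uniform = 12, random = 12, localized = 0,
                            same = -16, different = 19),
    landing_slope_ms_per_deg = 40,
    p_extra_saccades = c(`0` = 0.007, `1` = 0.703, `2` = 0.263, `3` = 0.027),
    final_fixation_mu_log = log(230), final_fixation_sigma_log = 0.35,
    slow_refix_penalty_ms = 190,
    initial_fixation_mean_ms = 210, initial_fixation_sd_ms = 40,
    accuracy_logit = c(intercept = 3.2, uniform = 0, random = 0,
                       localized = 0, same = 1.4, different = 0),
    intrafixation = FALSE) {
  cfg <- as.list(environment())
  conds <- sim_conditions()
  for (nm in c("latency_shift_ms", "landing_bias_deg", "landing_sd_deg",
               "condition_effect_ms")) {
    if (!all(conds %in% names(cfg[[nm]]))) {
      stop(nm, " must name all five conditions")
    }
  }
  if (abs(sum(p_extra_saccades) - 1) > 1e-8 || any(p_extra_saccades < 0)) {
    stop("p_extra_saccades must be a probability vector summing to 1")
  }
  if (any(c(landing_sd_deg, latency_sigma_log, rt_sigma_log) <= 0)) {
    stop("spread parameters must be positive")
  }
  structure(cfg, class = "sim_config")
}

sim_conditions <- function() {
  c("uniform", "random", "localized", "same", "different")
}

#' Simulate a transsaccadic grouping experiment
#'
#' Generates one trial table with the statistical structure the analysis
#' pipeline assumes (see [sim_config()]). Fully reproducible under `seed`.
#'
#' @param config A `sim_config`.
#' @param seed Optional integer seed.
#' @return A tibble with one row per trial and the full trial-record schema:
#'   `subject_id`, `trial_id`, `condition`, `stimulus_id`, `postsac_stimulus`,
#'   `target_class`, `saccade_latency_ms`, `saccade_duration_ms`,
#'   `landing_x_deg`, `landing_y_deg`, `n_additional_saccades`,
#'   `final_fixation_ms`, `initial_postsac_fixation_ms`, `rt_ms`, `response`,
#'   `correct`.
#' @examples
#' trials <- simulate_experiment(sim_config(n_subjects = 2,
#'                                          trials_per_condition = 10),
#'                               seed = 1)
#' dplyr::count(trials, condition)
#' @export
simulate_experiment <- function(config = sim_config(), seed = NULL) {
  if (!is.null(seed)) {
    return(withr::with_seed(seed, simulate_experiment(config, seed = NULL)))
  }
  stopifnot(inherits(config, "sim_config"))
  conds <- sim_conditions()
  n <- config$n_subjects * length(conds) * config$trials_per_condition
  tr <- tidyr::expand_grid(
    subject_id = seq_len(config$n_subjects),
    condition = conds,
    rep = seq_len(config$trials_per_condition)
  )
  tr <- dplyr::mutate(
    dplyr::group_by(tr, .data$subject_id),
    trial_id = sample(dplyr::n())
  )
  tr <- dplyr::arrange(dplyr::ungroup(tr), .data$subject_id, .data$trial_id)
  cond <- tr$condition

  intrafix <- isTRUE(config$intrafixation)
  latency <- if (intrafix) {
    stats::runif(n, 175, 275)
  } else {
    config$latency_shift_base_ms + config$latency_shift_ms[cond] +
      exp(stats::rnorm(n, config$latency_mu_log, config$latency_sigma_log))
  }
  duration <- if (intrafix) rep(0, n) else {
    pmax(20, stats::rnorm(n, config$saccade_duration_mean_ms,
                          config$saccade_duration_sd_ms))
  }
  landing_x <- if (intrafix) rep(0, n) else {
    stats::rnorm(n, -config$landing_bias_deg[cond],
                 config$landing_sd_deg[cond])
  }
  landing_y <- if (intrafix) rep(0, n) else {
    stats::rnorm(n, 0, config$landing_sd_deg[cond])
  }
  landing_err <- sqrt(landing_x^2 + landing_y^2)
  n_extra <- if (intrafix) rep(0L, n) else {
    sample(as.integer(names(config$p_extra_saccades)), n, replace = TRUE,
           prob = config$p_extra_saccades)
  }
  final_fix <- exp(stats::rnorm(n, config$final_fixation_mu_log,
                                config$final_fixation_sigma_log))
  slow_refix <- (n_extra == 2 & final_fix >= 240) | n_extra > 2
  cond_eff <- if (intrafix) rep(0, n) else config$condition_effect_ms[cond]
  rt <- exp(stats::rnorm(n, config$rt_mu_log, config$rt_sigma_log)) +
    cond_eff + config$landing_slope_ms_per_deg * landing_err +
    config$slow_refix_penalty_ms * slow_refix
  acc_logit <- unname(config$accuracy_logit["intercept"]) +
    (if (intrafix) 0 else unname(config$accuracy_logit[cond]))
  correct <- stats::runif(n) < stats::plogis(acc_logit)
  target_class <- sample(c("inside_both", "outside_both", "mixed"), n,
                         replace = TRUE, prob = c(0.25, 0.25, 0.5))
  true_side <- dplyr::case_when(
    target_class == "inside_both" ~ "in",
    target_class == "outside_both" ~ "out",
    .default = sample(c("in", "out"), n, replace = TRUE)
  )
  tibble::tibble(
    subject_id = tr$subject_id,
    trial_id = tr$trial_id,
    condition = cond,
    stimulus_id = sample(80, n, replace = TRUE),
    postsac_stimulus = sample(1:2, n, replace = TRUE),
    target_class = target_class,
    saccade_latency_ms = as.numeric(latency),
    saccade_duration_ms = as.numeric(duration),
    landing_x_deg = as.numeric(landing_x),
    landing_y_deg = as.numeric(landing_y),
    n_additional_saccades = as.integer(n_extra),
    final_fixation_ms = as.numeric(final_fix),
    initial_postsac_fixation_ms = pmax(50, stats::rnorm(
      n, config$initial_fixation_mean_ms, config$initial_fixation_sd_ms
    )),
    rt_ms = as.numeric(rt),
    response = unname(ifelse(correct, true_side,
                             ifelse(true_side == "in", "out", "in"))),
    correct = unname(correct)
  )
}

trial_schema <- function() {
  c("subject_id", "trial_id", "condition", "stimulus_id", "postsac_stimulus",
    "target_class", "saccade_latency_ms", "saccade_duration_ms",
    "landing_x_deg", "landing_y_deg", "n_additional_saccades",
    "final_fixation_ms", "initial_postsac_fixation_ms", "rt_ms", "response",
    "correct")
}

#' Write a trial table to CSV
#'
#' @param trials A trial tibble with the full schema (extra columns allowed).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  check_trial_schema(trials)
  readr::write_csv(trials, path)
  invisible(path)
}

#' Read a trial table from CSV
#'
#' Validates the mandatory trial-record columns; unknown columns are
#' preserved.
#'
#' @param path CSV path written by [write_trials()] (or schema-compatible).
#' @return A trial tibble.
#' @export
read_trials <- function(path) {
  tr <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_trial_schema(tr)
  tr$n_additional_saccades <- as.integer(tr$n_additional_saccades)
  tr$correct <- as.logical(tr$correct)
  tr
}

check_trial_schema <- function(trials) {
  missing <- setdiff(trial_schema(), names(trials))
  if (length(missing) > 0) {
    stop("trial table is missing mandatory column(s): ",
         paste(missing, collapse = ", "))
  }
  invisible(trials)
}

#' Flag response-coding inconsistencies
#'
#' For unambiguous target classes (`inside_both`, `outside_both`) the recorded
#' correctness must equal `response == true side`; rows violating this are
#' returned. `mixed` targets cannot be validated without the per-trial
#' displayed contour and are skipped.
#'
#' @param trials A trial tibble.
#' @return The subset of rows with inconsistent coding.
#' @export
check_response_consistency <- function(trials) {
  check_trial_schema(trials)
  side <- dplyr::case_when(
    trials$target_class == "inside_both" ~ "in",
    trials$target_class == "outside_both" ~ "out",
    .default = NA_character_
  )
  bad <- !is.na(side) & ((trials$response == side) != trials$correct)
  trials[bad, ]
}
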