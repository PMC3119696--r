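#' Censor trials on saccade execution quality
#'
#' Removes trials whose main saccade was executed poorly: a landing position
#' more than 1.5 degrees (Euclidean) from the stimulus center, or a saccade
#' duration above 85 ms. Boundary values (exactly 1.5 degrees or 85 ms) are
#' retained; the rules are strict inequalities.
#'
#' @param trials A trial tibble with `landing_x_deg`, `landing_y_deg` and
#'   `saccade_duration_ms`.
#' @param landing_cutoff_deg Landing distance cutoff (default 1.5).
#' @param duration_cutoff_ms Saccade duration cutoff (default 85).
#' @return The retained trials, with a `censor_report` attribute (see
#'   [censor_report()]).
#' @export
censor_saccade_execution <- function(trials, landing_cutoff_deg = 1.5,
                                     duration_cutoff_ms = 85) {
  need <- c("landing_x_deg", "landing_y_deg", "saccade_duration_ms")
  missing <- setdiff(need, names(trials))
  if (length(missing) > 0) {
    stop("missing field(s): ", paste(missing, collapse = ", "))
  }
  dist <- sqrt(trials$landing_x_deg^2 + trials$landing_y_deg^2)
  bad_landing <- dist > landing_cutoff_deg
  bad_duration <- trials$saccade_duration_ms > duration_cutoff_ms
  out <- trials[!(bad_landing | bad_duration), , drop = FALSE]
  attr(out, "censor_report") <- make_censor_report(
    trials, out,
    c(landing = sum(bad_landing),
      duration = sum(bad_duration & !bad_landing))
  )
  out
}

#' Censor trials on target localization difficulty
#'
#' Removes trials where the target square was apparently hard to find after
#' the main saccade: more than two additional saccades, or exactly two
#' additional saccades with a final fixation duration at or above the cutoff
#' (240 ms by default — trials below it are taken to have generated the
#' manual response without actually requiring the second additional saccade).
#'
#' @param trials A trial tibble with `n_additional_saccades` and
#'   `final_fixation_ms`.
#' @param fixation_cutoff_ms Final-fixation cutoff in ms (default 240); the
#'   rule is `>=`.
#' @return The retained trials, with a `censor_report` attribute.
#' @export
censor_target_localization <- function(trials, fixation_cutoff_ms = 240) {
  need <- c("n_additional_saccades", "final_fixation_ms")
  missing <- setdiff(need, names(trials))
  if (length(missing) > 0) {
    stop("missing field(s): ", paste(missing, collapse = ", "))
  }
  if (any(trials$n_additional_saccades < 0)) {
    stop("negative additional-saccade counts")
  }
  extra <- trials$n_additional_saccades
  too_many <- extra > 2
  slow_second <- extra == 2 & trials$final_fixation_ms >= fixation_cutoff_ms
  out <- trials[!(too_many | slow_second), , drop = FALSE]
  attr(out, "censor_report") <- make_censor_report(
    trials, out,
    c(extra_saccades = sum(too_many),
      slow_second_fixation = sum(slow_second))
  )
  out
}

make_censor_report <- function(input, retained, removed) {
  comp <- if ("condition" %in% names(retained) && nrow(retained) > 0) {
    tab <- table(retained$condition)
    tibble::tibble(condition = names(tab),
                   proportion = as.numeric(tab) / nrow(retained))
  } else {
    tibble::tibble(condition = character(0), proportion = numeric(0))
  }
  structure(
    list(
      n_input = nrow(input),
      n_removed = removed,
      n_retained = nrow(retained),
      retained_fraction = nrow(retained) / max(1, nrow(input)),
      condition_composition = comp
    ),
    class = "censor_report"
  )
}

#' Extract a censoring report
#'
#' @param trials A trial tibble returned by one of the censor functions.
#' @return The `censor_report` attached to it (or `NULL`).
#' @export
censor_report <- function(trials) attr(trials, "censor_report")

#' @export
print.censor_report <- function(x, ...) {
  cat(sprintf("<censor_report: %d in, %d retained (%.2f%%); removed: %s>\n",
              x$n_input, x$n_retained, 100 * x$retained_fraction,
              paste(names(x$n_removed), x$n_removed, sep = "=",
                    collapse = ", ")))
  invisible(x)
}

#' Apply both censoring stages
#'
#' Saccade-execution and target-localization censoring composed; the two
#' stages are order-invariant. The combined report is attached as attribute
#' `"censor_report"`.
#'
#' @param trials A trial tibble.
#' @param fixation_cutoff_ms Final-fixation cutoff (default 240).
#' @return The retained trials with a combined `censor_report` attribute.
#' @export
censor_trials <- function(trials, fixation_cutoff_ms = 240) {
  s1 <- censor_saccade_execution(trials)
  r1 <- censor_report(s1)
  s2 <- censor_target_localization(s1, fixation_cutoff_ms)
  r2 <- censor_report(s2)
  attr(s2, "censor_report") <- make_censor_report(
    trials, s2, c(r1$n_removed, r2$n_removed)
  )
  s2
}

#' Derive the final-fixation censoring cutoff from the data
#'
#' Searches the observed final-fixation durations of trials with exactly two
#' additional saccades for the cutoff c that makes the median total reaction
#' time of fast-refixation trials (fixation < c) equal to the median of
#' trials with a single additional saccade — i.e. minimizes the absolute
#' difference between the two medians. Ties resolve to the smallest cutoff.
#'
#' @param trials A trial tibble with `n_additional_saccades`,
#'   `final_fixation_ms` and `rt_ms`.
#' @return The derived cutoff in ms.
#' @export
derive_fixation_cutoff <- function(trials) {
  extra <- trials$n_additional_saccades
  if (!any(extra == 2)) stop("no trials with exactly two additional saccades")
  rt_one <- trials$rt_ms[extra == 1]
  if (length(rt_one) == 0) stop("no trials with one additional saccade")
  med_one <- stats::median(rt_one)
  fix2 <- trials$final_fixation_ms[extra == 2]
  rt2 <- trials$rt_ms[extra == 2]
  ord <- order(fix2)
  fix2 <- fix2[ord]; rt2 <- rt2[ord]
  candidates <- unique(fix2)
  obj <- vapply(candidates, function(cc) {
    sel <- fix2 < cc
    if (!any(sel)) return(Inf)
    abs(stats::median(rt2[sel]) - med_one)
  }, numeric(1))
  candidates[which.min(obj)] # which.min takes the first: smallest cutoff
}

#' Screen stimulus sets from pilot data
#'
#' Reproduces the pilot screening of candidate stimulus sets: reaction times
#' are z-scored within subject (correct responses only), pooled per stimulus
#' display across subjects, and a set is removed when any of its displays has
#' a mean normalized reaction time outside +/- `rt_band` around the overall
#' mean of display means, or when the set's accuracy falls below
#' `min_accuracy`.
#'
#' @param pilot_trials A trial tibble with `stimulus_id`, `postsac_stimulus`,
#'   `subject_id`, `rt_ms` and `correct`.
#' @param rt_band Allowed deviation of a display's mean normalized RT
#'   (default 0.6).
#' @param min_accuracy Minimum proportion correct per set (default 0.75).
#' @return Integer vector of retained `stimulus_id`s.
#' @export
screen_stimulus_sets <- function(pilot_trials, rt_band = 0.6,
                                 min_accuracy = 0.75) {
  tr <- pilot_trials
  acc <- dplyr::summarise(dplyr::group_by(tr, .data$stimulus_id),
                          accuracy = mean(.data$correct))
  rts <- dplyr::filter(tr, .data$correct)
  rts <- dplyr::group_by(rts, .data$subject_id)
  if (any(dplyr::summarise(rts, s = stats::sd(.data$rt_ms))$s == 0)) {
    stop("a subject has zero reaction-time variance; cannot normalize")
  }
  rts <- dplyr::mutate(rts, z = as.numeric(scale(.data$rt_ms)))
  disp <- dplyr::summarise(
    dplyr::group_by(dplyr::ungroup(rts), .data$stimulus_id,
                    .data$postsac_stimulus),
    mean_z = mean(.data$z), .groups = "drop"
  )
  grand <- mean(disp$mean_z)
  bad_rt <- unique(disp$stimulus_id[abs(disp$mean_z - grand) > rt_band])
  bad_acc <- acc$stimulus_id[acc$accuracy < min_accuracy]
  sort(setdiff(unique(tr$stimulus_id), union(bad_rt, bad_acc)))
}
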