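strip_report <- function(x) {
  attr(x, "censor_report") <- NULL
  tibble::as_tibble(x)
}

toy_trials <- function(landing = 0.2, duration = 40, extra = 1, fix = 100,
                       rt = 600, n = length(landing)) {
  tibble::tibble(
    condition = rep("uniform", n),
    landing_x_deg = rep_len(landing, n),
    landing_y_deg = 0,
    saccade_duration_ms = rep_len(duration, n),
    n_additional_saccades = rep_len(as.integer(extra), n),
    final_fixation_ms = rep_len(fix, n),
    rt_ms = rep_len(rt, n)
  )
}

test_that("saccade-execution censoring applies strict boundary rules", {
  tr <- toy_trials(landing = c(0.2, 1.6, 0.4, 1.51, 0.9, 1.5), duration = 40)
  out <- censor_saccade_execution(tr)
  expect_identical(nrow(out), 4L) # 1.5 is not > 1.5
  expect_equal(out$landing_x_deg, c(0.2, 0.4, 0.9, 1.5))
  rep <- censor_report(out)
  expect_identical(unname(rep$n_removed["landing"]), 2L)
  expect_identical(rep$n_input - sum(rep$n_removed), rep$n_retained)
  # duration rule, also strict
  tr2 <- toy_trials(landing = 0.1, duration = c(85, 85.1, 40), n = 3)
  expect_identical(nrow(censor_saccade_execution(tr2)), 2L)
  # empty and all-compliant tables
  expect_identical(nrow(censor_saccade_execution(tr[0, ])), 0L)
  clean <- toy_trials(landing = c(0.1, 0.3), n = 2)
  expect_equal(strip_report(censor_saccade_execution(clean)), clean)
  expect_error(censor_saccade_execution(dplyr::select(tr, -landing_x_deg)),
               "landing_x_deg")
})

test_that("target-localization censoring applies the 240 ms rule", {
  tr <- toy_trials(extra = c(1, 2, 2, 3), fix = c(300, 239, 240, 100), n = 4)
  out <- censor_target_localization(tr)
  expect_identical(nrow(out), 2L)
  expect_equal(out$final_fixation_ms, c(300, 239)) # >= 240 removes boundary
  # all single-extra trials pass untouched
  ones <- toy_trials(extra = 1, fix = 500, n = 5)
  expect_identical(nrow(censor_target_localization(ones)), 5L)
  # infinite cutoff: only the > 2 rule applies
  expect_identical(nrow(censor_target_localization(tr, Inf)), 3L)
  expect_error(censor_target_localization(toy_trials(extra = -1)),
               "negative")
})

test_that("censoring is idempotent and order-invariant", {
  tr <- simulate_experiment(sim_config(n_subjects = 3,
                                       trials_per_condition = 100), seed = 31)
  ab <- censor_target_localization(censor_saccade_execution(tr))
  ba <- censor_saccade_execution(censor_target_localization(tr))
  expect_equal(strip_report(ab), strip_report(ba))
  again <- censor_target_localization(censor_saccade_execution(ab))
  expect_equal(strip_report(again), strip_report(ab))
  both <- censor_trials(tr)
  expect_equal(strip_report(both), strip_report(ab))
  rep <- censor_report(both)
  expect_identical(rep$n_input, nrow(tr))
  expect_equal(sum(rep$condition_composition$proportion), 1)
})

test_that("default simulator settings land in the retention band", {
  tr <- simulate_experiment(sim_config(), seed = 13)
  rep <- censor_report(censor_trials(tr))
  expect_gte(rep$retained_fraction, 0.80)
  expect_lte(rep$retained_fraction, 0.90)
})

test_that("the fixation cutoff recovers a planted changepoint", {
  # fixation durations sit on a 5 ms grid, so "one observed-value step" is
  # 5 ms. Below the changepoint two-extra RTs drift mildly with fixation
  # duration, calibrated so the median of trials with fix < 240 equals the
  # one-extra median exactly; at or above 240 they are 400 ms slower. The
  # expected objective is then V-shaped with its vertex at 240.
  withr::with_seed(17, {
    n1 <- 4000; n2 <- 16000
    grid <- seq(100, 395, by = 5)
    fix_med <- stats::median(grid[grid < 240]) # 167.5
    rt1 <- stats::rnorm(n1, 650, 20)
    fix2 <- sample(grid, n2, replace = TRUE)
    rt2 <- stats::rnorm(n2, 650, 20) + 2 * (fix2 - fix_med) +
      400 * (fix2 >= 240)
    tr <- tibble::tibble(
      n_additional_saccades = c(rep(1L, n1), rep(2L, n2)),
      final_fixation_ms = c(sample(grid, n1, replace = TRUE), fix2),
      rt_ms = c(rt1, rt2)
    )
  })
  cutoff <- derive_fixation_cutoff(tr)
  expect_lte(abs(cutoff - 240), 5) # within one observed-value step
  # brute-force objective scan oracle
  fix_sorted <- sort(unique(tr$final_fixation_ms[tr$n_additional_saccades == 2]))
  med1 <- stats::median(tr$rt_ms[tr$n_additional_saccades == 1])
  objective <- vapply(fix_sorted, function(cc) {
    sel <- tr$n_additional_saccades == 2 & tr$final_fixation_ms < cc
    if (!any(sel)) return(Inf)
    abs(stats::median(tr$rt_ms[sel]) - med1)
  }, numeric(1))
  expect_identical(cutoff, fix_sorted[which.min(objective)])
})

test_that("degenerate cutoff searches resolve by the tie rule", {
  # identical RT distributions: any cutoff works, smallest returned
  tr <- tibble::tibble(
    n_additional_saccades = rep(c(1L, 2L), each = 50),
    final_fixation_ms = rep(seq(100, 345, by = 5), 2)[1:100],
    rt_ms = rep(600, 100)
  )
  fix2 <- sort(unique(tr$final_fixation_ms[tr$n_additional_saccades == 2]))
  expect_identical(derive_fixation_cutoff(tr), fix2[2]) # smallest usable
  # monotone case: all two-extra trials slower; smallest usable cutoff wins
  tr2 <- tr
  tr2$rt_ms[tr2$n_additional_saccades == 2] <- 1100
  expect_identical(derive_fixation_cutoff(tr2), fix2[2])
  expect_error(derive_fixation_cutoff(toy_trials(extra = 1, n = 3)),
               "two additional")
})

test_that("stimulus-set screening removes inaccurate and deviant sets", {
  mk_pilot <- function() {
    tidyr::expand_grid(
      subject_id = 1:4, stimulus_id = 1:10, postsac_stimulus = 1:2,
      rep = 1:5
    )
  }
  withr::with_seed(41, {
    pt <- mk_pilot()
    pt$rt_ms <- stats::rlnorm(nrow(pt), log(600), 0.2)
    pt$correct <- TRUE
    # set 3: only 70% correct
    idx3 <- which(pt$stimulus_id == 3)
    pt$correct[sample(idx3, round(0.3 * length(idx3)))] <- FALSE
    # set 7, display 1: shift RTs far upward
    idx7 <- which(pt$stimulus_id == 7 & pt$postsac_stimulus == 1)
    pt$rt_ms[idx7] <- pt$rt_ms[idx7] * 3
  })
  kept <- screen_stimulus_sets(pt)
  expect_false(3 %in% kept)
  expect_false(7 %in% kept)
  expect_true(all(setdiff(1:10, c(3, 7)) %in% kept))
  # identical sets are all retained
  pt2 <- mk_pilot()
  pt2$rt_ms <- rep(c(500, 600, 700, 800), length.out = nrow(pt2))
  pt2$correct <- TRUE
  expect_identical(screen_stimulus_sets(pt2), 1:10)
  # zero-variance subject errors
  pt3 <- pt2
  pt3$rt_ms[pt3$subject_id == 2] <- 600
  expect_error(screen_stimulus_sets(pt3), "zero")
})
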