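test_that("landing adjustment removes a log-linear landing effect exactly", {
  # log-linear construction: log RT = log(500) + 0.1 d, no noise
  withr::with_seed(4, {
    d <- stats::runif(400, 0, 1.5)
    tr <- tibble::tibble(
      subject_id = rep(1:2, each = 200),
      rt_ms = exp(log(500) + 0.1 * d),
      landing_x_deg = d, landing_y_deg = 0
    )
  })
  adj <- adjust_rt_for_landing(tr)
  expect_equal(attr(adj, "landing_slope"), 0.1, tolerance = 1e-8)
  expect_equal(adj$adj_log_rt, rep(log(500), 400), tolerance = 1e-8)
  # slope-zero data: log-RTs unchanged
  tr0 <- dplyr::mutate(tr, rt_ms = 500)
  adj0 <- adjust_rt_for_landing(tr0)
  expect_equal(adj0$adj_log_rt, log(tr0$rt_ms), tolerance = 1e-10)
  expect_error(adjust_rt_for_landing(dplyr::mutate(tr, landing_x_deg = 1,
                                                   landing_y_deg = 0)),
               "zero variance")
})

test_that("adjusted log-RT decorrelates from landing distance on simulation", {
  cfg <- sim_config(n_subjects = 4, trials_per_condition = 500)
  tr <- simulate_experiment(cfg, seed = 44)
  adj <- adjust_rt_for_landing(tr)
  r <- stats::cor(adj$adj_log_rt, adj$landing_dist_deg)
  expect_lt(abs(r), 0.03)
})

test_that("condition contrasts reproduce the repeated-measures shape", {
  tr <- simulate_experiment(sim_config(), seed = 6) # 7 subjects
  adj <- adjust_rt_for_landing(dplyr::filter(censor_trials(tr), correct,
                                             rt_ms <= 1500))
  eff <- condition_contrasts(adj)
  expect_identical(eff$omnibus$df1, 4L)
  expect_identical(eff$omnibus$df2, 24L) # (5-1)(7-1): the F(4,24) design shape
  expect_identical(nrow(tidy(eff)), 5L)
  expect_identical(tidy(eff)$df2, rep(24L, 5))
  g <- glance(eff)
  expect_true(all(c("F", "df1", "df2", "p", "ms_error") %in% names(g)))
  # a missing cell errors informatively
  broken <- dplyr::filter(adj, !(subject_id == 3 & condition == "same"))
  expect_error(condition_contrasts(broken), "3/same")
  expect_error(condition_contrasts(dplyr::filter(adj, subject_id == 1)),
               "2 subjects")
})

test_that("identical data in all conditions gives zero contrasts", {
  base <- tidyr::expand_grid(subject_id = 1:4, condition = sim_conditions(),
                             rep = 1:10)
  base$adj_log_rt <- rep(log(c(550, 600, 650, 700, 750)),
                         length.out = nrow(base))
  # identical values in every cell: all contrasts and F are exactly 0
  eff <- condition_contrasts(base)
  expect_equal(tidy(eff)$estimate, rep(0, 5))
  expect_equal(tidy(eff)$F, rep(0, 5))
  expect_equal(tidy(eff)$diff_ms, rep(0, 5))
  expect_equal(eff$omnibus$F, 0)
})

test_that("a configured same-different gap is recovered in ms", {
  gaps <- vapply(1:20, function(i) {
    tr <- simulate_experiment(sim_config(trials_per_condition = 60),
                              seed = 100 + i)
    adj <- adjust_rt_for_landing(dplyr::filter(censor_trials(tr), correct,
                                               rt_ms <= 1500))
    tidy(condition_contrasts(adj))$diff_ms[3] # same - different
  }, numeric(1))
  # configured effects: same -16, different +19 -> gap -35 ms
  expect_lt(abs(mean(gaps) - (-35)), 8)
})

test_that("avov matches an independent one-way ANOVA on squared deviations", {
  withr::with_seed(9, {
    tr <- tibble::tibble(
      condition = rep(c("a", "b", "c"), times = c(40, 50, 60)),
      landing_x_deg = stats::rnorm(150, 0, rep(c(0.3, 0.5, 0.4),
                                               times = c(40, 50, 60))),
      landing_y_deg = stats::rnorm(150, 0, rep(c(0.3, 0.5, 0.4),
                                               times = c(40, 50, 60)))
    )
  })
  res <- avov_spread(tr)
  # oracle: stats::aov on the squared deviations
  g <- tr$condition
  d2 <- (tr$landing_x_deg - ave(tr$landing_x_deg, g))^2 +
    (tr$landing_y_deg - ave(tr$landing_y_deg, g))^2
  fit <- summary(stats::aov(d2 ~ g))[[1]]
  expect_equal(res$F, fit[["F value"]][1], tolerance = 1e-10)
  expect_equal(res$p, fit[["Pr(>F)"]][1], tolerance = 1e-10)
  expect_equal(res$df, c(fit[["Df"]][1], fit[["Df"]][2]))
})

test_that("avov detects a known dispersion ratio and nulls out on identity", {
  # group B is group A scaled x2 about its mean: variance ratio 4
  withr::with_seed(10, {
    a <- cbind(stats::rnorm(1000, 1, 0.3), stats::rnorm(1000, 0, 0.3))
    b <- sweep(sweep(a, 2, colMeans(a)), 2, c(1, 1), "*") * 2
    b <- sweep(b, 2, colMeans(a), "+")
  })
  tr <- tibble::tibble(
    condition = rep(c("a", "b"), each = 1000),
    landing_x_deg = c(a[, 1], b[, 1]),
    landing_y_deg = c(a[, 2], b[, 2])
  )
  res <- avov_spread(tr, contrast = c(a = -1, b = 1))
  expect_gt(res$contrast$estimate, 0)
  expect_lt(res$contrast$p, 0.01)
  # identical landing sets: F = 0
  tr2 <- tibble::tibble(
    condition = rep(c("a", "b"), each = 1000),
    landing_x_deg = c(a[, 1], a[, 1]),
    landing_y_deg = c(a[, 2], a[, 2])
  )
  expect_equal(avov_spread(tr2)$F, 0)
  expect_error(avov_spread(tr[c(1, 1001), ]), "at least 2 trials")
})

test_that("logistic accuracy analysis matches a direct ML fit", {
  withr::with_seed(11, {
    tr <- tibble::tibble(
      subject_id = rep(1:2, each = 100),
      condition = rep(sim_conditions(), 40),
      correct = stats::runif(200) < 0.8
    )
  })
  got <- accuracy_logistic(tr)
  # independent oracle: direct likelihood maximization with optim
  xmat <- stats::model.matrix(
    ~ factor(condition, sim_conditions()) + factor(subject_id), data = tr
  )
  nll <- function(beta) {
    eta <- as.vector(xmat %*% beta)
    -sum(tr$correct * eta - log1p(exp(eta)))
  }
  ml <- stats::optim(rep(0, ncol(xmat)), nll, method = "BFGS",
                     control = list(maxit = 1000, reltol = 1e-14))
  expect_equal(got$estimate, ml$par[2:5], tolerance = 2e-3,
               ignore_attr = TRUE)
})

test_that("null and configured accuracy effects behave as expected", {
  cfg <- sim_config(n_subjects = 4, trials_per_condition = 400,
                    accuracy_logit = c(intercept = 2, uniform = 0, random = 0,
                                       localized = 0, same = 0,
                                       different = 0))
  tr <- simulate_experiment(cfg, seed = 13)
  null_fit <- accuracy_logistic(tr)
  expect_true(all(abs(null_fit$estimate) < 3 * null_fit$se))
  # configured same-condition advantage is recovered across replicates
  est <- vapply(1:10, function(i) {
    cfg2 <- sim_config(n_subjects = 4, trials_per_condition = 300)
    fit <- accuracy_logistic(simulate_experiment(cfg2, seed = 300 + i))
    fit$estimate[fit$term == "same"]
  }, numeric(1))
  expect_lt(abs(mean(est) - 1.4), 0.35)
  # complete separation errors with advice
  sep <- tibble::tibble(subject_id = rep(1:2, each = 50),
                        condition = rep(sim_conditions(), 20),
                        correct = rep(c(TRUE, FALSE), each = 50))
  expect_error(accuracy_logistic(sep), "penalize")
  pen <- accuracy_logistic(sep, penalize = TRUE)
  expect_true(all(is.finite(pen$estimate)))
})
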