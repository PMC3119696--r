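#' Adjust log reaction times for saccade landing accuracy
#'
#' Saccade landing error confounds manual reaction times, so each data point
#' is linearly regressed to a landing on the display center: log-RT is
#' regressed on the landing distance within each subject, the per-subject
#' slopes are averaged into a single slope (no heterogeneity of slopes is
#' assumed), and `slope * distance` is subtracted from every log-RT — the
#' predicted value at distance zero plus the residual.
#'
#' @param trials A trial tibble (retained, correct-response trials) with
#'   `rt_ms`, `landing_x_deg`, `landing_y_deg` and `subject_id`.
#' @return The input with columns `landing_dist_deg`, `log_rt` and
#'   `adj_log_rt` added, and attributes `landing_slope` (the pooled slope,
#'   log-ms per degree) and `slope_test` (list: per-subject slopes, F, df,
#'   p — the slope tested against its between-subject variability).
#' @export
adjust_rt_for_landing <- function(trials) {
  need <- c("rt_ms", "landing_x_deg", "landing_y_deg", "subject_id")
  missing <- setdiff(need, names(trials))
  if (length(missing) > 0) {
    stop("missing field(s): ", paste(missing, collapse = ", "))
  }
  d <- sqrt(trials$landing_x_deg^2 + trials$landing_y_deg^2)
  if (stats::sd(d) == 0) stop("zero variance in landing distance")
  lrt <- log(trials$rt_ms)
  slopes <- vapply(split(seq_along(d), trials$subject_id), function(idx) {
    if (stats::sd(d[idx]) == 0) return(NA_real_)
    stats::coef(stats::lm(lrt[idx] ~ d[idx]))[2]
  }, numeric(1))
  slopes <- slopes[!is.na(slopes)]
  slope <- mean(slopes)
  ns <- length(slopes)
  slope_test <- if (ns > 1 && stats::sd(slopes) > 0) {
    f <- (mean(slopes) / (stats::sd(slopes) / sqrt(ns)))^2
    list(slopes = slopes, F = f, df = c(1, ns - 1),
         p = stats::pf(f, 1, ns - 1, lower.tail = FALSE))
  } else {
    list(slopes = slopes, F = NA_real_, df = c(1, ns - 1), p = NA_real_)
  }
  out <- dplyr::mutate(trials, landing_dist_deg = d, log_rt = lrt,
                       adj_log_rt = lrt - slope * d)
  attr(out, "landing_slope") <- slope
  attr(out, "slope_test") <- slope_test
  out
}

default_contrasts <- function() {
  list(
    neutral_vs_object = c(uniform = 1 / 2, random = 1 / 2, localized = -1 / 3,
                          same = -1 / 3, different = -1 / 3),
    uniform_vs_random = c(uniform = 1, random = -1, localized = 0, same = 0,
                          different = 0),
    same_vs_different = c(uniform = 0, random = 0, localized = 0, same = 1,
                          different = -1),
    same_vs_localized = c(uniform = 0, random = 0, localized = -1, same = 1,
                          different = 0),
    different_vs_localized = c(uniform = 0, random = 0, localized = -1,
                               same = 0, different = 1)
  )
}

#' Within-subject condition contrasts on adjusted log reaction times
#'
#' Computes subject-by-condition cell means of (landing-adjusted) log
#' reaction times and analyzes them as a repeated-measures cell-means model:
#' the error term is the subject-by-condition interaction with
#' `(conditions - 1) * (subjects - 1)` degrees of freedom. Reports the
#' omnibus condition test and planned contrasts ({uniform, random} vs the
#' object-like previews, uniform vs random, same vs different, and each
#' contour preview vs the localized baseline), each on 1 numerator df,
#' together with back-transformed differences in ms.
#'
#' @param trials A trial tibble with `subject_id`, `condition` and the value
#'   column; typically the output of [adjust_rt_for_landing()].
#' @param value Column to analyze (default `adj_log_rt`; tidy-eval).
#' @param contrasts Named list of contrast vectors over the five conditions
#'   (defaults to the planned set).
#' @return An object of class `preview_effects`; see [tidy.preview_effects()]
#'   and [glance.preview_effects()].
#' @export
condition_contrasts <- function(trials, value = adj_log_rt,
                                contrasts = default_contrasts()) {
  value <- rlang::enquo(value)
  conds <- sim_conditions()
  v <- rlang::eval_tidy(value, trials)
  df <- tibble::tibble(subject = trials$subject_id,
                       condition = trials$condition, v = v)
  cells <- dplyr::summarise(
    dplyr::group_by(df, .data$subject, .data$condition),
    m = mean(.data$v), .groups = "drop"
  )
  full <- tidyr::expand_grid(subject = unique(cells$subject),
                             condition = conds)
  chk <- dplyr::anti_join(full, cells, by = c("subject", "condition"))
  if (nrow(chk) > 0) {
    stop("missing subject x condition cell(s): ",
         paste(chk$subject, chk$condition, sep = "/", collapse = ", "))
  }
  if (length(unique(cells$subject)) < 2) stop("need at least 2 subjects")
  wide <- tidyr::pivot_wider(cells, names_from = "condition",
                             values_from = "m")
  m <- as.matrix(wide[, conds])
  s_n <- nrow(m); c_n <- length(conds)
  cond_means <- colMeans(m)
  subj_means <- rowMeans(m)
  grand <- mean(m)
  resid <- m - outer(subj_means, rep(1, c_n)) -
    outer(rep(1, s_n), cond_means) + grand
  df_err <- as.integer((c_n - 1) * (s_n - 1))
  ms_err <- sum(resid^2) / df_err
  ss_cond <- s_n * sum((cond_means - grand)^2)
  f_omni <- if (ms_err == 0) {
    if (ss_cond == 0) 0 else Inf
  } else {
    (ss_cond / (c_n - 1)) / ms_err
  }
  ctr <- purrr::imap(contrasts, function(w, nm) {
    w <- w[conds]
    est <- sum(w * cond_means)
    if (abs(est) < 1e-10 * max(1, abs(grand))) est <- 0
    se <- sqrt(ms_err * sum(w^2) / s_n)
    f <- if (se == 0) { if (est == 0) 0 else Inf } else (est / se)^2
    pos <- w > 0; neg <- w < 0
    ms_a <- exp(sum(w[pos] * cond_means[pos]) / sum(w[pos]))
    ms_b <- exp(sum(-w[neg] * cond_means[neg]) / sum(-w[neg]))
    tibble::tibble(
      contrast = nm, estimate = est, se = se, F = f,
      df1 = 1L, df2 = df_err,
      p = stats::pf(f, 1, df_err, lower.tail = FALSE),
      diff_ms = ms_a - ms_b,
      se_ms = se * exp(grand) # delta-method scale at the grand mean
    )
  })
  structure(
    list(
      cells = cells,
      condition_means = cond_means,
      grand_mean = grand,
      ms_error = ms_err,
      df_error = df_err,
      omnibus = tibble::tibble(
        F = f_omni, df1 = as.integer(c_n - 1), df2 = df_err,
        p = stats::pf(f_omni, c_n - 1, df_err, lower.tail = FALSE)
      ),
      contrasts = dplyr::bind_rows(ctr),
      landing_slope = attr(trials, "landing_slope"),
      slope_test = attr(trials, "slope_test")
    ),
    class = "preview_effects"
  )
}

#' @export
print.preview_effects <- function(x, ...) {
  cat(sprintf("<preview_effects: F(%d,%d) = %.2f, p = %.3g>\n",
              x$omnibus$df1, x$omnibus$df2, x$omnibus$F, x$omnibus$p))
  print(x$contrasts)
  invisible(x)
}

#' Tidy the planned contrasts of a preview-effects analysis
#'
#' @param x A `preview_effects` object.
#' @param ... Unused.
#' @return A tibble with one row per planned contrast: estimate (log scale),
#'   SE, F, dfs, p, and the back-transformed difference in ms.
#' @export
tidy.preview_effects <- function(x, ...) x$contrasts

#' One-row summary of a preview-effects analysis
#'
#' @param x A `preview_effects` object.
#' @param ... Unused.
#' @return A tibble with the omnibus F test, its dfs and p, the error mean
#'   square, and the landing-covariate slope (if any).
#' @export
glance.preview_effects <- function(x, ...) {
  tibble::tibble(
    F = x$omnibus$F, df1 = x$omnibus$df1, df2 = x$omnibus$df2,
    p = x$omnibus$p, ms_error = x$ms_error,
    landing_slope = x$landing_slope %||% NA_real_
  )
}

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom rlang %||% .data :=
NULL

#' Plot adjusted condition means
#'
#' @param x A `preview_effects` object.
#' @param ... Unused.
#' @return A ggplot object of back-transformed condition means (ms) with
#'   within-subject standard errors.
#' @export
autoplot.preview_effects <- function(x, ...) {
  cells <- x$cells
  centered <- dplyr::mutate(
    dplyr::group_by(cells, .data$subject),
    dev = .data$m - mean(.data$m)
  )
  sumr <- dplyr::summarise(
    dplyr::group_by(dplyr::ungroup(centered), .data$condition),
    mean = mean(.data$m),
    se = stats::sd(.data$dev) / sqrt(dplyr::n()), .groups = "drop"
  )
  sumr$condition <- factor(sumr$condition, sim_conditions())
  ggplot2::ggplot(sumr, ggplot2::aes(x = .data$condition,
                                     y = exp(.data$mean))) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = exp(.data$mean - .data$se), ymax = exp(.data$mean + .data$se)
    )) +
    ggplot2::labs(x = NULL, y = "adjusted reaction time (ms)") +
    ggplot2::theme_minimal()
}

#' Analysis of variance of variance for landing spread
#'
#' Compares the dispersion of 2D saccade landing positions between condition
#' groups: each trial contributes its squared Euclidean deviation from its
#' group's mean landing position, and a one-way analysis of variance (plus an
#' optional planned two-group contrast) is run on these squared deviations.
#'
#' @param trials A trial tibble with `landing_x_deg`, `landing_y_deg` and a
#'   grouping column.
#' @param group Grouping column (tidy-eval; default `condition`).
#' @param contrast Optional named numeric contrast over the group levels.
#' @return A list of class `avov` with the omnibus `F`, `df`, `p`, the group
#'   table, and (when requested) the contrast test.
#' @export
avov_spread <- function(trials, group = condition, contrast = NULL) {
  group <- rlang::enquo(group)
  g <- as.character(rlang::eval_tidy(group, trials))
  if (length(unique(g)) < 2) stop("need at least 2 groups")
  if (any(table(g) < 2)) stop("each group needs at least 2 trials")
  x <- trials$landing_x_deg
  y <- trials$landing_y_deg
  mx <- tapply(x, g, mean)[g]
  my <- tapply(y, g, mean)[g]
  d2 <- (x - mx)^2 + (y - my)^2
  lev <- sort(unique(g))
  ni <- as.numeric(table(g)[lev])
  gm <- tapply(d2, g, mean)[lev]
  grand <- mean(d2)
  ss_b <- sum(ni * (gm - grand)^2)
  ss_w <- sum((d2 - tapply(d2, g, mean)[g])^2)
  df_b <- length(lev) - 1
  df_w <- length(d2) - length(lev)
  f <- (ss_b / df_b) / (ss_w / df_w)
  out <- list(
    F = f, df = c(df_b, df_w),
    p = stats::pf(f, df_b, df_w, lower.tail = FALSE),
    groups = tibble::tibble(group = lev, n = ni, mean_sq_dev = as.numeric(gm))
  )
  if (!is.null(contrast)) {
    w <- contrast[lev]
    if (any(is.na(w))) stop("contrast must name every group level")
    est <- sum(w * gm)
    ms_w <- ss_w / df_w
    se <- sqrt(ms_w * sum(w^2 / ni))
    fc <- (est / se)^2
    out$contrast <- tibble::tibble(
      estimate = est, se = se, F = fc, df1 = 1, df2 = df_w,
      p = stats::pf(fc, 1, df_w, lower.tail = FALSE)
    )
  }
  structure(out, class = "avov")
}

#' @export
print.avov <- function(x, ...) {
  cat(sprintf("<avov: F(%d,%d) = %.2f, p = %.3g>\n", x$df[1], x$df[2], x$F,
              x$p))
  invisible(x)
}

#' Within-subjects logistic accuracy analysis
#'
#' Logistic regression of response correctness on preview condition (uniform
#' as the reference level) with subject fixed effects; coefficients are
#' per-condition log-odds differences from the uniform baseline, with Wald
#' tests.
#'
#' @param trials A trial tibble with `correct`, `condition` and `subject_id`.
#' @param penalize When `TRUE`, adds one half-weight success and failure
#'   pseudo-observation per subject-condition cell (a data-augmentation
#'   shrinkage that removes complete separation).
#' @return A tibble with one row per condition coefficient: `term`,
#'   `estimate` (log-odds vs uniform), `se`, `statistic` (Wald z), `p`.
#' @export
accuracy_logistic <- function(trials, penalize = FALSE) {
  df <- tibble::tibble(
    correct = as.numeric(trials$correct),
    condition = factor(trials$condition, sim_conditions()),
    subject = factor(trials$subject_id),
    w = 1
  )
  if (penalize) {
    aug <- tidyr::expand_grid(
      condition = unique(df$condition), subject = unique(df$subject),
      correct = c(0, 1), w = 0.5
    )
    df <- dplyr::bind_rows(df, aug)
  }
  fit <- suppressWarnings(stats::glm(
    correct ~ condition + subject, family = stats::binomial(), data = df,
    weights = df$w
  ))
  prob <- stats::fitted(fit)
  if (!penalize && (!fit$converged ||
                    any(prob < 1e-8) || any(prob > 1 - 1e-8))) {
    stop("complete or quasi-complete separation; refit with penalize = TRUE")
  }
  sm <- summary(fit)$coefficients
  keep <- grepl("^condition", rownames(sm))
  tibble::tibble(
    term = sub("^condition", "", rownames(sm)[keep]),
    estimate = sm[keep, 1], se = sm[keep, 2],
    statistic = sm[keep, 3], p = sm[keep, 4]
  )
}
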