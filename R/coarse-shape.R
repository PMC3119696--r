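#' Bounding boxes of a stimulus batch
#'
#' Minimum-area bounding rectangles of both latent contours of every stimulus
#' set in a batch, for coarse-shape analyses.
#'
#' @param batch A list of `element_layout`s.
#' @return A tibble with `stimulus_id`, `contour` (1 or 2), `aspect_ratio`,
#'   `orientation` (degrees in \[0, 180)), `width`, `height`.
#' @export
batch_shape_table <- function(batch) {
  purrr::map_dfr(batch, function(set) {
    purrr::map_dfr(1:2, function(k) {
      bb <- min_bounding_rect(set[[paste0("contour", k)]])
      tibble::tibble(
        stimulus_id = set$id, contour = k,
        aspect_ratio = bb$aspect_ratio, orientation = bb$orientation,
        width = bb$width, height = bb$height
      )
    })
  })
}

# axial (mod-180) orientation difference, reported in [0, 90]
axial_diff <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

# mean of per-subject Pearson correlations with a one-sample t test
subject_correlation <- function(df, xvar, yvar) {
  rs <- vapply(split(df, df$subject_id), function(sd) {
    if (nrow(sd) < 3 || stats::sd(sd[[xvar]]) == 0 ||
        stats::sd(sd[[yvar]]) == 0) {
      return(NA_real_)
    }
    stats::cor(sd[[xvar]], sd[[yvar]])
  }, numeric(1))
  rs <- rs[!is.na(rs)]
  ns <- length(rs)
  if (ns < 2) {
    return(list(r = if (ns == 1) rs else NA_real_, t = NA_real_,
                df = ns - 1L, p = NA_real_, n_subjects = ns))
  }
  tt <- stats::t.test(rs)
  list(r = mean(rs), t = unname(tt$statistic), df = ns - 1L, p = tt$p.value,
       n_subjects = ns)
}

#' Coarse-shape analysis of preview costs
#'
#' Tests whether the cost of a mismatching (different-contour) preview is
#' explained by the coarsest shape description only — the aspect ratio and
#' orientation of the minimum bounding rectangle of each contour. For every
#' different-preview trial the presaccadic (previewed) and postsaccadic
#' (displayed) contours are looked up in the shape table; trials where both
#' shapes are elongated (aspect ratio above `aspect_threshold`) enter a
#' per-subject correlation of log reaction time with the axial orientation
#' difference. The analysis also reports how much of the mean cost relative
#' to the localized baseline survives removal of large orientation
#' differences (above `orientation_threshold`), and the correlation of
#' reaction time with the relative aspect ratio on the complementary subset.
#'
#' @param trials A trial tibble including `condition`, `stimulus_id`,
#'   `postsac_stimulus`, `subject_id` and an adjusted log-RT column
#'   `adj_log_rt` (see [adjust_rt_for_landing()]).
#' @param shapes A shape table from [batch_shape_table()].
#' @param aspect_threshold Elongation criterion on both aspect ratios
#'   (default 1.2).
#' @param orientation_threshold Large orientation difference in degrees
#'   (default 33).
#' @return A list of class `coarse_shape_analysis`: `trials` (the annotated
#'   different-preview trials), `elongated_correlation` (RT vs orientation
#'   difference), `aspect_correlation` (RT vs relative aspect ratio on the
#'   complementary subset), `cost_ms`, `cost_excluding_ms`,
#'   `cost_reduction` (fractional), and `prop_elongated`.
#' @export
coarse_shape_analysis <- function(trials, shapes, aspect_threshold = 1.2,
                                  orientation_threshold = 33) {
  stopifnot("adj_log_rt" %in% names(trials))
  shp <- function(ids, contour_no, what) {
    key <- paste(ids, contour_no)
    lut <- stats::setNames(shapes[[what]],
                           paste(shapes$stimulus_id, shapes$contour))
    unname(lut[key])
  }
  diff_tr <- dplyr::filter(trials, .data$condition == "different")
  post <- diff_tr$postsac_stimulus
  pre <- 3 - post # different preview shows the other latent contour
  diff_tr <- dplyr::mutate(
    diff_tr,
    aspect_post = shp(.data$stimulus_id, post, "aspect_ratio"),
    aspect_pre = shp(.data$stimulus_id, pre, "aspect_ratio"),
    orient_post = shp(.data$stimulus_id, post, "orientation"),
    orient_pre = shp(.data$stimulus_id, pre, "orientation"),
    orient_diff = axial_diff(.data$orient_pre, .data$orient_post),
    rel_aspect = abs(log(.data$aspect_pre / .data$aspect_post)),
    elongated = .data$aspect_pre > aspect_threshold &
      .data$aspect_post > aspect_threshold
  )
  elong <- dplyr::filter(diff_tr, .data$elongated)
  elong_cor <- if (nrow(elong) > 0) {
    subject_correlation(elong, "orient_diff", "adj_log_rt")
  } else NULL
  compl <- dplyr::filter(diff_tr, !.data$elongated |
                           .data$orient_diff <= orientation_threshold)
  aspect_cor <- if (nrow(compl) > 0) {
    subject_correlation(compl, "rel_aspect", "adj_log_rt")
  } else NULL
  loc_mean <- mean(exp(trials$adj_log_rt[trials$condition == "localized"]))
  cost <- mean(exp(diff_tr$adj_log_rt)) - loc_mean
  keep <- !(diff_tr$elongated & diff_tr$orient_diff > orientation_threshold)
  cost_excl <- mean(exp(diff_tr$adj_log_rt[keep])) - loc_mean
  structure(
    list(
      trials = diff_tr,
      elongated_correlation = elong_cor,
      aspect_correlation = aspect_cor,
      cost_ms = cost,
      cost_excluding_ms = cost_excl,
      cost_reduction = if (cost != 0) 1 - cost_excl / cost else NA_real_,
      prop_elongated = mean(diff_tr$elongated)
    ),
    class = "coarse_shape_analysis"
  )
}

#' @export
print.coarse_shape_analysis <- function(x, ...) {
  cat(sprintf(
    paste0("<coarse_shape_analysis: %.1f%% elongated; cost %.1f ms ",
           "(%.1f ms excluding large orientation differences)>\n"),
    100 * x$prop_elongated, x$cost_ms, x$cost_excluding_ms
  ))
  if (!is.null(x$elongated_correlation)) {
    ec <- x$elongated_correlation
    cat(sprintf("  RT ~ orientation difference: r = %.3f, t(%d) = %.2f, p = %.3g\n",
                ec$r, ec$df, ec$t, ec$p))
  }
  invisible(x)
}
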