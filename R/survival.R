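#' Normalize subject medians before pooling
#'
#' Shifts each subject's values by a constant so that every subject's median
#' equals the overall median of the pooled raw values. Within-subject
#' differences are exactly preserved (a pure shift).
#'
#' @param data A data frame with one row per observation.
#' @param value Column with the values (tidy-eval).
#' @param subject Column identifying subjects (tidy-eval).
#' @return The input with the value column replaced by its normalized version.
#' @examples
#' df <- tibble::tibble(s = rep(c("A", "B"), each = 3),
#'                      v = c(190, 200, 210, 290, 300, 310))
#' normalize_medians(df, v, s)$v
#' @export
normalize_medians <- function(data, value, subject) {
  value <- rlang::enquo(value)
  subject <- rlang::enquo(subject)
  v <- rlang::eval_tidy(value, data)
  s <- rlang::eval_tidy(subject, data)
  if (length(v) == 0) stop("no values to normalize")
  grand <- stats::median(v)
  med <- tapply(v, s, function(x) {
    if (length(x) == 0) stop("empty subject")
    stats::median(x)
  })
  shifted <- v + (grand - med[as.character(s)])
  dplyr::mutate(data, !!rlang::quo_get_expr(value) := as.numeric(shifted))
}

# centered moving average whose window shrinks symmetrically at the edges
# (1, 3, ..., k bins)
smooth_symmetric <- function(x, k = 5) {
  half <- (k - 1) %/% 2
  n <- length(x)
  vapply(seq_len(n), function(i) {
    h <- min(half, i - 1, n - i)
    mean(x[(i - h):(i + h)])
  }, numeric(1))
}

#' Discrete-time survival and hazard of latencies
#'
#' Bins positive event times (saccadic latencies, manual reaction times) into
#' fixed-width bins and computes, per bin: the survival probability (the
#' fraction of events later than the bin's upper edge; one minus the
#' cumulative proportion), the hazard (events in the bin divided by the
#' number at risk entering it), and a smoothed hazard (centered moving
#' average over `smooth_bins` bins, shrinking symmetrically at the edges).
#' When a `condition` column is present the table is computed per condition.
#'
#' @param data A data frame, or a bare numeric vector of event times.
#' @param value Column with event times in ms (tidy-eval; ignored for a
#'   numeric vector input).
#' @param bin_ms Bin width in ms (5 for saccadic latencies, 15 for manual
#'   reaction times in the original design).
#' @param smooth_bins Moving-average window (default 5).
#' @param condition Optional grouping column (tidy-eval).
#' @return A tibble of class `survival_table` with columns `condition` (if
#'   grouped), `bin`, `time` (upper bin edge, ms), `n_events`, `at_risk`,
#'   `survival`, `hazard`, `smoothed_hazard`.
#' @export
survival_hazard <- function(data, value, bin_ms, smooth_bins = 5,
                            condition = NULL) {
  if (is.numeric(data)) {
    df <- tibble::tibble(.value = data)
    vals <- list(df$.value)
    names(vals) <- NA_character_
  } else {
    value <- rlang::enquo(value)
    condition <- rlang::enquo(condition)
    v <- rlang::eval_tidy(value, data)
    if (rlang::quo_is_null(condition)) {
      vals <- list(v)
      names(vals) <- NA_character_
    } else {
      g <- rlang::eval_tidy(condition, data)
      vals <- split(v, g)
    }
  }
  stopifnot(bin_ms > 0)
  out <- purrr::imap(vals, function(v, cond) {
    if (length(v) == 0) stop("empty input")
    if (any(v <= 0)) stop("event times must be positive")
    n_bins <- ceiling(max(v) / bin_ms)
    edges <- seq_len(n_bins) * bin_ms
    bin <- pmin(ceiling(v / bin_ms), n_bins)
    n_events <- tabulate(bin, n_bins)
    at_risk <- length(v) - c(0, cumsum(n_events)[-n_bins])
    hazard <- ifelse(at_risk > 0, n_events / at_risk, 0)
    survival <- 1 - cumsum(n_events) / length(v)
    tibble::tibble(
      condition = cond, bin = seq_len(n_bins), time = edges,
      n_events = n_events, at_risk = at_risk,
      survival = survival, hazard = hazard,
      smoothed_hazard = smooth_symmetric(hazard, smooth_bins)
    )
  })
  out <- dplyr::bind_rows(out)
  if (all(is.na(out$condition))) out$condition <- NULL
  class(out) <- c("survival_table", class(out))
  out
}

#' Plot survival and smoothed hazard functions
#'
#' @param x A `survival_table`.
#' @param ... Unused.
#' @return A ggplot object with survival and smoothed-hazard facets.
#' @export
autoplot.survival_table <- function(x, ...) {
  df <- tidyr::pivot_longer(
    tibble::as_tibble(x),
    c("survival", "smoothed_hazard"),
    names_to = "measure", values_to = "probability"
  )
  df$measure <- factor(df$measure, c("survival", "smoothed_hazard"),
                       c("survival", "smoothed hazard"))
  aes <- if ("condition" %in% names(df)) {
    ggplot2::aes(x = .data$time, y = .data$probability,
                 color = .data$condition)
  } else {
    ggplot2::aes(x = .data$time, y = .data$probability)
  }
  ggplot2::ggplot(df, aes) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~measure, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (ms)", y = "probability") +
    ggplot2::theme_minimal()
}
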