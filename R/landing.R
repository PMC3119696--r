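#' Landing-position iso-frequency region
#'
#' Builds a 2D histogram of saccade landing positions over the display (bin
#' width `bin_px` pixels, 0.21 degrees at the default scale) and selects the
#' highest-count bins until their cumulative mass first reaches the requested
#' fraction of all landings — the region an iso-frequency contour enclosing
#' that mass would outline. The combined marginal median landing point is
#' returned alongside.
#'
#' @param landings A data frame with landing coordinates.
#' @param x,y Coordinate columns (tidy-eval; defaults `landing_x_deg`,
#'   `landing_y_deg`).
#' @param bin_px Bin width in pixels (default 10).
#' @param ppd Pixels per degree (default 47.06).
#' @param mass Enclosed fraction, in (0, 1) (default 0.90).
#' @param halfwidth Display half-width in degrees (default 1.9).
#' @return A tibble of class `landing_region`, one row per selected bin
#'   (`x`, `y` bin centers, `count`), with attributes `median` (length-2
#'   marginal median landing), `mass_enclosed`, `bin_deg` and `n`.
#' @export
landing_isofrequency <- function(landings, x = landing_x_deg,
                                 y = landing_y_deg, bin_px = 10, ppd = 47.06,
                                 mass = 0.90, halfwidth = 1.9) {
  if (mass <= 0 || mass >= 1) stop("mass must lie in (0, 1)")
  x <- rlang::eval_tidy(rlang::enquo(x), landings)
  y <- rlang::eval_tidy(rlang::enquo(y), landings)
  if (length(x) < 10) stop("need at least 10 landings")
  bin_deg <- bin_px / ppd
  lim <- max(halfwidth, max(abs(c(x, y)))) + bin_deg
  edges <- seq(-ceiling(lim / bin_deg), ceiling(lim / bin_deg)) * bin_deg
  ix <- findInterval(x, edges, rightmost.closed = TRUE)
  iy <- findInterval(y, edges, rightmost.closed = TRUE)
  counts <- dplyr::count(tibble::tibble(ix = ix, iy = iy), .data$ix, .data$iy,
                         sort = TRUE)
  cum <- cumsum(counts$n)
  k <- which(cum >= mass * length(x))[1]
  sel <- counts[seq_len(k), ]
  out <- tibble::tibble(
    x = (edges[sel$ix] + edges[sel$ix + 1]) / 2,
    y = (edges[sel$iy] + edges[sel$iy + 1]) / 2,
    count = sel$n
  )
  attr(out, "median") <- c(stats::median(x), stats::median(y))
  attr(out, "mass_enclosed") <- cum[k] / length(x)
  attr(out, "bin_deg") <- bin_deg
  attr(out, "n") <- length(x)
  class(out) <- c("landing_region", class(out))
  out
}

#' Plot landing iso-frequency regions per condition
#'
#' @param trials A trial tibble with landing coordinates and `condition`.
#' @param ... Passed to [landing_isofrequency()].
#' @return A ggplot object: one facet per condition showing the bins
#'   enclosing the requested mass and the marginal median landing point.
#' @export
plot_landing_map <- function(trials, ...) {
  conds <- split(trials, trials$condition)
  regions <- purrr::imap(conds, function(df, nm) {
    reg <- landing_isofrequency(df, ...)
    med <- attr(reg, "median")
    dplyr::mutate(tibble::as_tibble(reg), condition = nm,
                  med_x = med[1], med_y = med[2])
  })
  df <- dplyr::bind_rows(regions)
  bin_deg <- attr(landing_isofrequency(conds[[1]], ...), "bin_deg")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$count),
                       width = bin_deg, height = bin_deg) +
    ggplot2::geom_point(ggplot2::aes(x = .data$med_x, y = .data$med_y),
                        color = "red", shape = 3) +
    ggplot2::facet_wrap(~condition) +
    ggplot2::coord_fixed(xlim = c(-1.9, 1.9), ylim = c(-1.9, 1.9)) +
    ggplot2::labs(x = "x (deg)", y = "y (deg)", fill = "landings") +
    ggplot2::theme_minimal()
}
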