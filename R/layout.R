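#' Place local elements along a contour
#'
#' Elements are placed at equidistant arc-length positions (with a random
#' global offset) and perturbed by uniform jitter strictly along the contour.
#' The realized average spacing is the perimeter divided by the element count
#' `n = floor(perimeter / spacing)`. Jitter is drawn per element from
#' \eqn{\pm 0.42} of the realized spacing and resampled (rejection, never
#' clipping) until two constraints hold: each consecutive along-contour gap
#' lies between 58% and 142% of the realized spacing, and the element is at
#' least half the realized spacing away (Euclidean) from every contour
#' intersection point.
#'
#' @param contour An `rf_contour`.
#' @param role Element role label (`"contour1"` or `"contour2"`).
#' @param spacing Target average spacing in degrees; determines the element
#'   count only (the realized spacing is perimeter / count).
#' @param intersections Optional tibble of intersection points (columns `x`,
#'   `y`) to keep clear of.
#' @param jitter Logical; disable to place the equidistant scaffold exactly.
#' @param max_attempts Per-element rejection cap (default 1000).
#' @param max_restarts Whole-contour restarts when the wrap-around gap cannot
#'   be satisfied (default 50).
#' @param seed Optional integer seed.
#' @return A tibble with one row per element: `role`, `arc_s` (arc length
#'   position), `theta`, `x`, `y`, `tangent` (degrees in \[0,180)),
#'   `spacing_ref` (the realized average spacing), `gap_next` (arc gap to the
#'   next element along the contour, wrap included) and `int_dist` (distance
#'   to the nearest intersection point, `Inf` when none given).
#' @export
place_on_contour <- function(contour, role = "contour1", spacing = 0.35,
                             intersections = NULL, jitter = TRUE,
                             max_attempts = 1000, max_restarts = 50,
                             seed = NULL) {
  if (!is.null(seed)) {
    return(withr::with_seed(seed, place_on_contour(
      contour, role, spacing, intersections, jitter, max_attempts,
      max_restarts, seed = NULL
    )))
  }
  arc <- contour_arc_table(contour)
  per <- arc$perimeter
  stopifnot(spacing > 0, spacing < per)
  n <- floor(per / spacing)
  if (n < 3) stop("spacing too large: fewer than 3 elements fit on the contour")
  unit <- per / n # realized average spacing
  ipts <- if (!is.null(intersections) && nrow(intersections) > 0) {
    cbind(intersections$x, intersections$y)
  } else NULL

  # fast interpolated lookup during rejection sampling; accepted elements are
  # re-evaluated analytically below so they sit exactly on the contour
  point_at <- function(s) {
    s <- s %% per
    c(arc$theta_of_s(s), arc$x_of_s(s), arc$y_of_s(s))
  }
  clear_ok <- function(p) {
    is.null(ipts) ||
      min(sqrt((ipts[, 1] - p[2])^2 + (ipts[, 2] - p[3])^2)) >=
        0.5 * unit + 1e-6 # margin covers the interpolation error
  }

  for (restart in seq_len(max_restarts)) {
    offset <- stats::runif(1, 0, per)
    base <- offset + (seq_len(n) - 1) * unit
    u <- numeric(n)
    pts <- matrix(NA_real_, n, 3)
    ok <- TRUE
    for (i in seq_len(n)) {
      placed <- FALSE
      for (attempt in seq_len(max_attempts)) {
        ui <- if (jitter) stats::runif(1, -0.42, 0.42) * unit else 0
        if (i > 1) {
          gap <- (base[i] + ui) - (base[i - 1] + u[i - 1])
          if (gap < 0.58 * unit || gap > 1.42 * unit) next
        }
        p <- point_at(base[i] + ui)
        if (!clear_ok(p)) next
        u[i] <- ui
        pts[i, ] <- p
        placed <- TRUE
        break
      }
      if (!placed) { ok <- FALSE; break }
      if (!jitter) next
    }
    if (!ok) {
      if (!jitter) break # deterministic scaffold cannot improve by restarting
      next
    }
    wrap <- per - (base[n] + u[n]) + (base[1] + u[1])
    if (jitter && (wrap < 0.58 * unit || wrap > 1.42 * unit)) next
    s_jit <- base + u # consecutive along-contour order by construction
    s_final <- s_jit %% per
    gaps <- c(diff(s_jit), wrap)
    th <- arc$theta_of_s(s_final)
    r <- contour_radius(contour, th) # exact on-contour positions
    px <- contour$center[1] + r * cos(th)
    py <- contour$center[2] + r * sin(th)
    int_dist <- if (is.null(ipts)) rep(Inf, n) else {
      vapply(seq_len(n), function(i) {
        min(sqrt((ipts[, 1] - px[i])^2 + (ipts[, 2] - py[i])^2))
      }, numeric(1))
    }
    return(tibble::tibble(
      role = role,
      arc_s = s_final,
      theta = th %% (2 * pi),
      x = px, y = py,
      tangent = contour_tangent(contour, th),
      spacing_ref = unit,
      gap_next = gaps,
      int_dist = int_dist
    ))
  }
  stop("element placement constraints unsatisfiable for this contour pair ",
       "(intersections too dense for the requested spacing)")
}

#' Element layout container
#'
#' Bundles the element table of one stimulus set with its two latent contours
#' and placement metadata.
#'
#' @param elements Element tibble (rows from [place_on_contour()] and
#'   background/target rows).
#' @param contour1,contour2 The two latent `rf_contour`s (display frame).
#' @param intersections Intersection tibble in the display frame.
#' @param avg_spacing Realized average contour spacing in degrees (mean of the
#'   two per-contour values).
#' @param display_halfwidth Half-width of the square display in degrees
#'   (default 1.9).
#' @return An object of class `element_layout`.
#' @export
element_layout <- function(elements, contour1, contour2, intersections,
                           avg_spacing, display_halfwidth = 1.9) {
  structure(
    list(
      elements = elements,
      contour1 = contour1, contour2 = contour2,
      intersections = intersections,
      avg_spacing = avg_spacing,
      display_halfwidth = display_halfwidth,
      target_index = NA_integer_,
      target_class = NA_character_
    ),
    class = "element_layout"
  )
}

#' @export
print.element_layout <- function(x, ...) {
  cat(sprintf(
    "<element_layout: %d elements (%s), avg spacing %.3f deg, target: %s>\n",
    nrow(x$elements),
    paste(names(table(x$elements$role)), table(x$elements$role),
          sep = "=", collapse = ", "),
    x$avg_spacing,
    if (is.na(x$target_index)) "none" else x$target_class
  ))
  invisible(x)
}

#' @export
tidy.element_layout <- function(x, ...) x$elements

# nearest-neighbour distance of every element to any other element
nn_distances <- function(xy) {
  d <- as.matrix(stats::dist(xy))
  diag(d) <- Inf
  apply(d, 1, min)
}

#' Proximity-cue test p-value
#'
#' Tests whether contour elements are detectable from local density alone by
#' comparing the nearest-neighbour distances of contour-role elements against
#' those of background-role elements with a two-sided Wilcoxon rank-sum test.
#' A large p-value (the generator requires p > 0.3) means no proximity cue.
#'
#' @param layout An `element_layout` with at least 5 contour and 5 background
#'   elements.
#' @return The rank-sum p-value.
#' @export
proximity_pvalue <- function(layout) {
  el <- layout$elements
  is_contour <- el$role %in% c("contour1", "contour2")
  is_bg <- el$role %in% c("background", "target")
  if (sum(is_contour) < 5 || sum(is_bg) < 5) {
    stop("need at least 5 contour and 5 background elements")
  }
  nn <- nn_distances(cbind(el$x, el$y))
  suppressWarnings(
    stats::wilcox.test(nn[is_contour], nn[is_bg], exact = FALSE)$p.value
  )
}

#' Fill the display background with elements
#'
#' Adds background elements by dart-throwing: candidate positions are uniform
#' over the display square and accepted when at least half the average spacing
#' away from every existing element. Once a minimum background count is
#' reached, filling continues until the proximity-cue test clears p > 0.3.
#'
#' @param layout An `element_layout` with contour elements placed.
#' @param p_threshold Proximity p-value to exceed (default 0.3).
#' @param min_background Minimum number of background elements before the test
#'   can stop the fill (default 20).
#' @param max_darts Cap on candidate draws (default 1e4); exceeding it is an
#'   error.
#' @param seed Optional integer seed.
#' @return The layout with background elements appended.
#' @export
fill_background <- function(layout, p_threshold = 0.3, min_background = 20,
                            max_darts = 1e4, seed = NULL) {
  if (!is.null(seed)) {
    return(withr::with_seed(seed, fill_background(
      layout, p_threshold, min_background, max_darts, seed = NULL
    )))
  }
  hw <- layout$display_halfwidth
  min_d <- 0.5 * layout$avg_spacing
  n0 <- nrow(layout$elements)
  is_contour <- layout$elements$role %in% c("contour1", "contour2")
  # preallocate and keep nearest-neighbour distances incrementally up to date
  cap <- n0 + 512L
  px <- c(layout$elements$x, rep(NA_real_, cap - n0))
  py <- c(layout$elements$y, rep(NA_real_, cap - n0))
  nn <- c(nn_distances(cbind(layout$elements$x, layout$elements$y)),
          rep(NA_real_, cap - n0))
  n <- n0
  for (dart in seq_len(max_darts)) {
    cand <- stats::runif(2, -hw, hw)
    d <- sqrt((px[1:n] - cand[1])^2 + (py[1:n] - cand[2])^2)
    if (min(d) < min_d) next
    n <- n + 1L
    px[n] <- cand[1]; py[n] <- cand[2]
    nn[1:(n - 1)] <- pmin(nn[1:(n - 1)], d)
    nn[n] <- min(d)
    n_bg <- n - n0
    if (n_bg >= max(5, min_background)) {
      p <- suppressWarnings(stats::wilcox.test(
        nn[1:n0][is_contour], nn[(n0 + 1):n], exact = FALSE
      )$p.value)
      if (p > p_threshold) {
        layout$elements <- dplyr::bind_rows(
          layout$elements,
          tibble::tibble(role = "background",
                         x = px[(n0 + 1):n], y = py[(n0 + 1):n])
        )
        return(layout)
      }
    }
  }
  stop("background fill did not eliminate the proximity cue within ",
       max_darts, " darts")
}
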