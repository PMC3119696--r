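#' Compatibility report for a pair of latent contours
#'
#' Summarizes how well two superimposed contours can coexist in one element
#' display: the crossing angles at their intersections, the shortest
#' along-contour arc between consecutive intersections (over both contours),
#' and the distribution of the radial distance between the two radius
#' functions.
#'
#' @param c1,c2 `rf_contour` objects sharing a polar origin.
#' @param intersections Optional precomputed result of
#'   [find_intersections()]; computed when missing.
#' @param n_grid Grid density for the radial-distance statistics.
#' @param arc1,arc2 Optional precomputed arc-length tables (internal caching).
#' @return A list of class `compatibility_report` with fields
#'   `n_intersections`, `intersection_angles` (degrees), `min_segment_length`
#'   (degrees of arc), and `radial_distance` (list with `min`, `max`, `mean` of
#'   \eqn{|r_1(\theta) - r_2(\theta)|}).
#' @export
compatibility_report <- function(c1, c2, intersections = NULL, n_grid = 4096,
                                 arc1 = NULL, arc2 = NULL) {
  if (is.null(intersections)) intersections <- find_intersections(c1, c2)
  theta <- seq(0, 2 * pi, length.out = n_grid + 1L)[-(n_grid + 1L)]
  dr <- abs(contour_radius(c1, theta) - contour_radius(c2, theta))
  min_seg <- NA_real_
  if (nrow(intersections) >= 2) {
    if (is.null(arc1)) arc1 <- contour_arc_table(c1)
    if (is.null(arc2)) arc2 <- contour_arc_table(c2)
    segs <- unlist(lapply(list(arc1, arc2), function(arc) {
      s <- sort(arc$s_of_theta(intersections$theta))
      diff(c(s, s[1] + arc$perimeter))
    }))
    min_seg <- min(segs)
  }
  structure(
    list(
      n_intersections = nrow(intersections),
      intersection_angles = intersections$crossing_angle,
      min_segment_length = min_seg,
      radial_distance = list(min = min(dr), max = max(dr), mean = mean(dr))
    ),
    class = "compatibility_report"
  )
}

#' @export
print.compatibility_report <- function(x, ...) {
  cat(sprintf(
    "<compatibility_report: %d intersections, min segment %.3g deg, mean |dr| %.3g deg>\n",
    x$n_intersections, x$min_segment_length, x$radial_distance$mean
  ))
  invisible(x)
}

# score a pool of compatibility reports: z-scored weighted sum of
# (min segment length)+, (mean radial distance)+, (deviation of crossing
# angles from 90 deg)-. Non-intersecting candidates get -Inf.
score_candidates <- function(reports, weights = c(1, 1, 1)) {
  seg <- vapply(reports, function(r) {
    if (r$n_intersections >= 2) r$min_segment_length else NA_real_
  }, numeric(1))
  dr <- vapply(reports, function(r) r$radial_distance$mean, numeric(1))
  ang <- vapply(reports, function(r) {
    if (r$n_intersections >= 2) mean(abs(r$intersection_angles - 90)) else NA_real_
  }, numeric(1))
  zs <- function(v) {
    s <- stats::sd(v, na.rm = TRUE)
    if (!is.finite(s) || s == 0) return(rep(0, length(v)))
    (v - mean(v, na.rm = TRUE)) / s
  }
  score <- weights[1] * zs(seg) + weights[2] * zs(dr) - weights[3] * zs(ang)
  score[is.na(seg)] <- -Inf
  score
}

#' Select a compatible partner contour
#'
#' Generates `n_candidates` fresh random contours in the same polar frame as
#' `c1`, scores each against `c1`, and returns the best candidate together with
#' its compatibility report. The score is a weighted sum of three pool-z-scored
#' criteria: larger minimum inter-intersection segment length, larger mean
#' radial distance between the contours (discriminability), and smaller
#' deviation of the crossing angles from 90 degrees. Candidates that do not
#' intersect `c1` at least twice, or whose minimum segment length falls below
#' `segment_floor`, are infeasible. Ties break to the first candidate index, so
#' selection is deterministic under a fixed seed.
#'
#' @param c1 The first `rf_contour` (pre-alignment, polar origin at the display
#'   center).
#' @param n_candidates Size of the candidate pool (default 100).
#' @param weights Length-3 weights for the three criteria (default `c(1,1,1)`).
#' @param segment_floor Hard floor on the minimum segment length in degrees
#'   (default 0.35, about one average element spacing).
#' @param seed Optional integer seed for the candidate pool.
#' @param ... Passed to [generate_contour()].
#' @return A list with elements `contour` (the selected `rf_contour`),
#'   `report` (its `compatibility_report`) and `index` (position in the pool).
#' @export
select_partner <- function(c1, n_candidates = 100, weights = c(1, 1, 1),
                           segment_floor = 0.35, seed = NULL, ...) {
  stopifnot(n_candidates >= 1)
  if (!is.null(seed)) {
    return(withr::with_seed(seed, select_partner(
      c1, n_candidates, weights, segment_floor, seed = NULL, ...
    )))
  }
  pool <- lapply(seq_len(n_candidates), function(i) generate_contour(...))
  pool <- lapply(pool, translate_contour, offset = c1$center) # shared origin
  arc1 <- contour_arc_table(c1, n = 2048)
  reports <- lapply(pool, function(cc) {
    ints <- tryCatch(find_intersections(c1, cc, n_grid = 2048),
                     error = function(e) NULL)
    if (is.null(ints)) return(structure(list(
      n_intersections = 0L, intersection_angles = numeric(0),
      min_segment_length = NA_real_,
      radial_distance = list(min = NA_real_, max = NA_real_, mean = NA_real_)
    ), class = "compatibility_report"))
    compatibility_report(c1, cc, intersections = ints, n_grid = 2048,
                         arc1 = arc1, arc2 = contour_arc_table(cc, n = 2048))
  })
  if (!any(vapply(reports, function(r) r$n_intersections >= 2, logical(1)))) {
    stop("no candidate intersects the first contour; enlarge the candidate pool")
  }
  score <- score_candidates(reports, weights)
  seg_ok <- vapply(reports, function(r) {
    r$n_intersections >= 2 && r$min_segment_length >= segment_floor
  }, logical(1))
  score[!seg_ok] <- -Inf
  if (all(score == -Inf)) {
    stop("no intersecting candidate meets the segment-length floor; ",
         "enlarge the candidate pool or lower `segment_floor`")
  }
  idx <- which.max(score) # which.max returns the first maximum: tie rule
  list(contour = pool[[idx]], report = reports[[idx]], index = idx)
}
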