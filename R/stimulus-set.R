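#' Generate one complete stimulus set
#'
#' Builds the latent geometry of one display: a first random radial frequency
#' contour, a compatible partner selected from a fresh candidate pool, both
#' contours translated together so the first contour's centroid sits at the
#' display center (standardizing the saccade landing position), elements
#' placed along both contours with arc-length jitter and intersection
#' clearance, and a background fill that eliminates the proximity cue. Steps
#' that can fail (partner selection, constrained placement, background fill,
#' an element leaving the display square) are retried with fresh draws.
#'
#' @param spacing Target average element spacing in degrees (default 0.35).
#' @param n_candidates Partner candidate pool size (default 100).
#' @param segment_floor Minimum inter-intersection segment length in degrees
#'   (default 0.35).
#' @param max_attempts Retry cap for the whole set (default 25).
#' @param seed Optional integer seed.
#' @param id Stimulus set identifier stored on the layout.
#' @return An `element_layout` with fields `id` and `compatibility` added.
#' @export
generate_stimulus_set <- function(spacing = 0.35, n_candidates = 100,
                                  segment_floor = 0.35, max_attempts = 25,
                                  seed = NULL, id = NA_integer_) {
  if (!is.null(seed)) {
    return(withr::with_seed(seed, generate_stimulus_set(
      spacing, n_candidates, segment_floor, max_attempts, seed = NULL, id = id
    )))
  }
  for (attempt in seq_len(max_attempts)) {
    c1 <- generate_contour()
    partner <- tryCatch(
      select_partner(c1, n_candidates = n_candidates,
                     segment_floor = segment_floor),
      error = function(e) NULL
    )
    if (is.null(partner)) next
    c2 <- partner$contour
    ints <- find_intersections(c1, c2)
    cen <- polygon_centroid(contour_points(c1)$x, contour_points(c1)$y)
    c1 <- translate_contour(c1, -cen)
    c2 <- translate_contour(c2, -cen)
    ints$x <- ints$x - cen[1]
    ints$y <- ints$y - cen[2]
    e1 <- tryCatch(
      place_on_contour(c1, "contour1", spacing, intersections = ints),
      error = function(e) NULL
    )
    e2 <- tryCatch(
      place_on_contour(c2, "contour2", spacing, intersections = ints),
      error = function(e) NULL
    )
    if (is.null(e1) || is.null(e2)) next
    elements <- dplyr::bind_rows(e1, e2)
    if (max(abs(c(elements$x, elements$y))) > 1.9) next
    layout <- element_layout(
      elements, c1, c2, ints,
      avg_spacing = mean(c(e1$spacing_ref[1], e2$spacing_ref[1]))
    )
    layout <- tryCatch(fill_background(layout), error = function(e) NULL)
    if (is.null(layout)) next
    layout$id <- id
    layout$compatibility <- partner$report
    return(layout)
  }
  stop("could not generate a valid stimulus set in ", max_attempts, " attempts")
}

# classify candidate target hosts among background elements:
# eccentricity band, off-contour margin, and inside/outside class
target_candidates <- function(layout, ecc_range = c(0.75, 1.35),
                              margin = 0.05) {
  el <- layout$elements
  idx <- which(el$role == "background")
  if (length(idx) == 0) {
    return(tibble::tibble(index = integer(0), class = character(0)))
  }
  x <- el$x[idx]; y <- el$y[idx]
  ecc <- sqrt(x^2 + y^2)
  radial_gap <- function(cc) {
    qx <- x - cc$center[1]; qy <- y - cc$center[2]
    sqrt(qx^2 + qy^2) - contour_radius(cc, atan2(qy, qx))
  }
  d1 <- radial_gap(layout$contour1)
  d2 <- radial_gap(layout$contour2)
  ok <- ecc >= ecc_range[1] & ecc <= ecc_range[2] &
    abs(d1) > margin & abs(d2) > margin
  cls <- dplyr::case_when(
    d1 < 0 & d2 < 0 ~ "inside_both",
    d1 > 0 & d2 > 0 ~ "outside_both",
    .default = "mixed"
  )
  tibble::tibble(index = idx[ok], class = cls[ok])
}

#' Assign target squares across a batch of stimulus sets
#'
#' Replaces one random background element per display by the target, at an
#' eccentricity between 0.75 and 1.35 degrees and clear of both latent
#' contours, with the target class stratified exactly across the batch: 25%
#' of displays inside both contours, 25% outside both, 50% inside one and
#' outside the other. Class membership is determined with the point-in-contour
#' test against both latent contours.
#'
#' @param batch A list of `element_layout`s; length divisible by 4.
#' @param ecc_range Eccentricity band in degrees (default `c(0.75, 1.35)`).
#' @param margin Minimum radial distance from either contour in degrees
#'   (default 0.05), avoiding ambiguous on-contour targets.
#' @param max_shuffles Retry cap for the stratified assignment (default 200).
#' @param seed Optional integer seed.
#' @return The batch with `target_index`/`target_class` set and the chosen
#'   element's role changed to `"target"`.
#' @export
assign_targets <- function(batch, ecc_range = c(0.75, 1.35), margin = 0.05,
                           max_shuffles = 200, seed = NULL) {
  if (!is.null(seed)) {
    return(withr::with_seed(seed, assign_targets(
      batch, ecc_range, margin, max_shuffles, seed = NULL
    )))
  }
  n <- length(batch)
  if (n %% 4 != 0) stop("batch size must be divisible by 4")
  cand <- lapply(batch, target_candidates, ecc_range = ecc_range,
                 margin = margin)
  achievable <- lapply(cand, function(tc) unique(tc$class))
  empty <- which(lengths(achievable) == 0)
  if (length(empty) > 0) {
    stop("no background element can host a target in display(s) ",
         paste(empty, collapse = ", "))
  }
  quota_full <- c(inside_both = n / 4, outside_both = n / 4, mixed = n / 2)
  classes <- names(quota_full)
  assignment <- NULL
  for (shuffle in seq_len(max_shuffles)) {
    rem <- quota_full
    ord <- sample(order(lengths(achievable))) # random among equal scarcity
    ord <- ord[order(lengths(achievable)[ord])]
    asg <- rep(NA_character_, n)
    ok <- TRUE
    for (i in ord) {
      open <- intersect(achievable[[i]], classes[rem > 0])
      if (length(open) == 0) { ok <- FALSE; break }
      pick <- if (length(open) == 1) open else {
        sample(open, 1, prob = rem[open])
      }
      asg[i] <- pick
      rem[pick] <- rem[pick] - 1
    }
    if (ok && all(rem == 0)) { assignment <- asg; break }
  }
  if (is.null(assignment)) {
    stop("could not satisfy the 25/25/50 target stratification; ",
         "display(s) lacking class candidates: ",
         paste(which(vapply(achievable, length, 1L) < 3), collapse = ", "))
  }
  for (i in seq_len(n)) {
    pool <- cand[[i]]$index[cand[[i]]$class == assignment[i]]
    pick <- if (length(pool) == 1) pool else sample(pool, 1)
    batch[[i]]$elements$role[pick] <- "target"
    batch[[i]]$target_index <- pick
    batch[[i]]$target_class <- assignment[i]
  }
  batch
}

#' Generate a batch of stimulus sets with targets assigned
#'
#' Convenience wrapper: generates `n_sets` stimulus sets (retrying failed
#' geometry draws) and assigns target squares with the stratified 25/25/50
#' inside/outside allocation. If the stratification cannot be met with the
#' generated sets, offending sets are regenerated.
#'
#' @param n_sets Number of stimulus sets (divisible by 4; default 80).
#' @param spacing Target average element spacing in degrees (default 0.35).
#' @param seed Optional integer seed.
#' @param ... Passed to [generate_stimulus_set()].
#' @return A list of `element_layout`s with targets assigned.
#' @export
generate_stimulus_batch <- function(n_sets = 80, spacing = 0.35, seed = NULL,
                                    ...) {
  if (!is.null(seed)) {
    return(withr::with_seed(seed, generate_stimulus_batch(
      n_sets, spacing, seed = NULL, ...
    )))
  }
  if (n_sets %% 4 != 0) stop("n_sets must be divisible by 4")
  batch <- lapply(seq_len(n_sets), function(i) {
    generate_stimulus_set(spacing = spacing, id = i, ...)
  })
  for (round in 1:20) {
    out <- tryCatch(assign_targets(batch), error = function(e) e)
    if (!inherits(out, "error")) return(out)
    # regenerate the sets that cannot host all classes, then retry
    short <- which(vapply(batch, function(b) {
      length(unique(target_candidates(b)$class)) < 3
    }, logical(1)))
    if (length(short) == 0) stop(out)
    for (i in short) {
      batch[[i]] <- generate_stimulus_set(spacing = spacing, id = i, ...)
    }
  }
  stop("target stratification failed repeatedly across regenerated sets")
}

#' Serialize a stimulus layout to JSON
#'
#' @param layout An `element_layout`.
#' @param path Optional file path.
#' @return The JSON string (invisibly when written to a file).
#' @export
layout_to_json <- function(layout, path = NULL) {
  obj <- list(
    id = layout$id,
    display_halfwidth = layout$display_halfwidth,
    avg_spacing = layout$avg_spacing,
    target_index = layout$target_index,
    target_class = layout$target_class,
    contour1 = jsonlite::fromJSON(contour_to_json(layout$contour1)),
    contour2 = jsonlite::fromJSON(contour_to_json(layout$contour2)),
    intersections = as.data.frame(layout$intersections),
    elements = as.data.frame(layout$elements)
  )
  js <- jsonlite::toJSON(obj, digits = I(17), auto_unbox = TRUE, na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Deserialize a stimulus layout from JSON
#'
#' @param json JSON string or file path written by [layout_to_json()].
#' @return An `element_layout`.
#' @export
layout_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  mk <- function(co) rf_contour(co$components$frequency, co$components$amplitude,
                                co$components$phase, co$base_radius, co$center)
  layout <- element_layout(
    tibble::as_tibble(obj$elements), mk(obj$contour1), mk(obj$contour2),
    tibble::as_tibble(obj$intersections), obj$avg_spacing,
    obj$display_halfwidth
  )
  layout$id <- obj$id
  layout$target_index <- if (is.null(obj$target_index)) NA_integer_ else obj$target_index
  layout$target_class <- if (is.null(obj$target_class)) NA_character_ else obj$target_class
  layout
}
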