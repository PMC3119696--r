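# Independent oracles used across test files. These deliberately avoid the
# package's own code paths.

# even-odd (ray crossing) point-in-polygon test
polygon_even_odd <- function(px, py, qx, qy) {
  n <- length(px)
  j <- n
  inside <- rep(FALSE, length(qx))
  for (i in seq_len(n)) {
    crosses <- ((py[i] > qy) != (py[j] > qy)) &
      (qx < (px[j] - px[i]) * (qy - py[i]) / (py[j] - py[i]) + px[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# shoelace centroid, written independently of polygon_centroid()
shoelace_centroid <- function(x, y) {
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  c(sum((x + xn) * cr) / (6 * a), sum((y + yn) * cr) / (6 * a))
}

# brute-force minimum-area rectangle by scanning rotation angles
brute_min_rect_area <- function(x, y, step_deg = 0.1) {
  angles <- seq(0, 90 - step_deg, by = step_deg) * pi / 180
  areas <- vapply(angles, function(a) {
    u <- x * cos(a) + y * sin(a)
    v <- -x * sin(a) + y * cos(a)
    (max(u) - min(u)) * (max(v) - min(v))
  }, numeric(1))
  min(areas)
}

# a tiny layout object for proximity tests built from raw coordinates
fake_layout <- function(contour_xy, background_xy, avg_spacing = 0.35) {
  structure(
    list(
      elements = tibble::tibble(
        role = c(rep("contour1", nrow(contour_xy)),
                 rep("background", nrow(background_xy))),
        x = c(contour_xy[, 1], background_xy[, 1]),
        y = c(contour_xy[, 2], background_xy[, 2])
      ),
      avg_spacing = avg_spacing,
      display_halfwidth = 1.9,
      target_index = NA_integer_,
      target_class = NA_character_
    ),
    class = "element_layout"
  )
}
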