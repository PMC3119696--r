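#' Radial frequency pattern contours
#'
#' A radial frequency pattern (RFP) is a closed contour defined in polar
#' coordinates as a fixed base radius plus a sum of sinusoidal modulations,
#' \deqn{r(\theta) = r_0 + \sum_i A_i \sin(f_i \theta + \phi_i),}
#' with integer frequencies \eqn{f_i} so that the curve closes exactly after one
#' revolution. The polar origin of a contour may be offset from the display
#' center; the offset is stored in `center` and all Cartesian outputs include it.
#'
#' @param frequency Integer vector of component frequencies (cycles/revolution).
#' @param amplitude Numeric vector of component amplitudes (degrees of visual
#'   angle), same length as `frequency`.
#' @param phase Numeric vector of component phases (radians), same length.
#' @param base_radius Base radius in degrees (default 1).
#' @param center Length-2 numeric, offset of the polar origin from the display
#'   center in degrees.
#'
#' @return An object of class `rf_contour`.
#' @export
rf_contour <- function(frequency, amplitude, phase, base_radius = 1,
                       center = c(0, 0)) {
  stopifnot(
    length(frequency) == length(amplitude),
    length(frequency) == length(phase),
    length(center) == 2, is.finite(base_radius), base_radius > 0
  )
  if (any(abs(frequency - round(frequency)) > 1e-9)) {
    stop("component frequencies must be integers (closure after one revolution)")
  }
  structure(
    list(
      frequency = as.integer(round(frequency)),
      amplitude = as.numeric(amplitude),
      phase = as.numeric(phase),
      base_radius = as.numeric(base_radius),
      center = as.numeric(center)
    ),
    class = "rf_contour"
  )
}

#' @export
print.rf_contour <- function(x, ...) {
  cat(sprintf(
    "<rf_contour: %d components, base radius %.3g deg, center (%.4g, %.4g)>\n",
    length(x$frequency), x$base_radius, x$center[1], x$center[2]
  ))
  invisible(x)
}

#' Generate a random radial frequency contour
#'
#' Draws component frequencies uniformly from `freq_set`, amplitudes uniformly
#' from `amp_range` and phases uniformly from \eqn{[0, 2\pi)}. The fixed base
#' radius keeps the radius function strictly positive for any realizable draw;
#' positivity is nevertheless checked on a dense grid and the contour redrawn
#' in the (practically impossible) event of a non-positive radius.
#'
#' @param n_components Number of sinusoidal components (default 10).
#' @param freq_set Integer frequencies to draw from (default `2:4`).
#' @param amp_range Amplitude range in degrees (default `c(0.03, 0.1)`).
#' @param base_radius Base radius in degrees (default 1).
#' @param seed Optional integer; when given the draw is made under this seed
#'   without disturbing the caller's RNG state.
#'
#' @return An `rf_contour`.
#' @examples
#' cntr <- generate_contour(seed = 1)
#' range(contour_radius(cntr, seq(0, 2 * pi, length.out = 360)))
#' @export
generate_contour <- function(n_components = 10, freq_set = 2:4,
                             amp_range = c(0.03, 0.1), base_radius = 1,
                             seed = NULL) {
  stopifnot(n_components >= 1)
  if (!is.null(seed)) {
    return(withr::with_seed(seed, generate_contour(
      n_components, freq_set, amp_range, base_radius, seed = NULL
    )))
  }
  theta_chk <- seq(0, 2 * pi, length.out = 513L)[-513L]
  for (attempt in 1:100) {
    cntr <- rf_contour(
      frequency = sample(freq_set, n_components, replace = TRUE),
      amplitude = stats::runif(n_components, amp_range[1], amp_range[2]),
      phase = stats::runif(n_components, 0, 2 * pi),
      base_radius = base_radius
    )
    if (all(contour_radius(cntr, theta_chk) > 0)) return(cntr)
  }
  stop("failed to draw a contour with strictly positive radius") # nocov
}

#' Radius function of a contour
#'
#' @param contour An `rf_contour`.
#' @param theta Polar angles in radians (about the contour's own polar origin).
#' @return Numeric vector of radii in degrees.
#' @export
contour_radius <- function(contour, theta) {
  m <- sin(outer(theta, contour$frequency) +
             rep(contour$phase, each = length(theta)))
  contour$base_radius + as.vector(m %*% contour$amplitude)
}

# dr/dtheta, analytic
contour_radius_deriv <- function(contour, theta) {
  m <- cos(outer(theta, contour$frequency) +
             rep(contour$phase, each = length(theta)))
  as.vector(m %*% (contour$amplitude * contour$frequency))
}

#' Cartesian points on a contour
#'
#' @param contour An `rf_contour`.
#' @param n Number of equally spaced polar angles to sample (used when `theta`
#'   is not given).
#' @param theta Optional explicit polar angles (radians).
#' @return A tibble with columns `theta`, `x`, `y` (degrees, display-centered).
#' @export
contour_points <- function(contour, n = 4096, theta = NULL) {
  if (is.null(theta)) theta <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  r <- contour_radius(contour, theta)
  tibble::tibble(
    theta = theta,
    x = contour$center[1] + r * cos(theta),
    y = contour$center[2] + r * sin(theta)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' Tidy a contour into a point table
#'
#' @param x An `rf_contour`.
#' @param n Number of sampled points.
#' @param ... Unused.
#' @return A tibble of sampled contour points (`theta`, `x`, `y`).
#' @export
tidy.rf_contour <- function(x, n = 512, ...) contour_points(x, n = n)

#' Local tangent direction of a contour
#'
#' Direction of the tangent vector \eqn{(dx/d\theta, dy/d\theta)}, reported as
#' an axial angle in degrees in \eqn{[0, 180)}.
#'
#' @param contour An `rf_contour`.
#' @param theta Polar angles in radians.
#' @return Numeric vector of tangent directions in degrees.
#' @export
contour_tangent <- function(contour, theta) {
  r <- contour_radius(contour, theta)
  dr <- contour_radius_deriv(contour, theta)
  dx <- dr * cos(theta) - r * sin(theta)
  dy <- dr * sin(theta) + r * cos(theta)
  (atan2(dy, dx) * 180 / pi) %% 180
}

#' Angular mean radius of a contour
#'
#' Computes \eqn{(1/2\pi)\int_0^{2\pi} r(\theta)\,d\theta} by periodic
#' quadrature (the rectangle rule on an equispaced grid, which is spectrally
#' accurate for trigonometric polynomials). For integer component frequencies
#' the sinusoids integrate to zero over a revolution, so the mean radius equals
#' the base radius.
#'
#' @param contour An `rf_contour`.
#' @param n Number of quadrature nodes (default 8192).
#' @return Mean radius in degrees.
#' @export
mean_radius <- function(contour, n = 8192) {
  theta <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  mean(contour_radius(contour, theta))
}

# area centroid of a closed polygon (shoelace); x, y without repeated endpoint
polygon_centroid <- function(x, y) {
  n <- length(x)
  xn <- c(x[-1], x[1])
  yn <- c(y[-1], y[1])
  cross <- x * yn - xn * y
  a <- sum(cross) / 2
  if (abs(a) < 1e-12) stop("degenerate polygon: zero area")
  c(sum((x + xn) * cross), sum((y + yn) * cross)) / (6 * a)
}

#' Align a contour's centroid with the display center
#'
#' Translates the contour (a pure shift of its polar origin) so that the area
#' centroid of its sampled polygon coincides with the display center. The shape
#' itself is unchanged; the translation is recorded in `center`.
#'
#' @param contour An `rf_contour`.
#' @param n_samples Polygon sampling density (default 4096; must be >= 3).
#' @return The translated `rf_contour`.
#' @export
align_centroid <- function(contour, n_samples = 4096) {
  stopifnot(n_samples >= 3)
  pts <- contour_points(contour, n = n_samples)
  cen <- polygon_centroid(pts$x, pts$y)
  translate_contour(contour, -cen)
}

#' Translate a contour
#'
#' @param contour An `rf_contour`.
#' @param offset Length-2 numeric shift in degrees.
#' @return The shifted `rf_contour`.
#' @export
translate_contour <- function(contour, offset) {
  contour$center <- contour$center + as.numeric(offset)
  contour
}

#' Intersections of two contours sharing a polar origin
#'
#' Finds all polar angles where the two radius functions agree, by locating
#' sign changes of \eqn{r_1 - r_2} on a dense angular grid and refining each by
#' bisection. Both contours must share the same polar origin (i.e. be compared
#' before any centroid alignment, or after identical translations).
#'
#' @param c1,c2 `rf_contour` objects with identical `center`.
#' @param n_grid Angular grid density (default 4096).
#' @param tol Bisection tolerance on theta (default 1e-8).
#' @return A tibble with one row per intersection: `theta` (radians), `x`, `y`
#'   (degrees, display-centered) and `crossing_angle` (degrees in \[0, 90\], the
#'   absolute angle between the two tangent directions).
#' @export
find_intersections <- function(c1, c2, n_grid = 4096, tol = 1e-8) {
  if (max(abs(c1$center - c2$center)) > 1e-12) {
    stop("contours must share the same polar origin")
  }
  dfun <- function(theta) contour_radius(c1, theta) - contour_radius(c2, theta)
  theta <- seq(0, 2 * pi, length.out = n_grid + 1L)
  d <- dfun(theta)
  if (max(abs(d)) < 1e-9) {
    stop("degenerate pair: contours are identical within tolerance")
  }
  exact <- theta[-(n_grid + 1L)][d[-(n_grid + 1L)] == 0]
  idx <- which(d[-(n_grid + 1L)] * d[-1L] < 0)
  roots <- exact
  if (length(idx) > 0) {
    a <- theta[idx]; b <- theta[idx + 1]; fa <- d[idx]
    for (iter in seq_len(ceiling(log2((2 * pi / n_grid) / tol)) + 1L)) {
      m <- (a + b) / 2
      fm <- dfun(m)
      lo <- fa * fm >= 0 # root in [m, b]
      a[lo] <- m[lo]; fa[lo] <- fm[lo]
      b[!lo] <- m[!lo]
    }
    roots <- c(roots, (a + b) / 2)
  }
  roots <- sort(unique(roots %% (2 * pi)))
  if (length(roots) > 1) roots <- roots[c(TRUE, diff(roots) > 10 * tol)]
  if (length(roots) == 0) {
    return(tibble::tibble(theta = numeric(0), x = numeric(0), y = numeric(0),
                          crossing_angle = numeric(0)))
  }
  r <- contour_radius(c1, roots)
  t1 <- contour_tangent(c1, roots)
  t2 <- contour_tangent(c2, roots)
  dlt <- abs(t1 - t2) %% 180
  tibble::tibble(
    theta = roots,
    x = c1$center[1] + r * cos(roots),
    y = c1$center[2] + r * sin(roots),
    crossing_angle = pmin(dlt, 180 - dlt)
  )
}

# cumulative arc length along a contour; returns a list with interpolators
contour_arc_table <- function(contour, n = 8192) {
  theta <- seq(0, 2 * pi, length.out = n + 1L)
  r <- contour_radius(contour, theta)
  dr <- contour_radius_deriv(contour, theta)
  g <- sqrt(r^2 + dr^2)
  ds <- (g[-1] + g[-(n + 1L)]) / 2 * diff(theta)
  s <- c(0, cumsum(ds))
  list(
    theta = theta, s = s, perimeter = s[n + 1L],
    theta_of_s = stats::approxfun(s, theta, rule = 2),
    s_of_theta = stats::approxfun(theta, s, rule = 2),
    x_of_s = stats::approxfun(s, contour$center[1] + r * cos(theta), rule = 2),
    y_of_s = stats::approxfun(s, contour$center[2] + r * sin(theta), rule = 2)
  )
}

#' Perimeter of a contour
#'
#' Arc length of one full revolution, by trapezoidal quadrature of
#' \eqn{\sqrt{r^2 + r'^2}}.
#'
#' @param contour An `rf_contour`.
#' @param n Quadrature density (default 8192).
#' @return Perimeter in degrees.
#' @export
contour_perimeter <- function(contour, n = 8192) {
  contour_arc_table(contour, n)$perimeter
}

#' Point-in-contour test
#'
#' A radial frequency contour is star-shaped about its polar origin, so a point
#' is inside the contour iff its radius about that origin is smaller than the
#' contour radius at its polar angle.
#'
#' @param contour An `rf_contour` (typically centroid-aligned).
#' @param points A length-2 numeric, or a 2-column matrix / data frame with
#'   columns `x` and `y`, in degrees relative to the display center.
#' @param tol Ambiguity tolerance: a point whose radial distance to the contour
#'   is below `tol` raises an error (default 1e-9).
#' @return Logical vector, `TRUE` for inside.
#' @export
point_inside <- function(contour, points, tol = 1e-9) {
  if (is.data.frame(points)) points <- cbind(points$x, points$y)
  if (is.null(dim(points))) points <- matrix(points, ncol = 2)
  qx <- points[, 1] - contour$center[1]
  qy <- points[, 2] - contour$center[2]
  rad <- sqrt(qx^2 + qy^2)
  dr <- rad - contour_radius(contour, atan2(qy, qx))
  if (any(abs(dr) < tol)) {
    stop("point lies on the contour within tolerance; classification ambiguous")
  }
  dr < 0
}

#' Minimum-area bounding rectangle of a contour
#'
#' Computes the smallest-area enclosing rectangle of the sampled contour
#' polygon by rotating calipers over the convex hull: the optimal rectangle has
#' a side collinear with a hull edge, so only hull-edge directions need to be
#' scanned.
#'
#' @param contour An `rf_contour`, or a 2-column matrix / data frame of
#'   polygon vertices (`x`, `y`).
#' @param n Polygon sampling density for contour input (default 4096).
#' @return A list of class `bounding_box` with fields `width`, `height`
#'   (extents along / perpendicular to the supporting edge direction, degrees),
#'   `orientation` (long-axis direction, degrees in \[0, 180)), `aspect_ratio`
#'   (>= 1) and `area`.
#' @export
min_bounding_rect <- function(contour, n = 4096) {
  pts <- if (inherits(contour, "rf_contour")) {
    contour_points(contour, n = n)
  } else if (is.data.frame(contour)) {
    contour
  } else {
    data.frame(x = contour[, 1], y = contour[, 2])
  }
  hull <- grDevices::chull(pts$x, pts$y)
  hx <- pts$x[hull]; hy <- pts$y[hull]
  k <- length(hull)
  edges <- atan2(hy[c(2:k, 1)] - hy, hx[c(2:k, 1)] - hx)
  best <- NULL
  for (phi in unique(edges %% pi)) {
    u <- c(cos(phi), sin(phi))
    v <- c(-sin(phi), cos(phi))
    pu <- hx * u[1] + hy * u[2]
    pv <- hx * v[1] + hy * v[2]
    w <- max(pu) - min(pu)
    h <- max(pv) - min(pv)
    if (is.null(best) || w * h < best$area) {
      long <- if (w >= h) phi else phi + pi / 2
      best <- list(
        width = w, height = h,
        orientation = (long * 180 / pi) %% 180,
        aspect_ratio = max(w, h) / min(w, h),
        area = w * h
      )
    }
  }
  structure(best, class = "bounding_box")
}

#' @export
print.bounding_box <- function(x, ...) {
  cat(sprintf(
    "<bounding_box: %.3f x %.3f deg, aspect %.3f, orientation %.1f deg>\n",
    x$width, x$height, x$aspect_ratio, x$orientation
  ))
  invisible(x)
}

#' Serialize a contour to JSON
#'
#' Writes base radius, center and the component triples so the contour
#' round-trips bit-exactly (full double precision).
#'
#' @param contour An `rf_contour`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when written to a file).
#' @export
contour_to_json <- function(contour, path = NULL) {
  js <- jsonlite::toJSON(
    list(
      base_radius = contour$base_radius,
      center = contour$center,
      components = data.frame(
        frequency = contour$frequency,
        amplitude = contour$amplitude,
        phase = contour$phase
      )
    ),
    digits = I(17), auto_unbox = TRUE
  )
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Deserialize a contour from JSON
#'
#' @param json A JSON string or a path to a JSON file written by
#'   [contour_to_json()].
#' @return An `rf_contour`.
#' @export
contour_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  rf_contour(
    frequency = obj$components$frequency,
    amplitude = obj$components$amplitude,
    phase = obj$components$phase,
    base_radius = obj$base_radius,
    center = obj$center
  )
}
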