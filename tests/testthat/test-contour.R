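test_that("radius function evaluates the Fourier sum and closes exactly", {
  one <- rf_contour(2, 0.1, 0)
  expect_equal(contour_radius(one, pi / 4), 1.1)
  circle <- rf_contour(3, 0, 0)
  theta <- seq(0, 2 * pi, length.out = 100)
  expect_equal(contour_radius(circle, theta), rep(1, 100))
  cntr <- generate_contour(seed = 11)
  expect_lt(abs(contour_radius(cntr, 0) - contour_radius(cntr, 2 * pi)),
            1e-12)
  r <- contour_radius(cntr, seq(0, 2 * pi, length.out = 1e4))
  expect_true(all(r >= 0) && all(r <= 2))
})

test_that("generated contours respect the parameter ranges", {
  for (seed in 1:5) {
    cntr <- generate_contour(seed = seed)
    expect_length(cntr$frequency, 10)
    expect_true(all(cntr$frequency %in% 2:4))
    expect_true(all(cntr$amplitude >= 0.03 & cntr$amplitude <= 0.1))
    expect_true(all(cntr$phase >= 0 & cntr$phase < 2 * pi))
    expect_identical(cntr$base_radius, 1)
  }
  expect_error(rf_contour(2.5, 0.05, 0), "integer")
})

test_that("mean radius equals the base radius for integer frequencies", {
  # independent oracle: trapezoidal quadrature at 1e5 nodes
  quad <- function(cntr) {
    th <- seq(0, 2 * pi, length.out = 1e5 + 1)
    r <- contour_radius(cntr, th)
    sum((r[-1] + r[-length(r)]) / 2 * diff(th)) / (2 * pi)
  }
  expect_equal(mean_radius(rf_contour(3, 0, 0)), 1)
  single <- rf_contour(3, 0.05, 1.2)
  expect_equal(mean_radius(single), quad(single), tolerance = 1e-9)
  expect_lt(abs(mean_radius(single) - 1), 1e-6)
  for (seed in 1:5) {
    cntr <- generate_contour(seed = seed)
    expect_lt(abs(mean_radius(cntr) - quad(cntr)), 1e-6)
    expect_lt(abs(mean_radius(cntr) - 1), 1e-6)
  }
})

test_that("centroid alignment recenters the sampled polygon exactly", {
  circle <- rf_contour(2, 0, 0)
  aligned <- align_centroid(circle)
  expect_equal(aligned$center, c(0, 0), tolerance = 1e-9)
  # even-frequency components are centro-symmetric: no translation needed
  f2 <- rf_contour(2, 0.1, 0.7)
  expect_lt(sqrt(sum(align_centroid(f2, 1e4)$center^2)), 1e-6)
  for (seed in 1:4) {
    aligned <- align_centroid(generate_contour(seed = seed))
    pts <- contour_points(aligned, n = 4096)
    cen <- shoelace_centroid(pts$x, pts$y) # independent implementation
    expect_lt(sqrt(sum(cen^2)), 1e-6)
  }
})

test_that("intersection finding matches analytic root sets", {
  circle <- rf_contour(2, 0, 0)
  outer_circle <- rf_contour(2, 0, 0, base_radius = 1.2)
  expect_identical(nrow(find_intersections(circle, outer_circle)), 0L)
  s2 <- rf_contour(2, 0.1, 0)
  ints <- find_intersections(circle, s2)
  expect_equal(ints$theta, c(0, pi / 2, pi, 3 * pi / 2), tolerance = 1e-7)
  s3a <- rf_contour(3, 0.05, 0)
  s3b <- rf_contour(3, 0.05, pi)
  expect_identical(nrow(find_intersections(s3a, s3b)), 6L)
  expect_error(find_intersections(circle, rf_contour(4, 0, 0)), "identical")
  # intersection count of an intersecting pair is even
  for (seed in 1:4) {
    a <- generate_contour(seed = seed)
    b <- generate_contour(seed = seed + 100)
    n <- nrow(find_intersections(a, b))
    expect_identical(n %% 2L, 0L)
  }
})

test_that("crossing angles are the angle between tangent directions", {
  circle <- rf_contour(2, 0, 0)
  s2 <- rf_contour(2, 0.1, 0)
  ints <- find_intersections(circle, s2)
  # at theta = 0: circle tangent is vertical; modulated contour tangent
  # direction is atan2(r, dr) rotated; check against direct formula
  dr <- 0.1 * 2 * cos(2 * ints$theta)
  ang_mod <- (atan2(dr * sin(ints$theta) + 1 * cos(ints$theta),
                    dr * cos(ints$theta) - 1 * sin(ints$theta)) * 180 / pi) %% 180
  ang_circ <- (atan2(cos(ints$theta), -sin(ints$theta)) * 180 / pi) %% 180
  d <- abs(ang_mod - ang_circ) %% 180
  expect_equal(ints$crossing_angle, pmin(d, 180 - d), tolerance = 1e-6)
})

test_that("point_inside agrees with analytic and polygon oracles", {
  circle <- rf_contour(2, 0, 0)
  withr::with_seed(5, {
    q <- matrix(stats::runif(2000, -2, 2), ncol = 2)
    keep <- abs(sqrt(q[, 1]^2 + q[, 2]^2) - 1) > 1e-6
    q <- q[keep, ]
    expect_identical(point_inside(circle, q),
                     sqrt(q[, 1]^2 + q[, 2]^2) < 1)
  })
  expect_error(point_inside(circle, c(1, 0)), "ambiguous")
  expect_true(point_inside(circle, c(0, 0)))
  expect_false(point_inside(circle, c(3, 0)))
  # generated contours vs an independent even-odd polygon test
  for (seed in 1:3) {
    cntr <- align_centroid(generate_contour(seed = seed))
    poly <- contour_points(cntr, n = 4096)
    withr::with_seed(seed + 50, {
      q <- matrix(stats::runif(2000, -2, 2), ncol = 2)
    })
    oracle <- polygon_even_odd(poly$x, poly$y, q[, 1], q[, 2])
    got <- point_inside(cntr, q)
    expect_gt(mean(got == oracle), 1 - 2e-3) # boundary pixels may differ
  }
})

test_that("minimum bounding rectangle is optimal and oriented correctly", {
  circle <- rf_contour(2, 0, 0)
  bb <- min_bounding_rect(circle)
  expect_equal(bb$aspect_ratio, 1, tolerance = 1e-3)
  # 2:1 axis-aligned ellipse sampled as a polygon
  theta <- seq(0, 2 * pi, length.out = 2049)[-2049]
  bb2 <- min_bounding_rect(cbind(2 * cos(theta), sin(theta)))
  expect_equal(bb2$aspect_ratio, 2, tolerance = 1e-2)
  expect_lt(min(bb2$orientation, 180 - bb2$orientation), 1)
  # brute-force optimality on generated contours
  for (seed in 1:3) {
    cntr <- generate_contour(seed = seed)
    pts <- contour_points(cntr, n = 1024)
    bb <- min_bounding_rect(cntr, n = 1024)
    brute <- brute_min_rect_area(pts$x, pts$y)
    expect_lte(bb$area, brute + 1e-9)
    aabb <- (max(pts$x) - min(pts$x)) * (max(pts$y) - min(pts$y))
    expect_lte(bb$area, aabb + 1e-12)
    # the box contains every sampled point
    a <- bb$orientation * pi / 180
    u <- pts$x * cos(a) + pts$y * sin(a)
    v <- -pts$x * sin(a) + pts$y * cos(a)
    expect_lte(max(u) - min(u), max(bb$width, bb$height) + 1e-9)
    expect_lte(max(v) - min(v), min(bb$width, bb$height) + 1e-9)
  }
})

test_that("contour JSON serialization round-trips bit-exactly", {
  cntr <- align_centroid(generate_contour(seed = 9))
  back <- contour_from_json(contour_to_json(cntr))
  expect_identical(back$frequency, cntr$frequency)
  expect_identical(back$amplitude, cntr$amplitude)
  expect_identical(back$phase, cntr$phase)
  expect_identical(back$base_radius, cntr$base_radius)
  expect_identical(back$center, cntr$center)
  path <- withr::local_tempfile(fileext = ".json")
  contour_to_json(cntr, path)
  expect_identical(contour_from_json(path)$phase, cntr$phase)
})
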