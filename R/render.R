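#' Condition specification for a preview display
#'
#' Determines which elements are lit (high luminance) in the Gaussian preview
#' of a given experimental condition:
#' * `fixation` — none (the pre-trial display);
#' * `uniform` — all elements;
#' * `random` — a uniformly chosen half of all elements;
#' * `localized` — a uniformly chosen half of the elements lying within the
#'   maximal radius of the two latent contours;
#' * `same` — the elements of the contour shown postsaccadically;
#' * `different` — the elements of the other latent contour.
#'
#' @param layout An `element_layout`.
#' @param condition One of `"fixation"`, `"uniform"`, `"random"`,
#'   `"localized"`, `"same"`, `"different"`.
#' @param postsac_stimulus Which latent contour (1 or 2) the postsaccadic
#'   display will show; resolves `same`/`different`.
#' @param seed Optional integer seed (used by `random` and `localized`).
#' @return A list of class `condition_spec` with fields `name`,
#'   `postsac_stimulus` and `lit_set` (integer element indices).
#' @export
assign_condition <- function(layout, condition, postsac_stimulus = 1,
                             seed = NULL) {
  if (!is.null(seed)) {
    return(withr::with_seed(seed, assign_condition(
      layout, condition, postsac_stimulus, seed = NULL
    )))
  }
  stopifnot(postsac_stimulus %in% c(1, 2))
  el <- layout$elements
  n <- nrow(el)
  shown_role <- paste0("contour", postsac_stimulus)
  other_role <- paste0("contour", 3 - postsac_stimulus)
  lit <- switch(
    condition,
    fixation = integer(0),
    uniform = seq_len(n),
    random = sort(sample(seq_len(n), floor(n / 2))),
    localized = {
      theta <- seq(0, 2 * pi, length.out = 1025L)[-1025L]
      max_rad <- max(vapply(list(layout$contour1, layout$contour2),
                            function(cc) {
                              p <- contour_points(cc, theta = theta)
                              max(sqrt(p$x^2 + p$y^2))
                            }, numeric(1)))
      eligible <- which(sqrt(el$x^2 + el$y^2) <= max_rad)
      sort(sample(eligible, floor(length(eligible) / 2)))
    },
    same = which(el$role == shown_role),
    different = which(el$role == other_role),
    stop("unknown condition: ", condition)
  )
  structure(
    list(name = condition, postsac_stimulus = postsac_stimulus, lit_set = lit),
    class = "condition_spec"
  )
}

# pixel-center coordinate grids for a square display
display_grid <- function(size_deg, ppd) {
  npx <- round(size_deg * ppd)
  half <- npx / 2
  list(
    npx = npx,
    x = ((seq_len(npx) - 0.5) - half) / ppd,        # columns, rightward
    y = (half - (seq_len(npx) - 0.5)) / ppd          # rows, downward grid, y up
  )
}

new_display_image <- function(pixels, ppd, size_deg) {
  structure(list(pixels = pixels, ppd = ppd, size_deg = size_deg),
            class = "display_image")
}

#' @export
print.display_image <- function(x, ...) {
  cat(sprintf("<display_image: %d x %d px, %.2f ppd, range [%.3f, %.3f]>\n",
              nrow(x$pixels), ncol(x$pixels), x$ppd,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

# add a luminance increment profile around each element; profiles sum and the
# final image is clipped to [0, 1]
accumulate_profiles <- function(img, grid, xs, ys, fun, support) {
  for (i in seq_along(xs)) {
    cols <- which(abs(grid$x - xs[i]) <= support)
    rows <- which(abs(grid$y - ys[i]) <= support)
    if (length(cols) == 0 || length(rows) == 0) next
    dx <- grid$x[cols] - xs[i]
    dy <- grid$y[rows] - ys[i]
    img[rows, cols] <- img[rows, cols] + fun(
      matrix(dx, length(rows), length(cols), byrow = TRUE),
      matrix(dy, length(rows), length(cols))
    )
  }
  img
}

#' Render a Gaussian-blob preview display
#'
#' Every element contributes a Gaussian luminance increment (sd 0.05 deg) on a
#' 0.5 background: peak 0.27 for lit elements (absolute peak 0.77) and 0.14
#' for unlit elements (absolute peak 0.64). Overlapping increments sum before
#' the final clip to \[0, 1\].
#'
#' @param layout An `element_layout`.
#' @param spec A `condition_spec` from [assign_condition()].
#' @param ppd Pixels per degree (default 47.06, an 800-px, 17-degree monitor).
#' @param sd Gaussian sd in degrees (default 0.05).
#' @param peak_high,peak_low Luminance increments for lit/unlit elements.
#' @param size_deg Display side in degrees (default 3.8).
#' @return A `display_image`.
#' @export
render_gaussian <- function(layout, spec, ppd = 47.06, sd = 0.05,
                            peak_high = 0.27, peak_low = 0.14,
                            size_deg = 3.8) {
  grid <- display_grid(size_deg, ppd)
  img <- matrix(0, grid$npx, grid$npx)
  el <- layout$elements
  if (nrow(el) > 0) {
    peak <- ifelse(seq_len(nrow(el)) %in% spec$lit_set, peak_high, peak_low)
    for (lvl in unique(peak)) {
      sel <- peak == lvl
      img <- accumulate_profiles(
        img, grid, el$x[sel], el$y[sel],
        function(dx, dy) lvl * exp(-(dx^2 + dy^2) / (2 * sd^2)),
        support = 4 * sd
      )
    }
  }
  new_display_image(pmin(pmax(img + 0.5, 0), 1), ppd, size_deg)
}

#' Gabor orientations for a postsaccadic display
#'
#' Elements of the displayed contour are oriented along their local contour
#' tangent plus uniform jitter within +/- `jitter_deg`; all other elements
#' (background and the other latent contour) get a completely random
#' orientation. The target element gets no orientation (it is drawn as a
#' square).
#'
#' @param layout An `element_layout`.
#' @param postsac_stimulus Displayed contour (1 or 2).
#' @param jitter_deg Maximum absolute tangent jitter in degrees (default 22.5).
#' @param seed Optional integer seed.
#' @return A tibble with columns `element`, `role`, `x`, `y`, `on_shown`
#'   (logical) and `orientation` (degrees in \[0, 180), `NA` for the target).
#' @export
gabor_orientations <- function(layout, postsac_stimulus = 1,
                               jitter_deg = 22.5, seed = NULL) {
  if (!is.null(seed)) {
    return(withr::with_seed(seed, gabor_orientations(
      layout, postsac_stimulus, jitter_deg, seed = NULL
    )))
  }
  el <- layout$elements
  n <- nrow(el)
  shown_role <- paste0("contour", postsac_stimulus)
  on_shown <- el$role == shown_role
  ori <- stats::runif(n, 0, 180)
  ori[on_shown] <- (el$tangent[on_shown] +
                      stats::runif(sum(on_shown), -jitter_deg, jitter_deg)) %% 180
  if (!is.na(layout$target_index)) ori[layout$target_index] <- NA_real_
  tibble::tibble(
    element = seq_len(n), role = el$role, x = el$x, y = el$y,
    on_shown = on_shown, orientation = ori
  )
}

#' Render a Gabor postsaccadic display
#'
#' Elements are even-symmetric (cosine-phase) Gabor patches: a 10 cycles per
#' degree carrier in a Gaussian envelope of sd 0.06 deg, peak contrast
#' increment 0.27 on the 0.5 background so the element center attains
#' luminance 0.77. Orientations come from [gabor_orientations()]; the target
#' element is drawn as a luminance-defined square via [render_target()].
#'
#' @param layout An `element_layout`.
#' @param postsac_stimulus Displayed contour (1 or 2).
#' @param ppd Pixels per degree (default 47.06).
#' @param sd Gaussian envelope sd in degrees (default 0.06).
#' @param sf Carrier spatial frequency in cycles/degree (default 10).
#' @param peak Peak luminance increment (default 0.27).
#' @param jitter_deg Tangent jitter bound in degrees (default 22.5).
#' @param size_deg Display side in degrees (default 3.8).
#' @param seed Optional integer seed (orientations).
#' @return A `display_image` with the orientation table attached as attribute
#'   `"orientations"`.
#' @export
render_gabor <- function(layout, postsac_stimulus = 1, ppd = 47.06, sd = 0.06,
                         sf = 10, peak = 0.27, jitter_deg = 22.5,
                         size_deg = 3.8, seed = NULL) {
  ori <- gabor_orientations(layout, postsac_stimulus, jitter_deg, seed = seed)
  grid <- display_grid(size_deg, ppd)
  img <- matrix(0, grid$npx, grid$npx)
  gab <- ori[!is.na(ori$orientation), ]
  for (i in seq_len(nrow(gab))) {
    a <- gab$orientation[i] * pi / 180
    img <- accumulate_profiles(
      img, grid, gab$x[i], gab$y[i],
      function(dx, dy) {
        carrier <- cos(2 * pi * sf * (-dx * sin(a) + dy * cos(a)))
        peak * carrier * exp(-(dx^2 + dy^2) / (2 * sd^2))
      },
      support = 4 * sd
    )
  }
  out <- new_display_image(pmin(pmax(img + 0.5, 0), 1), ppd, size_deg)
  if (!is.na(layout$target_index)) {
    tpos <- c(layout$elements$x[layout$target_index],
              layout$elements$y[layout$target_index])
    out <- render_target(out, tpos)
  }
  attr(out, "orientations") <- ori
  out
}

#' Draw the target square onto a display image
#'
#' The target is a luminance-defined square of about 0.15 degrees: at the
#' default scale of 47.06 px/deg it is 7 px wide, a 2-px border at luminance
#' 0.75 around a 3-px inner surface at luminance 0.25, centered on the pixel
#' containing the target position. Border and core widths scale with `ppd`.
#'
#' @param image A `display_image`.
#' @param position Length-2 target center in degrees (display-centered).
#' @param border_lum,core_lum Border and core luminances.
#' @return The modified `display_image`.
#' @export
render_target <- function(image, position, border_lum = 0.75,
                          core_lum = 0.25) {
  ppd <- image$ppd
  npx <- nrow(image$pixels)
  b <- max(1L, round(2 * ppd / 47.06)) # border width in px
  k <- max(1L, round(3 * ppd / 47.06)) # core width in px
  side <- 2L * b + k
  half <- npx / 2
  col0 <- floor(position[1] * ppd + half) + 1L # pixel containing the center
  row0 <- floor(half - position[2] * ppd) + 1L
  off <- (side - 1L) %/% 2L
  rows <- (row0 - off):(row0 - off + side - 1L)
  cols <- (col0 - off):(col0 - off + side - 1L)
  if (min(rows) < 1 || min(cols) < 1 || max(rows) > npx || max(cols) > npx) {
    stop("target square would exceed the image bounds")
  }
  image$pixels[rows, cols] <- border_lum
  image$pixels[rows[(b + 1):(b + k)], cols[(b + 1):(b + k)]] <- core_lum
  image
}

#' Write a display image as an 8-bit grayscale PNG
#'
#' @param image A `display_image`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_display_png <- function(image, path) {
  png::writePNG(image$pixels, path)
  invisible(path)
}

#' Read a display image from a grayscale PNG
#'
#' @param path PNG file path.
#' @param ppd Pixels per degree recorded on the returned object.
#' @return A `display_image`.
#' @export
read_display_png <- function(path, ppd = 47.06) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3) px <- px[, , 1]
  new_display_image(px, ppd, ncol(px) / ppd)
}

#' Render the full image set of one stimulus display
#'
#' Produces the six preview images (fixation, uniform, random, localized, and
#' the two contour previews) and the two postsaccadic Gabor displays of one
#' stimulus set, with sidecar metadata.
#'
#' @param layout An `element_layout` with an assigned target.
#' @param ppd Pixels per degree.
#' @param seed Optional integer seed.
#' @return A named list of `display_image`s (`fixation`, `uniform`, `random`,
#'   `localized`, `preview1`, `preview2`, `postsac1`, `postsac2`) with a
#'   `meta` tibble attached.
#' @export
render_stimulus_set <- function(layout, ppd = 47.06, seed = NULL) {
  if (!is.null(seed)) {
    return(withr::with_seed(seed, render_stimulus_set(layout, ppd,
                                                      seed = NULL)))
  }
  imgs <- list(
    fixation = render_gaussian(layout, assign_condition(layout, "fixation"),
                               ppd),
    uniform = render_gaussian(layout, assign_condition(layout, "uniform"),
                              ppd),
    random = render_gaussian(layout, assign_condition(layout, "random"), ppd),
    localized = render_gaussian(layout, assign_condition(layout, "localized"),
                                ppd),
    preview1 = render_gaussian(layout, assign_condition(layout, "same", 1),
                               ppd),
    preview2 = render_gaussian(layout, assign_condition(layout, "same", 2),
                               ppd),
    postsac1 = render_gabor(layout, 1, ppd),
    postsac2 = render_gabor(layout, 2, ppd)
  )
  attr(imgs, "meta") <- tibble::tibble(
    id = layout$id, ppd = ppd,
    target_index = layout$target_index,
    target_class = layout$target_class,
    target_x = layout$elements$x[layout$target_index],
    target_y = layout$elements$y[layout$target_index]
  )
  imgs
}

#' Plot a display image
#'
#' @param x A `display_image`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.display_image <- function(x, ...) {
  npx <- nrow(x$pixels)
  half <- npx / 2
  df <- expand.grid(
    col = seq_len(npx), row = seq_len(npx)
  )
  df$x <- (df$col - 0.5 - half) / x$ppd
  df$y <- (half - (df$row - 0.5)) / x$ppd
  df$lum <- as.vector(t(x$pixels))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$lum)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 1)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (deg)", y = "y (deg)", fill = "luminance") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
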