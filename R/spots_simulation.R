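# Synthetic spot-field images with known ground truth for the particle
# counting stage: rasterized disks on a flat background, optional tangent
# pairs that only a watershed split can separate, and additive Gaussian
# noise.

#' Spot-field rendering parameters
#'
#' @param image_size side length in pixels (default 128).
#' @param pixel_size_um pixel size in um/px (default 0.1).
#' @param n_spots isolated spots (default 20).
#' @param radius_mean_px,radius_sd_px disk radius distribution (defaults 3
#'   and 0.5; radii are clamped to >= 1.5 px).
#' @param min_separation_px minimum edge-to-edge distance between
#'   non-touching spots (default 3).
#' @param touching_pairs tangent disk pairs placed in addition to
#'   `n_spots` (default 0); each pair contributes 2 to the ground-truth
#'   count.
#' @param intensity_fg,intensity_bg foreground / background levels, a.u.
#'   (defaults 200 and 10).
#' @param noise_sd additive Gaussian noise sd, a.u. (default 5).
#' @return an object of class `spot_field_params`.
#' @export
spot_field_params <- function(image_size = 128L, pixel_size_um = 0.1,
                              n_spots = 20L, radius_mean_px = 3,
                              radius_sd_px = 0.5, min_separation_px = 3,
                              touching_pairs = 0L, intensity_fg = 200,
                              intensity_bg = 10, noise_sd = 5) {
  image_size <- check_count(image_size, "image_size", lower = 8L)
  check_number(pixel_size_um, "pixel_size_um", lower = 0,
               strict_lower = TRUE)
  n_spots <- check_count(n_spots, "n_spots", lower = 0L)
  check_number(radius_mean_px, "radius_mean_px", lower = 0,
               strict_lower = TRUE)
  check_number(radius_sd_px, "radius_sd_px", lower = 0)
  check_number(min_separation_px, "min_separation_px", lower = 0)
  touching_pairs <- check_count(touching_pairs, "touching_pairs",
                                lower = 0L)
  check_number(intensity_fg, "intensity_fg", lower = 0)
  check_number(intensity_bg, "intensity_bg", lower = 0,
               upper = intensity_fg, strict_upper = TRUE)
  check_number(noise_sd, "noise_sd", lower = 0)
  structure(list(image_size = image_size, pixel_size_um = pixel_size_um,
                 n_spots = n_spots, radius_mean_px = radius_mean_px,
                 radius_sd_px = radius_sd_px,
                 min_separation_px = min_separation_px,
                 touching_pairs = touching_pairs,
                 intensity_fg = intensity_fg,
                 intensity_bg = intensity_bg, noise_sd = noise_sd),
            class = "spot_field_params")
}

rasterize_disk <- function(img, cx, cy, r, value) {
  n <- nrow(img)
  xs <- max(1L, floor(cx - r)):min(n, ceiling(cx + r))
  ys <- max(1L, floor(cy - r)):min(ncol(img), ceiling(cy + r))
  for (x in xs) for (y in ys)
    if ((x - cx)^2 + (y - cy)^2 <= r^2) img[x, y] <- value
  img
}

disk_area_px <- function(img_size, cx, cy, r) {
  xs <- max(1L, floor(cx - r)):min(img_size, ceiling(cx + r))
  ys <- max(1L, floor(cy - r)):min(img_size, ceiling(cy + r))
  sum(outer((xs - cx)^2, (ys - cy)^2, "+") <= r^2)
}

#' Render a spot-field image with ground truth
#'
#' Isolated disks are placed by rejection sampling so that every
#' edge-to-edge distance is at least `min_separation_px`; tangent pairs
#' are placed with centre distance exactly r1 + r2 so that only a
#' watershed split separates them. Placement failure after bounded retries
#' raises an error (infeasible packing).
#'
#' @param params a [spot_field_params()].
#' @param seed integer seed.
#' @param max_tries placement attempts per spot (default 2000).
#' @return a list with `image` (matrix, a.u.), `truth` (data.frame: x, y,
#'   radius_px, area_px, pair_id), and `count` (ground-truth spot count).
#' @export
render_spot_image <- function(params = spot_field_params(), seed = 1L,
                              max_tries = 2000L) {
  stopifnot(inherits(params, "spot_field_params"))
  n <- params$image_size
  with_seed(seed, {
    centers <- data.frame(x = numeric(0), y = numeric(0),
                          r = numeric(0), pair_id = integer(0))
    margin <- function(r) r + 2
    ok_place <- function(x, y, r, touching_with = 0L) {
      if (!nrow(centers)) return(TRUE)
      d <- sqrt((centers$x - x)^2 + (centers$y - y)^2)
      lim <- centers$r + r + params$min_separation_px
      if (touching_with > 0L) lim[touching_with] <- 0
      all(d >= lim)
    }
    draw_radius <- function()
      max(1.5, stats::rnorm(1, params$radius_mean_px, params$radius_sd_px))
    place <- function(pair_id = 0L) {
      r <- draw_radius()
      for (k in seq_len(max_tries)) {
        x <- stats::runif(1, margin(r), n - margin(r))
        y <- stats::runif(1, margin(r), n - margin(r))
        if (ok_place(x, y, r)) {
          centers[nrow(centers) + 1L, ] <<- list(x, y, r, pair_id)
          return(TRUE)
        }
      }
      FALSE
    }
    place_pair <- function(pair_id) {
      r1 <- draw_radius(); r2 <- draw_radius()
      for (k in seq_len(max_tries)) {
        x1 <- stats::runif(1, margin(r1 + 2 * r2), n - margin(r1 + 2 * r2))
        y1 <- stats::runif(1, margin(r1 + 2 * r2), n - margin(r1 + 2 * r2))
        th <- stats::runif(1, 0, 2 * pi)
        x2 <- x1 + (r1 + r2) * cos(th); y2 <- y1 + (r1 + r2) * sin(th)
        if (ok_place(x1, y1, r1) && ok_place(x2, y2, r2)) {
          # re-check the pair against each other is exempted by placement
          centers[nrow(centers) + 1L, ] <<- list(x1, y1, r1, pair_id)
          if (ok_place(x2, y2, r2, touching_with = nrow(centers))) {
            centers[nrow(centers) + 1L, ] <<- list(x2, y2, r2, pair_id)
            return(TRUE)
          }
          centers <<- centers[-nrow(centers), ]
        }
      }
      FALSE
    }
    for (i in seq_len(params$n_spots))
      if (!place()) stop_invalid("infeasible spot packing after %d retries",
                                 max_tries)
    for (p in seq_len(params$touching_pairs))
      if (!place_pair(p)) stop_invalid("infeasible tangent-pair packing after %d retries",
                                       max_tries)
    img <- matrix(params$intensity_bg, n, n)
    for (i in seq_len(nrow(centers)))
      img <- rasterize_disk(img, centers$x[i], centers$y[i], centers$r[i],
                            params$intensity_fg)
    if (params$noise_sd > 0)
      img <- img + matrix(stats::rnorm(n * n, 0, params$noise_sd), n, n)
    truth <- if (nrow(centers)) data.frame(
      x = centers$x, y = centers$y, radius_px = centers$r,
      area_px = vapply(seq_len(nrow(centers)), function(i)
        disk_area_px(n, centers$x[i], centers$y[i], centers$r[i]),
        numeric(1)),
      pair_id = centers$pair_id) else
        data.frame(x = numeric(0), y = numeric(0), radius_px = numeric(0),
                   area_px = numeric(0), pair_id = integer(0))
    list(image = img, truth = truth, count = nrow(centers))
  })
}
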