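# Two-state (tethered/free) Brownian model of peroxisome motion. Each
# particle switches between a slow "tethered" and a fast "free" diffusive
# state by a two-state Markov chain; per-frame displacements are isotropic
# Gaussian with per-axis sd sqrt(2 * D_state * dt). Detections are the true
# positions jittered by the localization error and thinned by the dropout
# probability.

#' Motility simulation parameters
#'
#' @param frame_interval_s time between frames (default 0.05, i.e. one
#'   image every 50 ms).
#' @param duration_s video duration (default 120, i.e. 2-minute videos).
#' @param n_particles particles per cell (default 150; real cells carry
#'   100-300 trackable peroxisomes).
#' @param d_free_um2_s diffusion coefficient of the free state
#'   (default 0.01 um^2/s).
#' @param d_tethered_um2_s diffusion coefficient of the tethered state
#'   (default 0.001 um^2/s).
#' @param p_tethered stationary occupancy of the tethered state
#'   (default 0.7).
#' @param switch_rate_per_s total state-switching rate (default 0.1/s).
#' @param detection_dropout probability that a true position yields no
#'   detection (default 0).
#' @param localization_sd_um localization error sd per axis (default 0).
#' @param fov_um field-of-view side length; initial positions are uniform
#'   in it (default 30).
#' @return an object of class `motility_params`.
#' @export
motility_params <- function(frame_interval_s = 0.05, duration_s = 120,
                            n_particles = 150L, d_free_um2_s = 0.01,
                            d_tethered_um2_s = 0.001, p_tethered = 0.7,
                            switch_rate_per_s = 0.1,
                            detection_dropout = 0,
                            localization_sd_um = 0, fov_um = 30) {
  check_number(frame_interval_s, "frame_interval_s", lower = 0,
               strict_lower = TRUE)
  check_number(duration_s, "duration_s", lower = 0, strict_lower = TRUE)
  n_particles <- check_count(n_particles, "n_particles", lower = 1L)
  check_number(d_free_um2_s, "d_free_um2_s", lower = 0)
  check_number(d_tethered_um2_s, "d_tethered_um2_s", lower = 0)
  if (d_tethered_um2_s > d_free_um2_s)
    stop_invalid("need d_free_um2_s >= d_tethered_um2_s")
  check_number(p_tethered, "p_tethered", lower = 0, upper = 1)
  check_number(switch_rate_per_s, "switch_rate_per_s", lower = 0)
  check_number(detection_dropout, "detection_dropout", lower = 0, upper = 1)
  check_number(localization_sd_um, "localization_sd_um", lower = 0)
  check_number(fov_um, "fov_um", lower = 0, strict_lower = TRUE)
  structure(list(frame_interval_s = frame_interval_s,
                 duration_s = duration_s, n_particles = n_particles,
                 d_free_um2_s = d_free_um2_s,
                 d_tethered_um2_s = d_tethered_um2_s,
                 p_tethered = p_tethered,
                 switch_rate_per_s = switch_rate_per_s,
                 detection_dropout = detection_dropout,
                 localization_sd_um = localization_sd_um,
                 fov_um = fov_um), class = "motility_params")
}

#' Simulate a detection table with ground-truth track identities
#'
#' Each particle uses its own derived random stream, so enlarging
#' `n_particles` does not change earlier particles' trajectories.
#'
#' @param params a [motility_params()].
#' @param seed integer seed.
#' @return a list with `detections` (frame, t_s, x_um, y_um) and
#'   `ground_truth` (frame, t_s, x_um, y_um, true_track_id, state); the
#'   detections are the ground-truth rows after jitter and dropout, in
#'   frame order.
#' @export
simulate_trackset <- function(params = motility_params(), seed = 1L) {
  stopifnot(inherits(params, "motility_params"))
  dt <- params$frame_interval_s
  n_frames <- floor(params$duration_s / dt) + 1L
  # per-step transition probabilities of the two-state chain with the
  # requested stationary occupancy and total switching rate
  r <- params$switch_rate_per_s * dt
  p_f2t <- min(1, r * params$p_tethered)
  p_t2f <- min(1, r * (1 - params$p_tethered))
  sd_state <- sqrt(2 * c(tethered = params$d_tethered_um2_s,
                         free = params$d_free_um2_s) * dt)
  truth <- vector("list", params$n_particles)
  for (i in seq_len(params$n_particles)) {
    truth[[i]] <- with_seed(derive_seed(seed, i), {
      state <- integer(n_frames)  # 1 = tethered, 2 = free
      state[1] <- if (stats::runif(1) < params$p_tethered) 1L else 2L
      u <- stats::runif(n_frames - 1L)
      for (k in seq_len(n_frames - 1L)) {
        p_sw <- if (state[k] == 1L) p_t2f else p_f2t
        state[k + 1L] <- if (u[k] < p_sw) 3L - state[k] else state[k]
      }
      sds <- sd_state[state[-n_frames]]
      x <- cumsum(c(stats::runif(1, 0, params$fov_um),
                    stats::rnorm(n_frames - 1L, 0, sds)))
      y <- cumsum(c(stats::runif(1, 0, params$fov_um),
                    stats::rnorm(n_frames - 1L, 0, sds)))
      jx <- x; jy <- y
      if (params$localization_sd_um > 0) {
        jx <- x + stats::rnorm(n_frames, 0, params$localization_sd_um)
        jy <- y + stats::rnorm(n_frames, 0, params$localization_sd_um)
      }
      keep <- if (params$detection_dropout > 0)
        stats::runif(n_frames) >= params$detection_dropout else
          rep(TRUE, n_frames)
      data.frame(frame = seq_len(n_frames) - 1L,
                 t_s = (seq_len(n_frames) - 1L) * dt,
                 x_um = x, y_um = y, det_x_um = jx, det_y_um = jy,
                 true_track_id = i,
                 state = c("tethered", "free")[state],
                 detected = keep)
    })
  }
  truth <- do.call(rbind, truth)
  truth <- truth[order(truth$frame, truth$true_track_id), ]
  rownames(truth) <- NULL
  det <- truth[truth$detected,
               c("frame", "t_s", "det_x_um", "det_y_um", "true_track_id")]
  names(det) <- c("frame", "t_s", "x_um", "y_um", "true_track_id")
  rownames(det) <- NULL
  list(detections = det[, c("frame", "t_s", "x_um", "y_um")],
       ground_truth = det)
}
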