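test_that("frozen particles produce constant-position tracks", {
  p <- motility_params(n_particles = 4, duration_s = 1, d_free_um2_s = 0,
                       d_tethered_um2_s = 0)
  sim <- simulate_trackset(p, seed = 2)
  for (id in unique(sim$ground_truth$true_track_id)) {
    tr <- sim$ground_truth[sim$ground_truth$true_track_id == id, ]
    expect_equal(length(unique(tr$x_um)), 1)
    expect_equal(length(unique(tr$y_um)), 1)
  }
})

test_that("pure free diffusion obeys the Rayleigh mean-step law", {
  dt <- 0.05; d <- 0.01
  p <- motility_params(frame_interval_s = dt, duration_s = 2400 * dt,
                       n_particles = 1, d_free_um2_s = d,
                       d_tethered_um2_s = d, p_tethered = 0)
  sim <- simulate_trackset(p, seed = 11)
  tr <- sim$ground_truth
  steps <- sqrt(diff(tr$x_um)^2 + diff(tr$y_um)^2)
  expect_equal(mean(steps) / dt, sqrt(pi * d * dt) / dt, tolerance = 0.05)
})

test_that("per-axis step variance equals 2 D dt", {
  dt <- 0.05; d <- 0.02
  p <- motility_params(frame_interval_s = dt, duration_s = 1e5 * dt,
                       n_particles = 1, d_free_um2_s = d,
                       d_tethered_um2_s = d, p_tethered = 0)
  sim <- simulate_trackset(p, seed = 8)
  vx <- var(diff(sim$ground_truth$x_um))
  vy <- var(diff(sim$ground_truth$y_um))
  expect_equal(vx, 2 * d * dt, tolerance = 0.05)
  expect_equal(vy, 2 * d * dt, tolerance = 0.05)
})

test_that("particle streams are split: more particles, same early tracks", {
  p2 <- motility_params(n_particles = 2, duration_s = 1)
  p5 <- motility_params(n_particles = 5, duration_s = 1)
  s2 <- simulate_trackset(p2, seed = 31)
  s5 <- simulate_trackset(p5, seed = 31)
  early <- s5$ground_truth[s5$ground_truth$true_track_id <= 2, ]
  rownames(early) <- NULL
  expect_equal(early, s2$ground_truth)
})

test_that("motility records reproduce X beta exactly when noise vanishes", {
  truth <- lmm_truth(beta = c(`(Intercept)` = 400), sigma_subject = 0,
                     sigma_resid = 1e-12, n_subjects_per_condition = 2)
  d <- simulate_motility_dataset(truth, seed = 1)
  expect_equal(d$mean_speed_nm_s, rep(400, nrow(d)), tolerance = 1e-6)
})

test_that("the factorial design renders a full-rank interaction matrix", {
  d <- simulate_motility_dataset(lmm_truth(n_subjects_per_condition = 9),
                                 seed = 3)
  X <- model.matrix(~ sirna * noco * stimulation, d)
  expect_equal(qr(X)$rank, ncol(X))
  expect_equal(ncol(X), 12)
})

test_that("motility generator validates its design", {
  expect_error(lmm_truth(n_subjects_per_condition = 0), "n_subjects")
  expect_error(lmm_truth(beta = c(nope = 1)), "Intercept")
  expect_error(simulate_motility_dataset(
    lmm_truth(beta = c(`(Intercept)` = 1, bogus_term = 2)), 1),
    "bogus_term")
})

test_that("subject-mean variance estimates the subject variance component", {
  truth <- lmm_truth(beta = c(`(Intercept)` = 400), sigma_subject = 60,
                     sigma_resid = 50, n_subjects_per_condition = 150)
  d <- simulate_motility_dataset(truth, seed = 5)
  sm <- tapply(d$mean_speed_nm_s, d$subject, mean)
  n_per <- 3
  est <- var(sm) - truth$sigma_resid^2 / n_per
  expect_equal(est, truth$sigma_subject^2, tolerance = 0.15)
})

test_that("spot fields record exact ground truth", {
  blank <- render_spot_image(spot_field_params(n_spots = 0, noise_sd = 0),
                             seed = 1)
  expect_equal(blank$count, 0)
  expect_true(all(blank$image == 10))
  pair <- render_spot_image(spot_field_params(n_spots = 0,
                                              touching_pairs = 1,
                                              radius_mean_px = 4,
                                              radius_sd_px = 0),
                            seed = 2)
  expect_equal(pair$count, 2)
  d <- sqrt(diff(pair$truth$x)^2 + diff(pair$truth$y)^2)
  expect_equal(d, sum(pair$truth$radius_px), tolerance = 1e-9)  # tangent
  five <- render_spot_image(spot_field_params(n_spots = 5, noise_sd = 0,
                                              radius_mean_px = 3,
                                              radius_sd_px = 0),
                            seed = 3)
  expect_equal(five$count, 5)
  # rasterized pixel count: foreground area equals the summed truth areas
  expect_equal(sum(five$image > 100), sum(five$truth$area_px))
})

test_that("generators are bitwise reproducible for a fixed seed", {
  expect_identical(simulate_trackset(motility_params(n_particles = 3,
                                                     duration_s = 1), 9),
                   simulate_trackset(motility_params(n_particles = 3,
                                                     duration_s = 1), 9))
  expect_identical(simulate_motility_dataset(lmm_truth(), 9),
                   simulate_motility_dataset(lmm_truth(), 9))
  expect_identical(render_spot_image(spot_field_params(), 9),
                   render_spot_image(spot_field_params(), 9))
  expect_identical(render_fret_channels(c(1, 2), optical_params(
    noise_model = list(type = "gaussian", sd_frac = 0.05)), 9),
    render_fret_channels(c(1, 2), optical_params(
      noise_model = list(type = "gaussian", sd_frac = 0.05)), 9))
})
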