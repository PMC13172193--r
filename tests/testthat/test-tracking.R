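test_that("duplicate detections merge to centroids below the radius", {
  two_close <- data.frame(x_um = c(0, 0.02), y_um = c(0, 0))
  merged <- merge_duplicates(two_close, 0.03)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$x_um, 0.01)
  two_far <- data.frame(x_um = c(0, 0.10), y_um = c(0, 0))
  expect_equal(merge_duplicates(two_far, 0.03), two_far)
  expect_equal(merge_duplicates(two_close, 0), two_close)
  # transitive chain: each neighbour within radius, ends not
  chain <- data.frame(x_um = c(0, 0.025, 0.05), y_um = 0)
  expect_equal(nrow(merge_duplicates(chain, 0.03)), 1)
})

test_that("a stationary detection links into a single full-length track", {
  det <- data.frame(frame = 0:9, t_s = (0:9) * 0.05, x_um = 1, y_um = 2)
  tk <- link_tracks(det, linker_params())
  expect_equal(unique(tk$track_id), 1)
  expect_equal(nrow(tk), 10)
})

test_that("well-separated particles are recovered exactly", {
  steps <- (0:9) * 0.1
  det <- rbind(
    data.frame(frame = 0:9, t_s = (0:9) * 0.05, x_um = steps, y_um = 0),
    data.frame(frame = 0:9, t_s = (0:9) * 0.05, x_um = 5 + steps, y_um = 5))
  det <- det[order(det$frame), ]
  tk <- link_tracks(det, linker_params())
  expect_equal(length(unique(tk$track_id)), 2)
  for (id in unique(tk$track_id)) {
    tr <- tk[tk$track_id == id, ]
    expect_equal(nrow(tr), 10)
    expect_equal(diff(tr$x_um), rep(0.1, 9), tolerance = 1e-12)
  }
})

test_that("a jump beyond max distance splits the track at max gap 0", {
  det <- data.frame(frame = 0:4, t_s = (0:4) * 0.05,
                    x_um = c(0, 0.1, 0.2, 1.0, 1.1), y_um = 0)
  tk <- link_tracks(det, linker_params())
  expect_equal(length(unique(tk$track_id)), 2)
  expect_equal(table(tk$track_id)[[1]], 3)
  expect_equal(table(tk$track_id)[[2]], 2)
})

test_that("an unsorted or duplicated frame list errors", {
  f1 <- data.frame(frame = 1, t_s = 0.05, x_um = 0, y_um = 0)
  f0 <- data.frame(frame = 0, t_s = 0, x_um = 0, y_um = 0)
  expect_error(link_tracks(list(f1, f0), linker_params()), "increasing")
  expect_error(link_tracks(list(f0, f0), linker_params()), "increasing")
})

test_that("frame-transition assignments match the exhaustive oracle", {
  set.seed(77)
  for (rep in 1:60) {
    n <- sample(0:6, 1); m <- sample(0:6, 1)
    from <- matrix(runif(2 * n, 0, 3), ncol = 2)
    to <- matrix(runif(2 * m, 0, 3), ncol = 2)
    maxd <- runif(1, 0.3, 1.5)
    pkg <- package_match(from, to, maxd)
    orc <- oracle_match(from, to, maxd)
    expect_equal(pkg$count, orc$count)
    expect_equal(pkg$dist, orc$dist, tolerance = 1e-9)
  }
})

test_that("every detection belongs to exactly one track", {
  sim <- simulate_trackset(motility_params(n_particles = 8, duration_s = 3,
                                           detection_dropout = 0.05),
                           seed = 3)
  tk <- link_tracks(sim$detections, linker_params())
  expect_equal(nrow(tk), nrow(sim$detections))
  expect_false(any(duplicated(tk[, c("frame", "x_um", "y_um")])))
})

test_that("duration filtering keeps boundary tracks and is monotone", {
  tk <- rbind(data.frame(track_id = 1, frame = 0:40, t_s = (0:40) * 0.05,
                         x_um = 0, y_um = 0),
              data.frame(track_id = 2, frame = 0:100, t_s = (0:100) * 0.05,
                         x_um = 1, y_um = 1),
              data.frame(track_id = 3, frame = 0:120, t_s = (0:120) * 0.05,
                         x_um = 2, y_um = 2))
  f5 <- filter_tracks(tk, 5)
  expect_equal(unique(f5$track_id), c(2, 3))   # 2 s dropped, 5 s kept
  expect_equal(filter_tracks(f5, 5), f5)       # idempotent
  expect_equal(unique(filter_tracks(tk, 6)$track_id), 3)
  expect_equal(filter_tracks(tk, 0), tk)
})

test_that("speed statistics convert displacements to nm/s", {
  tk <- data.frame(track_id = 1, frame = 0:10, t_s = (0:10) * 0.05,
                   x_um = (0:10) * 0.1, y_um = 0)
  st <- track_speed_stats(tk)
  expect_equal(st$stats$mean_speed_nm_s, 2000)
  expect_equal(st$stats$n_steps, 10)
  expect_equal(st$stats$duration_s, 0.5)
  stationary <- transform(tk, x_um = 3)
  expect_equal(track_speed_stats(stationary)$stats$mean_speed_nm_s, 0)
  expect_error(track_speed_stats(tk[1, ]), "fewer than 2")
})

test_that("speed statistics are invariant to translation and rotation", {
  set.seed(12)
  tk <- data.frame(track_id = 1, frame = 0:30, t_s = (0:30) * 0.05,
                   x_um = cumsum(rnorm(31, 0, 0.05)),
                   y_um = cumsum(rnorm(31, 0, 0.05)))
  base <- track_speed_stats(tk)$stats$mean_speed_nm_s
  th <- 0.7
  rot <- transform(tk,
                   x_um = cos(th) * x_um - sin(th) * y_um + 12,
                   y_um = sin(th) * x_um + cos(th) * y_um - 4)
  expect_equal(track_speed_stats(rot)$stats$mean_speed_nm_s, base,
               tolerance = 1e-9)
})

test_that("normalization anchors tracks at the origin, steps unchanged", {
  tk <- data.frame(track_id = c(1, 1, 2, 2), frame = c(0, 1, 0, 1),
                   t_s = c(0, 0.05, 0, 0.05),
                   x_um = c(3, 3.2, -1, -1), y_um = c(4, 4.1, 2, 2))
  nm <- normalize_tracks(tk)
  expect_equal(nm$x_um[nm$track_id == 1], c(0, 0.2))
  expect_equal(nm$y_um[nm$track_id == 1], c(0, 0.1))
  expect_equal(nm$x_um[nm$track_id == 2], c(0, 0))
  expect_equal(diff(nm$x_um[nm$track_id == 1]),
               diff(tk$x_um[tk$track_id == 1]))
})

test_that("speed histograms conserve the track count", {
  st <- data.frame(mean_speed_nm_s = rep(100, 10))
  h <- speed_histogram(st)
  expect_equal(sum(h$counts), 10)
  expect_equal(sum(h$counts > 0), 1)
  set.seed(5)
  st2 <- data.frame(mean_speed_nm_s = runif(137, 0, 500))
  h2 <- speed_histogram(st2, 35)
  expect_equal(length(h2$counts), 35)
  expect_equal(sum(h2$counts), 137)
  expect_error(speed_histogram(data.frame(mean_speed_nm_s = numeric(0))),
               "no tracks")
})
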