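# Frame-to-frame linking of particle detections into trajectories and
# per-track motility statistics. Matching per frame transition is a global
# minimum-cost one-to-one assignment (Hungarian algorithm) gated at the
# maximum linking distance: it maximises the number of links among allowed
# pairs and, among those, minimises the total linking distance.

#' Linker parameters
#'
#' Defaults follow the tracker settings used for peroxisome videos: max
#' gap 0 frames, maximum linking distance 0.5 um, exclusion radius 0.03 um.
#'
#' @param max_gap frames a track may go undetected before it is closed
#'   (default 0: any miss terminates the track).
#' @param max_distance_um maximum frame-to-frame linking distance
#'   (default 0.5).
#' @param exclusion_radius_um same-frame detections closer than this are
#'   merged to their centroid before linking (default 0.03).
#' @return an object of class `linker_params`.
#' @export
linker_params <- function(max_gap = 0L, max_distance_um = 0.5,
                          exclusion_radius_um = 0.03) {
  max_gap <- check_count(max_gap, "max_gap", lower = 0L)
  check_number(max_distance_um, "max_distance_um", lower = 0,
               strict_lower = TRUE)
  check_number(exclusion_radius_um, "exclusion_radius_um", lower = 0)
  structure(list(max_gap = max_gap, max_distance_um = max_distance_um,
                 exclusion_radius_um = exclusion_radius_um),
            class = "linker_params")
}

# Hungarian algorithm for the square min-cost assignment problem.
# Returns, for each column j, the assigned row. O(n^3), deterministic.
solve_assignment <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  if (n == 0L) return(integer(0))
  u <- numeric(n)
  v <- numeric(n + 1L)        # index j+1 = column j, column 0 virtual
  p <- integer(n + 1L)        # row matched to column (0 = none)
  way <- integer(n + 1L)
  cols <- seq_len(n)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, n)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      free_ <- !used[cols + 1L]
      cur <- cost[i0, ] - u[i0] - v[cols + 1L]
      upd <- free_ & (cur < minv)
      if (any(upd)) {
        minv[upd] <- cur[upd]
        way[which(upd) + 1L] <- j0
      }
      jf <- which(free_)
      j1 <- jf[which.min(minv[jf])]
      delta <- minv[j1]
      usedj <- which(used) - 1L           # columns in the alternating tree
      u[p[usedj + 1L]] <- u[p[usedj + 1L]] + delta
      v[usedj + 1L] <- v[usedj + 1L] - delta
      minv[free_] <- minv[free_] - delta
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  p[-1L]
}

# Gated partial assignment between two point sets: maximise matches among
# pairs <= max_distance, then minimise total distance. Returns for each
# "from" row the matched "to" index or NA.
match_points <- function(from_xy, to_xy, max_distance) {
  n <- nrow(from_xy); m <- nrow(to_xy)
  if (n == 0L || m == 0L) return(rep(NA_integer_, n))
  d <- sqrt(outer(from_xy[, 1], to_xy[, 1], "-")^2 +
              outer(from_xy[, 2], to_xy[, 2], "-")^2)
  BIG <- 1e9          # forbidden pairing
  PEN <- 1e3          # cost of leaving one side unmatched
  stopifnot(max_distance < PEN)
  N <- n + m
  cost <- matrix(0, N, N)
  cost[seq_len(n), seq_len(m)] <- ifelse(d <= max_distance, d, BIG)
  cost[seq_len(n), m + seq_len(n)] <- BIG
  cost[cbind(seq_len(n), m + seq_len(n))] <- PEN
  cost[n + seq_len(m), seq_len(m)] <- BIG
  cost[cbind(n + seq_len(m), seq_len(m))] <- PEN
  rowcol <- solve_assignment(cost)      # rowcol[j] = row matched to col j
  match_of_row <- integer(N)
  match_of_row[rowcol] <- seq_len(N)
  out <- match_of_row[seq_len(n)]
  out[out > m] <- NA_integer_
  # a forbidden (> max_distance) pairing can only appear if PEN routes were
  # exhausted, which the construction prevents; guard anyway
  real <- which(!is.na(out))
  if (length(real)) out[real[d[cbind(real, out[real])] > max_distance]] <-
      NA_integer_
  out
}

#' Merge near-coincident detections within a frame
#'
#' Same-frame detections closer than the exclusion radius are duplicates
#' of one object (the radius is far below optical resolution); they are
#' merged to their centroid, transitively via single linkage, until all
#' remaining points are pairwise at least the radius apart.
#'
#' @param points matrix or data.frame with columns x_um, y_um.
#' @param exclusion_radius_um merge radius; 0 is the identity.
#' @return a data.frame with columns x_um, y_um.
#' @export
merge_duplicates <- function(points, exclusion_radius_um = 0.03) {
  check_number(exclusion_radius_um, "exclusion_radius_um", lower = 0)
  pts <- as.data.frame(points)[, c("x_um", "y_um")]
  if (exclusion_radius_um == 0 || nrow(pts) < 2L) return(pts)
  repeat {
    dd <- as.matrix(stats::dist(pts))
    if (all(dd[upper.tri(dd)] >= exclusion_radius_um)) break
    hc <- stats::hclust(stats::as.dist(dd), method = "single")
    grp <- stats::cutree(hc, h = exclusion_radius_um * (1 - 1e-12))
    pts <- do.call(rbind, lapply(split(pts, grp), function(g)
      data.frame(x_um = mean(g$x_um), y_um = mean(g$y_um))))
    rownames(pts) <- NULL
    if (nrow(pts) < 2L) break
  }
  pts
}

#' Link per-frame detections into tracks
#'
#' Per frame transition, the ends of active tracks are matched to the new
#' frame's detections by a global minimum-total-distance one-to-one
#' assignment restricted to pairs within `max_distance_um`. Unmatched
#' detections start new tracks; a track unmatched for more than `max_gap`
#' consecutive frames is closed. Duplicate detections are merged per frame
#' first (see [merge_duplicates()]).
#'
#' @param detections data.frame with columns frame, t_s, x_um, y_um, or a
#'   list of per-frame data.frames with strictly increasing unique frames.
#' @param params a [linker_params()].
#' @return a data.frame with columns track_id, frame, t_s, x_um, y_um.
#' @export
link_tracks <- function(detections, params = linker_params()) {
  stopifnot(inherits(params, "linker_params"))
  if (is.data.frame(detections)) {
    need <- c("frame", "t_s", "x_um", "y_um")
    miss <- setdiff(need, names(detections))
    if (length(miss))
      stop_invalid("detections missing column(s): %s",
                   paste(miss, collapse = ", "))
    frames <- split(detections, detections$frame)
  } else {
    idx <- vapply(detections, function(f) f$frame[1], numeric(1))
    if (any(duplicated(idx)) || is.unsorted(idx, strictly = TRUE))
      stop_invalid("frame list must have strictly increasing unique frame indices")
    frames <- detections
  }
  frame_ids <- as.integer(vapply(frames, function(f) f$frame[1], numeric(1)))
  o <- order(frame_ids)
  frames <- frames[o]; frame_ids <- frame_ids[o]

  track_rows <- list()     # finished + active track point lists
  active <- data.frame(track_id = integer(0), last_frame = integer(0),
                       x_um = numeric(0), y_um = numeric(0))
  next_id <- 1L
  add_point <- function(id, frame, t_s, x, y) {
    track_rows[[length(track_rows) + 1L]] <<-
      data.frame(track_id = id, frame = frame, t_s = t_s,
                 x_um = x, y_um = y)
  }
  for (k in seq_along(frames)) {
    f <- frames[[k]]
    pts <- merge_duplicates(f[, c("x_um", "y_um")],
                            params$exclusion_radius_um)
    fid <- frame_ids[k]
    t_s <- f$t_s[1]
    # close tracks that have been missing too long
    keep <- active$last_frame >= fid - 1L - params$max_gap
    active <- active[keep, , drop = FALSE]
    active <- active[order(active$track_id), , drop = FALSE]
    m <- match_points(as.matrix(active[, c("x_um", "y_um")]),
                      as.matrix(pts), params$max_distance_um)
    matched_det <- rep(FALSE, nrow(pts))
    for (a in seq_len(nrow(active))) {
      if (!is.na(m[a])) {
        j <- m[a]
        matched_det[j] <- TRUE
        add_point(active$track_id[a], fid, t_s, pts$x_um[j], pts$y_um[j])
        active$last_frame[a] <- fid
        active$x_um[a] <- pts$x_um[j]
        active$y_um[a] <- pts$y_um[j]
      }
    }
    for (j in which(!matched_det)) {
      add_point(next_id, fid, t_s, pts$x_um[j], pts$y_um[j])
      active <- rbind(active, data.frame(track_id = next_id,
                                         last_frame = fid,
                                         x_um = pts$x_um[j],
                                         y_um = pts$y_um[j]))
      next_id <- next_id + 1L
    }
  }
  if (!length(track_rows))
    return(data.frame(track_id = integer(0), frame = integer(0),
                      t_s = numeric(0), x_um = numeric(0),
                      y_um = numeric(0)))
  out <- do.call(rbind, track_rows)
  out <- out[order(out$track_id, out$frame), ]
  rownames(out) <- NULL
  out
}

track_durations <- function(tracks) {
  vapply(split(tracks$t_s, tracks$track_id),
         function(t) max(t) - min(t), numeric(1))
}

#' Keep tracks at least a minimum duration long
#'
#' Duration is (last - first frame time); tracks exactly at the minimum
#' are kept. Typical minima are 5 s (baseline motility) or 10 s
#' (stimulation experiments).
#'
#' @param tracks track table from [link_tracks()].
#' @param min_duration_s minimum duration in seconds (default 5).
#' @return the filtered track table.
#' @export
filter_tracks <- function(tracks, min_duration_s = 5) {
  check_number(min_duration_s, "min_duration_s", lower = 0)
  dur <- track_durations(tracks)
  keep_ids <- as.numeric(names(dur)[dur >= min_duration_s])
  out <- tracks[tracks$track_id %in% keep_ids, ]
  rownames(out) <- NULL
  out
}

#' Per-track speed statistics
#'
#' Step (instantaneous/edge) speeds are the Euclidean displacements
#' between consecutive points divided by the elapsed time, in nm/s; the
#' mean track speed is the mean of the step speeds (equal to path length /
#' duration for a uniform frame interval).
#'
#' @param tracks track table from [link_tracks()].
#' @return a list with `stats` (track_id, duration_s, n_steps,
#'   mean_speed_nm_s) and `step_speeds` (track_id, t_s, speed_nm_s).
#' @export
track_speed_stats <- function(tracks) {
  by_track <- split(tracks, tracks$track_id)
  single <- vapply(by_track, nrow, integer(1)) < 2L
  if (any(single))
    stop_invalid("track(s) %s have fewer than 2 points",
                 paste(names(by_track)[single], collapse = ", "))
  stats_rows <- lapply(by_track, function(tr) {
    tr <- tr[order(tr$frame), ]
    dt <- diff(tr$t_s)
    step <- sqrt(diff(tr$x_um)^2 + diff(tr$y_um)^2) / dt * 1000
    list(stats = data.frame(track_id = tr$track_id[1],
                            duration_s = max(tr$t_s) - min(tr$t_s),
                            n_steps = length(step),
                            mean_speed_nm_s = mean(step)),
         steps = data.frame(track_id = tr$track_id[1],
                            t_s = tr$t_s[-1], speed_nm_s = step))
  })
  out <- list(stats = do.call(rbind, lapply(stats_rows, `[[`, "stats")),
              step_speeds = do.call(rbind,
                                    lapply(stats_rows, `[[`, "steps")))
  rownames(out$stats) <- rownames(out$step_speeds) <- NULL
  out
}

#' Translate tracks to a common origin for rose plots
#'
#' Each track is shifted so its first point lies at (0, 0); no rotation or
#' scaling is applied.
#'
#' @param tracks track table from [link_tracks()].
#' @return the translated track table.
#' @export
normalize_tracks <- function(tracks) {
  out <- do.call(rbind, lapply(split(tracks, tracks$track_id), function(tr) {
    tr <- tr[order(tr$frame), ]
    tr$x_um <- tr$x_um - tr$x_um[1]
    tr$y_um <- tr$y_um - tr$y_um[1]
    tr
  }))
  rownames(out) <- NULL
  out
}

#' Histogram of mean track speeds
#'
#' Equal-width bins spanning [0, max mean speed]; counts sum to the number
#' of tracks.
#'
#' @param stats track-stats table from [track_speed_stats()]`$stats`.
#' @param n_bins number of bins (default 35).
#' @return a list with `breaks` (length n_bins + 1) and `counts`.
#' @export
speed_histogram <- function(stats, n_bins = 35L) {
  n_bins <- check_count(n_bins, "n_bins", lower = 1L)
  v <- stats$mean_speed_nm_s
  if (!length(v)) stop_invalid("no tracks to histogram")
  top <- max(v)
  if (top <= 0) top <- 1
  breaks <- seq(0, top, length.out = n_bins + 1L)
  h <- graphics::hist(v, breaks = breaks, include.lowest = TRUE,
                      right = TRUE, plot = FALSE)
  list(breaks = breaks, counts = h$counts)
}
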