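#!/usr/bin/env Rscript
# Peroxisome motility from particle tracking: simulates two-state
# (tethered/free) Brownian peroxisomes at 50 ms resolution for a
# control-like and a knock-down-like cell, links detections with the
# study's tracker settings (max gap 0, max distance 0.5 um, exclusion
# radius 0.03 um), filters short tracks and summarises speeds.

library(peroxdyn)
out_dir <- "results/analysis"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
seed <- 20260902L

conds <- list(
  NC = motility_params(n_particles = 60, duration_s = 30,
                       d_free_um2_s = 0.010, d_tethered_um2_s = 0.001,
                       p_tethered = 0.7, detection_dropout = 0.02,
                       localization_sd_um = 0.01),
  siACBD5 = motility_params(n_particles = 60, duration_s = 30,
                            d_free_um2_s = 0.010, d_tethered_um2_s = 0.001,
                            p_tethered = 0.3, detection_dropout = 0.02,
                            localization_sd_um = 0.01))

all_stats <- list()
for (cond in names(conds)) {
  sim <- simulate_trackset(conds[[cond]],
                           seed = seed + match(cond, names(conds)))
  tracks <- link_tracks(sim$detections, linker_params())
  tracks <- filter_tracks(tracks, min_duration_s = 5)
  st <- track_speed_stats(tracks)$stats
  st$condition <- cond
  all_stats[[cond]] <- st
  rose <- normalize_tracks(tracks)
  write.csv(rose, file.path(out_dir, sprintf("rose_tracks_%s.csv", cond)),
            row.names = FALSE)
  cat(sprintf("%s: %d detections -> %d tracks >= 5 s; mean of track mean speeds %.0f nm/s\n",
              cond, nrow(sim$detections), length(unique(st$track_id)),
              mean(st$mean_speed_nm_s)))
}
stats <- do.call(rbind, all_stats)
write.csv(stats, file.path(out_dir, "track_speeds.csv"), row.names = FALSE)

h <- speed_histogram(stats, n_bins = 35)
write.csv(data.frame(bin_lo = head(h$breaks, -1), bin_hi = h$breaks[-1],
                     count = h$counts),
          file.path(out_dir, "speed_histogram.csv"), row.names = FALSE)
cat(sprintf("\nSpeed histogram: 35 bins over [0, %.0f] nm/s, %d tracks total.\n",
            max(h$breaks), sum(h$counts)))
cat("The less-tethered population shifts toward higher mean track speeds,
the motility signature of a disrupted peroxisome-ER tether.\n")
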