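#!/usr/bin/env Rscript
# Peroxisomal Ca2+ uptake under the two-step SOCE protocol, on synthetic
# cells with known ground truth. Simulates control (NC) and ACBD5
# knock-down (siACBD5) populations, calibrates bleed-through on
# single-fluorophore controls, corrects ratios, extracts the three SOCE
# metrics per cell and summarises the populations.

library(peroxdyn)
out_dir <- "results/analysis"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
seed <- 20260901L

proto <- stimulation_protocol()
cat(sprintf("Protocol: %d cycles every %g s; histamine (%g uM final) after cycle %d; Ca2+ (%g mM final) after cycle %d\n",
            proto$n_cycles, proto$cycle_interval_s,
            final_concentration(proto$stock_histamine_uM,
                                proto$added_volume_fraction),
            proto$histamine_event_cycle,
            final_concentration(proto$stock_calcium_mM,
                                proto$added_volume_fraction),
            proto$calcium_event_cycle))

optics <- optical_params(noise_model = list(type = "gaussian",
                                            sd_frac = 0.01))
bt <- estimate_bleedthrough(
  render_control_channels("donor", optics, n_cells = 30, seed = seed + 1),
  render_control_channels("acceptor", optics, n_cells = 30, seed = seed + 2))
cat(sprintf("Bleed-through calibration (truth 0.57 / 0.26 / 0.02): %.4f / %.4f / %.4f\n",
            bt$bt_donor_to_fret, bt$bt_acceptor_to_fret,
            bt$bt_acceptor_to_donor))

params <- ca_dynamics_params()
sensor <- sensor_params()
metrics <- list(); groups <- character(0); ratios <- list()
for (cond in c("NC", "siACBD5")) {
  ca <- simulate_ca_traces(proto, params, cond, n_cells = 60,
                           seed = seed + match(cond, c("NC", "siACBD5")))
  for (cid in unique(ca$cell_id)) {
    tr <- ca[ca$cell_id == cid, ]
    obs <- render_fret_channels(sensor_ratio(tr$ca_perox_nM, sensor),
                                optics,
                                seed = seed + 100 + length(metrics),
                                cell_id = paste(cond, cid, sep = "_"),
                                time_s = tr$time_s)
    rt <- correct_ratio(obs, bt)
    metrics[[length(metrics) + 1L]] <- extract_soce_metrics(rt)
    ratios[[length(ratios) + 1L]] <- rt
    groups[obs$cell_id[1]] <- cond
  }
}
metrics <- do.call(rbind, metrics)
summ <- summarize_population(do.call(rbind, ratios), metrics, groups)
write.csv(metrics, file.path(out_dir, "soce_metrics_per_cell.csv"),
          row.names = FALSE)
write.csv(summ$per_cycle, file.path(out_dir, "soce_ratio_per_cycle.csv"),
          row.names = FALSE)
write.csv(summ$per_metric, file.path(out_dir, "soce_metrics_summary.csv"),
          row.names = FALSE)

cat("\nPer-group SOCE metrics (mean +/- SEM):\n")
print(summ$per_metric, digits = 3, row.names = FALSE)
for (met in c("er_response", "pm_response")) {
  tt <- t.test(metrics[[met]][groups[metrics$cell_id] == "NC"],
               metrics[[met]][groups[metrics$cell_id] == "siACBD5"])
  cat(sprintf("Welch t-test NC vs siACBD5, %s: p = %.3g\n", met, tt$p.value))
}
cat("\nThe knock-down population shows the blunted ER- and PM-based
responses built into the generator truth; the baseline is unchanged.\n")
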