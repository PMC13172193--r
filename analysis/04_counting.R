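#!/usr/bin/env Rscript
# Peroxisome counting on synthetic spot fields: IsoData threshold,
# watershed splitting of touching spots, per-ROI counts and mean areas,
# compared against the rendered ground truth.

library(peroxdyn)
out_dir <- "results/analysis"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
seed <- 20260904L

rows <- list()
for (i in 1:20) {
  sp <- spot_field_params(n_spots = 20, touching_pairs = 2,
                          radius_mean_px = 4)
  field <- render_spot_image(sp, seed = seed + i)
  roi <- matrix(1L, sp$image_size, sp$image_size)
  res <- segment_and_count(field$image, roi, sp$pixel_size_um,
                           min_area_px = 3)
  rows[[i]] <- data.frame(field = i, threshold = res$threshold,
                          count = res$per_roi$count,
                          truth = field$count,
                          mean_area_um2 = res$per_roi$mean_area_um2,
                          truth_mean_area_um2 =
                            mean(field$truth$area_px) * sp$pixel_size_um^2)
}
tab <- do.call(rbind, rows)
write.csv(tab, file.path(out_dir, "counting_vs_truth.csv"),
          row.names = FALSE)
cat(sprintf("Counted %d/%d fields exactly (24 spots each incl. 2 tangent pairs).\n",
            sum(tab$count == tab$truth), nrow(tab)))
cat(sprintf("Mean absolute area error: %.4f um^2 (watershed lines cost at most ~1 px per split).\n",
            mean(abs(tab$mean_area_um2 - tab$truth_mean_area_um2))))

# write one example image + ROI pair through the TIFF round trip
field <- render_spot_image(spot_field_params(touching_pairs = 2,
                                             radius_mean_px = 4),
                           seed = seed)
write_gray_tiff(field$image, file.path(out_dir, "example_field.tif"))
write_gray_tiff(matrix(1L, 128, 128), file.path(out_dir, "example_roi.tif"))
cat("Example field and ROI mask written as 16-bit TIFF.\n")
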