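#!/usr/bin/env Rscript
# Segment spontaneous ISC calcium events in the control and cKO presets and
# tabulate frequency (per 0.01 mm^2 per minute), duration, and area.
suppressMessages(library(tonotopy))
dir.create("results", showWarnings = FALSE)
presets <- jsonlite::read_json("results/data/presets.json", simplifyVector = TRUE)

rows <- list()
for (grp in names(presets)) {
  p <- presets[[grp]]
  for (rep in 1:3) {
    cfg <- synth_config(seed = 1000 + 10 * match(grp, names(presets)) + rep,
                        duration_s = 600, image_shape = c(128, 128),
                        pixel_scale_um = 0.83,
                        event_rate_per_min = p$event_rate_per_min,
                        event_footprint_um = p$event_footprint_um,
                        event_amplitude_dff = p$event_amplitude_dff)
    sim <- gen_isc_ihc_movie(cfg)
    grid <- make_grid_rois(sim$movie, sim$ground_truth$region_mask, 10)
    det <- extract_events(binarize_activity(grid), frame_rate_hz = 2,
                          grid_px = 10, pixel_scale_um = 0.83, dff = grid)
    area <- sum(sim$ground_truth$region_mask) * 0.83^2 / 1e6
    m <- summarize_events(det, 600, area)
    rows[[length(rows) + 1]] <- data.frame(
      group = grp, rep = rep, n_planted = length(sim$ground_truth$events),
      n_detected = m$n_events, frequency = m$frequency,
      mean_duration_s = m$mean_duration_s, mean_area_mm2 = m$mean_area_mm2)
  }
}
tab <- do.call(rbind, rows)
write.csv(tab, "results/isc_event_metrics.csv", row.names = FALSE)
print(tab, digits = 3)
agg <- aggregate(cbind(frequency, mean_duration_s, mean_area_mm2) ~ group, tab, mean)
cat("\nGroup means:\n"); print(agg, digits = 3)
cat("\nSmaller, weaker events in the cKO preset leave frequency similar while\n",
    "mean event area drops - the contrast the segmentation is built to expose.\n")
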