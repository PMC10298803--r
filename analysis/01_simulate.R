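#!/usr/bin/env Rscript
# Build the synthetic study cohort: a control-like and a Cx26-deficient-like
# preset for every recording modality.  The presets differ only in event
# rate / footprint / amplitude (cochlear imaging) and in planted audiometric
# thresholds; everything downstream (02-07) consumes these conditions.
suppressMessages(library(tonotopy))
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

presets <- list(
  control = list(event_rate_per_min = 2.0, event_footprint_um = 40,
                 event_amplitude_dff = 0.5, abr_threshold_db = 35,
                 dpoae_threshold_db = 40),
  cko     = list(event_rate_per_min = 2.4, event_footprint_um = 24,
                 event_amplitude_dff = 0.35, abr_threshold_db = 85,
                 dpoae_threshold_db = 90)
)
jsonlite::write_json(presets, "results/data/presets.json",
                     auto_unbox = TRUE, digits = NA)

# Audiometric series are cheap; write them out as CSV for 06_audiometry.R.
for (grp in names(presets)) {
  p <- presets[[grp]]
  abr <- gen_abr_series(seq(0, 100, 5), p$abr_threshold_db,
                        growth_uv_per_db = 0.1, background_pp_sd_uv = 1,
                        seed = 100 + match(grp, names(presets)))
  write_abr_series(abr$series, sprintf("results/data/abr_%s.csv", grp))
  dp <- gen_dpoae_spectra(16000, seq(20, 100, 5), p$dpoae_threshold_db,
                          seed = 200 + match(grp, names(presets)))
  write_dpoae_series(dp$series, sprintf("results/data/dpoae_%s.csv", grp))
  cat(sprintf("%s: ABR planted %g dB, DPOAE planted %g dB written\n",
              grp, p$abr_threshold_db, p$dpoae_threshold_db))
}

# Evoked widefield stimulus log (7 tones x 4 repeats, 5 s spacing at 2 Hz).
freqs <- round(3000 * 2^(0:6 * 0.5))
sched <- data.frame(freq_hz = rep(freqs, each = 4), level_db = 80,
                    onset_frame = seq(10, by = 10, length.out = 28))
write_stim_log(sched, "results/data/evoked_stim_log.csv")
cat("evoked stimulus log:", nrow(sched), "presentations,",
    length(freqs), "frequencies\n")
cat("done; movies are regenerated on demand by their seeds (see presets.json)\n")
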