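test_that("configurations validate their parameters", {
  expect_s3_class(synth_config(), "synth_config")
  expect_error(synth_config(duration_s = 0))
  expect_error(synth_config(frame_rate_hz = -1))
  expect_error(synth_config(event_amplitude_dff = 0))
  # footprint larger than the ISC region is rejected
  cfg <- synth_config(image_shape = c(40, 40), pixel_scale_um = 1,
                      event_footprint_um = 60)
  expect_error(gen_isc_ihc_movie(cfg), "footprint")
})

test_that("identical seeds give identical outputs; seeds leave the RNG alone", {
  cfg <- synth_config(seed = 42, duration_s = 30, image_shape = c(48, 48),
                      pixel_scale_um = 1, event_footprint_um = 12)
  a <- gen_isc_ihc_movie(cfg)
  set.seed(999); before <- runif(3)
  set.seed(999)
  b <- gen_isc_ihc_movie(cfg)
  after <- runif(3)
  expect_identical(a$movie$data, b$movie$data)
  expect_identical(a$ground_truth$events, b$ground_truth$events)
  expect_identical(before, after)  # generator does not disturb the caller RNG

  s1 <- gen_sgn_traces(cfg, n_rois = 8, kcl_onset_s = 25)
  s2 <- gen_sgn_traces(cfg, n_rois = 8, kcl_onset_s = 25)
  expect_identical(s1$traces, s2$traces)
  t1 <- gen_2p_tuning(n_cells = 10, seed = 5)
  t2 <- gen_2p_tuning(n_cells = 10, seed = 5)
  expect_identical(t1$tensor$responses, t2$tensor$responses)
})

test_that("planted ISC events are recovered exactly from noiseless movies", {
  cfg <- synth_config(seed = 1, duration_s = 120, frame_rate_hz = 2,
                      image_shape = c(64, 64), pixel_scale_um = 1,
                      noise_sd_dff = 0)
  # one rectangular event aligned to grid squares: 8 ROIs, known frames
  ev <- list(list(rect = c(41, 50, 11, 50), start = 60, amplitude = 0.5))
  sim <- gen_isc_ihc_movie(cfg, events = ev)
  grid <- make_grid_rois(sim$movie, sim$ground_truth$region_mask, 10)
  det <- extract_events(binarize_activity(grid), frame_rate_hz = 2,
                        grid_px = 10, pixel_scale_um = 1, dff = grid)
  expect_length(det, 1)
  expect_equal(det[[1]]$n_rois, 8)  # 40 x 10 px footprint spans 8 squares
  expect_equal(det[[1]]$start_frame, 60)
  # the final decay frame may sit below the median + 3 SD binarization level;
  # the detected extent must stay within the planted window and span >= 3 frames
  expect_lte(det[[1]]$end_frame, sim$ground_truth$events[[1]]$end_frame)
  expect_gte(det[[1]]$end_frame, det[[1]]$start_frame + 2)

  # event_rate = 0: baseline only, no events planted or detected
  cfg0 <- synth_config(seed = 2, duration_s = 60, image_shape = c(64, 64),
                       pixel_scale_um = 1, event_rate_per_min = 0,
                       event_footprint_um = 16, noise_sd_dff = 0)
  sim0 <- gen_isc_ihc_movie(cfg0)
  expect_length(sim0$ground_truth$events, 0)
  g0 <- make_grid_rois(sim0$movie, sim0$ground_truth$region_mask, 10)
  expect_length(extract_events(binarize_activity(g0)), 0)
})

test_that("the generator's realized event count matches its event log", {
  cfg <- synth_config(seed = 1, duration_s = 600, event_rate_per_min = 2,
                      image_shape = c(96, 96), pixel_scale_um = 1,
                      event_footprint_um = 16)
  sim <- gen_isc_ihc_movie(cfg)
  n <- length(sim$ground_truth$events)
  # the draw is Poisson(20): the log must match the draw, and the draw must
  # be plausible under the planted rate (5 sigma)
  expect_true(abs(n - 20) <= 5 * sqrt(20))
  expect_equal(n, with_seed_pois(cfg$seed, 20))
})

test_that("IHC coupling follows event footprints", {
  cfg <- synth_config(seed = 3, duration_s = 60, image_shape = c(64, 64),
                      pixel_scale_um = 1, noise_sd_dff = 0)
  ev <- list(list(rect = c(33, 45, 1, 32), start = 40, amplitude = 0.6))
  sim <- gen_isc_ihc_movie(cfg, events = ev, n_ihc = 10)
  gt <- sim$ground_truth$events[[1]]
  # coupled IHCs are exactly those with centers inside the footprint x-range
  expect_equal(gt$ihc_ids, which(sim$ihc$centers_x >= 1 & sim$ihc$centers_x <= 32))
  # their traces rise during the event, others stay flat
  nd <- normalize_dff(sim$ihc$traces, "roi_median")
  peaks_in <- apply(nd$values[gt$ihc_ids, 40:47, drop = FALSE], 1, max)
  expect_true(all(peaks_in > 0.3))
  others <- setdiff(seq_len(10), gt$ihc_ids)
  expect_true(all(apply(nd$values[others, , drop = FALSE], 1, max) < 0.05))
})

test_that("SGN generator controls K+ responders and burst synchrony", {
  cfg0 <- synth_config(seed = 8, duration_s = 600, frame_rate_hz = 2,
                       noise_sd_dff = 0)
  cfg <- synth_config(seed = 8, duration_s = 600, frame_rate_hz = 2,
                      noise_sd_dff = 0.02)
  # all responsive at 0.5 dF/F: the filter keeps everyone
  s <- gen_sgn_traces(cfg0, n_rois = 12, kcl_onset_s = 540)
  win <- s$ground_truth$kcl_frame:ncol(s$traces)
  expect_equal(filter_sgn_by_kcl(s$traces, win), 1:12)
  # half the ROIs respond at 0.05 (below 10%): exactly the other half kept
  s2 <- gen_sgn_traces(cfg0, n_rois = 12, kcl_onset_s = 540,
                       responsive_fraction = 0.5)
  expect_equal(filter_sgn_by_kcl(s2$traces, win), 1:6)
  expect_equal(s2$ground_truth$responsive, rep(c(TRUE, FALSE), each = 6))
  # synchrony increases with the burst-sharing parameter
  hi <- gen_sgn_traces(cfg, n_rois = 15, kcl_onset_s = 540, rho = 0.9)
  lo <- gen_sgn_traces(synth_config(seed = 9, duration_s = 600, frame_rate_hz = 2,
                                    noise_sd_dff = 0.02),
                       n_rois = 15, kcl_onset_s = 540, rho = 0)
  pre <- 1:1000
  expect_gt(correlation_summary(hi$traces[, pre])$summary,
            correlation_summary(lo$traces[, pre])$summary + 0.3)
})

test_that("widefield generator rejects invalid geometry and schedules", {
  cfg <- synth_config(seed = 1, duration_s = 30, image_shape = c(64, 64))
  expect_error(gen_widefield_ic(cfg, band_angle_deg = 120), "0, 90")
  sched <- data.frame(freq_hz = 4000, level_db = 80, onset_frame = 100)
  expect_error(gen_widefield_ic(cfg, tone_schedule = sched), "beyond")
})

test_that("evoked widefield responses recover the planted threshold", {
  lv <- seq(40, 100, by = 10)
  sched <- data.frame(freq_hz = rep(8000, length(lv) * 2),
                      level_db = rep(lv, each = 2),
                      onset_frame = seq(10, by = 12, length.out = length(lv) * 2))
  cfg <- synth_config(seed = 4, duration_s = 100, frame_rate_hz = 2,
                      image_shape = c(96, 96), noise_sd_dff = 0,
                      event_rate_per_min = 0)
  w <- gen_widefield_ic(cfg, tone_schedule = sched, planted_threshold_db = 70)
  nd <- normalize_dff(w$movie$data, "pixel_p10")
  tm <- unmix_tone_responses(nd$values, w$stim_log, 2,
                             roi_mask = w$ground_truth$left_mask)
  r <- tm$responses[order(tm$responses$level_db), ]
  # monotone rate-level function under a monotone planted function
  expect_true(all(diff(r$amplitude) >= -1e-9))
  # threshold at the planted half-maximum convention
  th <- response_threshold(r$level_db, r$amplitude,
                           criterion = w$ground_truth$resp_amp_max / 2)
  expect_lte(abs(th$threshold_db - 70), 10)
})

test_that("crenation generator rejects impossible layouts and scales areas", {
  cfg <- synth_config(seed = 2, duration_s = 40, image_shape = c(128, 128),
                      pixel_scale_um = 0.5)
  expect_error(gen_crenation_movie(cfg, n_regions = 10), "without overlap")
  cr <- gen_crenation_movie(cfg, n_regions = 1, region_area_um2 = 400)
  # 400 um^2 at 0.5 um/px: 40 x 40 px square
  expect_equal(cr$ground_truth$regions[[1]]$area_um2, 400)
  expect_equal(crenation_area(length(cr$ground_truth$regions[[1]]$pixels), 0.5),
               400)
})

test_that("tuning generator validates inputs and plants recoverable BFs", {
  expect_error(gen_2p_tuning(freqs_hz = c(4000)), "at least 2")
  expect_error(gen_2p_tuning(levels_db = 50), "at least 2")
  g <- gen_2p_tuning(n_cells = 100, noise_sd_frac = 0, seed = 2)
  bf <- vapply(1:100, function(i) best_frequency(g$tensor, i)$bf_hz, 1)
  expect_equal(bf, g$ground_truth$bf_hz)
})
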