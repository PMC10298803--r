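test_that("bilateral IC events are detected with correct dominance", {
  cfg <- synth_config(seed = 7, duration_s = 60, frame_rate_hz = 2,
                      image_shape = c(128, 128), noise_sd_dff = 0,
                      event_rate_per_min = 1)
  w <- gen_widefield_ic(cfg, band_sigma_px = 5)
  gt <- w$ground_truth
  nd <- normalize_dff(w$movie$data, "pixel_p10")
  ev <- detect_ic_events(nd$values, gt$left_mask, gt$right_mask,
                         frame_rate_hz = 2)
  expect_equal(nrow(ev), nrow(gt$events))  # noiseless rate recovery is exact
  expect_equal(ev$peak_frame, gt$events$frame)
  expect_equal(ev$left_amp, gt$events$left_amp, tolerance = 1e-6)
  expect_equal(ev$dominant,
               ifelse(gt$events$left_amp >= gt$events$right_amp, "left", "right"))
})

test_that("forced left dominance and sub-threshold events behave as planted", {
  dff <- array(0, dim = c(60, 64, 64))
  left <- matrix(FALSE, 64, 64); left[20:45, 5:28] <- TRUE
  right <- matrix(FALSE, 64, 64); right[20:45, 36:59] <- TRUE
  add_ev <- function(dff, f, la, ra) {
    for (k in -2:2) {
      wgt <- exp(-k^2 / 2)
      dff[f + k, , ][left] <- dff[f + k, , ][left] + la * wgt
      dff[f + k, , ][right] <- dff[f + k, , ][right] + ra * wgt
    }
    dff
  }
  for (f in c(10, 25, 40)) dff <- add_ev(dff, f, 0.03, 0.015)  # left 2x right
  ev <- detect_ic_events(dff, left, right, frame_rate_hz = 2)
  expect_equal(ev$dominant, rep("left", 3))
  # amplitude 0.5% is below the 1% threshold
  dff2 <- add_ev(array(0, dim = c(60, 64, 64)), 30, 0.005, 0.005)
  expect_equal(nrow(detect_ic_events(dff2, left, right, frame_rate_hz = 2)), 0)
})

test_that("rotated line scans recover planted band geometry", {
  # uniform image: constant profile
  ls <- tonotopic_linescan(matrix(0.3, 80, 80), center = c(40, 40),
                           length_px = 30, width_px = 9, angle_deg = 45)
  expect_equal(as.vector(ls), rep(0.3, 30), tolerance = 1e-12)

  # axis-aligned band at angle 0: exact column means
  img <- matrix(0, 80, 80); img[, 41:43] <- 1
  ls0 <- tonotopic_linescan(img, center = c(40, 40), length_px = 21,
                            width_px = 5, angle_deg = 0)
  expect_equal(as.vector(ls0), as.numeric(seq(30, 50) %in% 41:43))

  # planted Gaussian band perpendicular to a 45-degree axis: peak within 1 px
  # of the position predicted from the band equation
  th <- 45 * pi / 180
  cy <- 40; cx <- 40; u0 <- 6; sig <- 3
  g <- expand.grid(y = 1:80, x = 1:80)
  u <- (g$x - cx) * cos(th) + (g$y - cy) * sin(th)
  img2 <- matrix(exp(-(u - u0)^2 / (2 * sig^2)), 80, 80)
  ls2 <- tonotopic_linescan(img2, center = c(cy, cx), length_px = 41,
                            width_px = 9, angle_deg = 45)
  # u = 0 maps to position (41+1)/2 = 21
  expect_lte(abs(which.max(ls2[, 1]) - (21 + u0)), 1)
  expect_error(tonotopic_linescan(img2, center = c(5, 5), length_px = 41,
                                  width_px = 9, angle_deg = 45), "outside")
})

test_that("band events are regional maxima above the fixed threshold", {
  pos <- 1:50; fr <- 1:40
  bump <- outer(exp(-(pos - 20)^2 / 18), exp(-(fr - 15)^2 / 8)) * 0.05
  ev <- detect_band_events(bump, threshold = 0.02)
  expect_equal(nrow(ev), 1)
  expect_equal(c(ev$position, ev$frame), c(20, 15))
  expect_equal(nrow(detect_band_events(matrix(0.001, 20, 20))), 0)

  # random smooth fields match an exhaustive all-neighbors scan
  set.seed(19)
  for (rep in 1:5) {
    f <- matrix(rnorm(30 * 30), 30)
    f <- EBImage::gblur(f, 2)  # smooth => distinct values, no plateaus
    ev2 <- detect_band_events(f, threshold = 0.01)
    oracle <- NULL
    for (i in 2:29) for (j in 2:29) {
      nb <- f[(i - 1):(i + 1), (j - 1):(j + 1)]
      if (f[i, j] > 0.01 && f[i, j] == max(nb))
        oracle <- rbind(oracle, c(i, j))
    }
    # interior maxima must agree exactly (border handled by definition)
    ev2i <- ev2[ev2$position %in% 2:29 & ev2$frame %in% 2:29, ]
    expect_equal(nrow(ev2i), nrow(oracle))
    expect_setequal(paste(ev2i$position, ev2i$frame),
                    paste(oracle[, 1], oracle[, 2]))
  }
})

test_that("band width follows the 75th-percentile-of-peak rule", {
  prof <- c(rep(0, 10), rep(1, 7), rep(0, 10))
  expect_equal(band_width(prof), 7)
  # scale invariance
  expect_equal(band_width(prof * 0.37), 7)
  # Gaussian closed form: 2*sigma*sqrt(2*ln(4/3))
  for (sig in c(3, 5, 10)) {
    x <- seq_len(200)
    g <- exp(-(x - 100)^2 / (2 * sig^2))
    expect_lte(abs(band_width(g) - 2 * sig * sqrt(2 * log(4 / 3))), 1)
  }
  # width is measured about the global peak only
  two <- c(rep(0, 5), rep(0.9, 4), rep(0, 5), rep(1, 6), rep(0, 5))
  expect_equal(band_width(two), 6)
  expect_error(band_width(rep(0, 10)), "positive")
})

test_that("spatial integral is the trapezoidal rule and is linear", {
  expect_equal(spatial_integral(rep(2, 100)), 2 * 99)
  expect_equal(spatial_integral(c(0, 1, 0)), 1)
  set.seed(3)
  y <- rnorm(57)
  expect_equal(spatial_integral(y), sum((y[-1] + y[-57]) / 2))
  z <- rnorm(57)
  expect_equal(spatial_integral(2 * y + 3 * z),
               2 * spatial_integral(y) + 3 * spatial_integral(z))
})

test_that("tone unmixing averages repeats and recovers amplitudes", {
  T <- 200; fr <- 2
  dff <- array(0, dim = c(T, 32, 32))
  onsets <- seq(10, by = 12, length.out = 12)
  log <- data.frame(freq_hz = rep(c(4000, 8000, 16000), each = 4),
                    level_db = 80, onset_frame = onsets)
  for (o in onsets) for (k in 0:4) dff[o + k, 10:20, 10:20] <- 0.1 * exp(-k / 2)
  tm <- unmix_tone_responses(dff, log, fr)
  expect_equal(nrow(tm$responses), 3)
  expect_equal(tm$responses$n_repeats, rep(4, 3))
  roi_frac <- 121 / 1024  # response dilution over the whole-frame ROI
  expect_equal(tm$responses$amplitude, rep(0.1 * roi_frac, 3), tolerance = 1e-10)

  # identical repeats: mean equals a single response
  expect_equal(tm$segments[[1]][, 15, 15],
               dff[(onsets[1] - 2):(onsets[1] + 6), 15, 15])

  # zero-mean noise averaged over 4 repeats shrinks SD by 2
  set.seed(29)
  sds <- replicate(20, {
    dn <- array(rnorm(T * 4 * 4, 0, 0.05), dim = c(T, 4, 4))
    tn <- unmix_tone_responses(dn, log, fr)
    sd(tn$segments[[1]])
  })
  expect_equal(mean(sds), 0.05 / 2, tolerance = 0.05)

  # overlapping windows rejected
  bad <- data.frame(freq_hz = 4000, level_db = 80, onset_frame = c(20, 24))
  expect_error(unmix_tone_responses(dff, bad, fr), "overlapping")
})

test_that("evoked thresholds interpolate like the ABR rule", {
  lv <- seq(40, 100, by = 10)
  amp <- c(0, 0, 0.05, 0.10, 0.15, 0.20, 0.25)
  r <- response_threshold(lv, amp, criterion = 0.10)
  # exact crossing at a tested level
  expect_equal(r$threshold_db, 70)
  expect_false(r$no_response)
  r2 <- response_threshold(lv, rep(0.001, 7), criterion = 0.10)
  expect_true(r2$no_response)
  # noiseless linear growth crossing between tested levels: closed form
  amp3 <- pmax(0, 0.004 * (lv - 55))
  r3 <- response_threshold(lv, amp3, criterion = 0.05)
  expect_equal(r3$threshold_db, 55 + 0.05 / 0.004)
})

test_that("activated area counts supra-threshold pixels times pixel area", {
  img <- matrix(0.2, 100, 100)
  expect_equal(activated_area(img, pixel_scale_um = 10), 1.0)
  expect_equal(activated_area(matrix(0.1, 100, 100), 10), 0)
  # planted disk within 5% of pi r^2
  r <- 18
  g <- expand.grid(y = 1:100, x = 1:100)
  disk <- matrix(as.numeric((g$y - 50)^2 + (g$x - 50)^2 <= r^2), 100, 100) * 0.3
  expect_equal(activated_area(disk, 10), pi * (r * 10 / 1000)^2, tolerance = 0.05)
})

test_that("tonotopic peak positions track planted maps and references", {
  freqs <- c(3000, 6000, 12000, 24000)
  profs <- t(vapply(seq_along(freqs), function(i) {
    exp(-(1:100 - (20 + 15 * (i - 1)))^2 / 50)
  }, numeric(100)))
  ps <- tonotopic_peak_shift(profs, freqs)
  expect_equal(ps$peak_position, c(20, 35, 50, 65))
  expect_equal(ps$shift_vs_lowest, c(0, 15, 30, 45))
  fit <- lm(ps$peak_position ~ log2(ps$freq_hz))
  expect_gt(suppressWarnings(summary(fit))$r.squared, 0.99)
  # identical profiles: zero shifts; ties flagged
  same <- matrix(rep(c(rep(0, 10), 1, 1, rep(0, 8)), 3), 3, byrow = TRUE)
  ps2 <- tonotopic_peak_shift(same, c(1, 2, 4) * 1000)
  expect_equal(ps2$shift_vs_lowest, rep(0, 3))
  expect_true(all(ps2$tie))
})
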