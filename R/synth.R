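#' Synthetic recording configuration
#'
#' Shared parameter block for the seeded generators.  Defaults emulate the
#' pre-hearing cochlear imaging conditions this package targets: 2 Hz frame
#' rate, 10-minute recordings, and a 0.83 um/px scale (a 512 x 512 px field
#' spanning 425 um), at a desk-scale 128 x 128 px field of view.
#'
#' @param seed RNG seed; identical configurations reproduce identical outputs.
#' @param duration_s recording length (s).
#' @param frame_rate_hz frame rate (Hz).
#' @param image_shape c(y, x) frame size in pixels.
#' @param pixel_scale_um micrometres per pixel.
#' @param event_rate_per_min spontaneous event rate (events/min).
#' @param event_footprint_um mean spatial extent of an event along each axis
#'   (um).
#' @param event_amplitude_dff peak event amplitude (dF/F).
#' @param noise_sd_dff Gaussian noise SD (dF/F units).
#' @param bleach_tau_s photobleach time constant (s; 0 = none).
#' @return object of class `synth_config`.
#' @export
synth_config <- function(seed = 1, duration_s = 600, frame_rate_hz = 2,
                         image_shape = c(128, 128), pixel_scale_um = 0.83,
                         event_rate_per_min = 2, event_footprint_um = 40,
                         event_amplitude_dff = 0.5, noise_sd_dff = 0.05,
                         bleach_tau_s = 0) {
  stopifnot(duration_s > 0, frame_rate_hz > 0, length(image_shape) == 2,
            all(image_shape >= 20), pixel_scale_um > 0,
            event_rate_per_min >= 0, event_footprint_um > 0,
            event_amplitude_dff > 0, noise_sd_dff >= 0, bleach_tau_s >= 0)
  structure(list(seed = as.integer(seed), duration_s = duration_s,
                 frame_rate_hz = frame_rate_hz, image_shape = image_shape,
                 pixel_scale_um = pixel_scale_um,
                 event_rate_per_min = event_rate_per_min,
                 event_footprint_um = event_footprint_um,
                 event_amplitude_dff = event_amplitude_dff,
                 noise_sd_dff = noise_sd_dff, bleach_tau_s = bleach_tau_s),
            class = "synth_config")
}

# Trapezoidal event time course: half-amplitude rise frame, full-amplitude
# plateau, linear decay.  Simplest shape compatible with the >= 3 frame
# duration filter.
trapezoid_profile <- function(plateau_frames = 4, decay_frames = 3) {
  c(0.5, rep(1, plateau_frames), rev(seq_len(decay_frames)) / (decay_frames + 1))
}

ellipse_pixels <- function(Y, X, cy, cx, ry, rx) {
  yy <- max(1, floor(cy - ry)):min(Y, ceiling(cy + ry))
  xx <- max(1, floor(cx - rx)):min(X, ceiling(cx + rx))
  g <- expand.grid(y = yy, x = xx)
  keep <- ((g$y - cy) / ry)^2 + ((g$x - cx) / rx)^2 <= 1
  g <- g[keep, , drop = FALSE]
  g$y + (g$x - 1) * Y  # linear indices within a frame
}

#' Synthetic ISC-sheet calcium movie with coupled hair-cell transients
#'
#' Generates a movie of stochastic inner-supporting-cell calcium events on the
#' lower half of the frame (the ISC region), with a row of oval IHC ROIs along
#' the region border whose cells receive coupled transients whenever an event
#' footprint reaches them.  Events have flat elliptical spatial footprints and
#' a trapezoidal time course; the movie is baseline fluorescence times
#' (1 + dF/F signal), with optional exponential photobleach and Gaussian
#' noise.
#'
#' @param config a [synth_config()].
#' @param n_ihc number of IHC oval ROIs (default 20).
#' @param events optional explicit event list overriding the random draw; each
#'   element is a list with `start`, `amplitude`, and either `rect =
#'   c(y0, y1, x0, x1)` or `cy, cx, ry, rx`, plus optional `plateau`.
#' @param plateau_frames,decay_frames trapezoid shape (defaults 4 and 3).
#' @param coupling_prob probability that an IHC over an event footprint fires
#'   (default 1).
#' @param baseline_f baseline fluorescence (arbitrary units, default 100).
#' @return list with `movie` ([calcium_movie()]), `ihc` (list: `traces` raw
#'   ROI x time matrix, `centers`, `pixels`), and `ground_truth` (planted
#'   events with member pixels, frames, amplitudes and coupled IHC ids, plus
#'   the region mask).
#' @export
gen_isc_ihc_movie <- function(config, n_ihc = 20, events = NULL,
                              plateau_frames = 4, decay_frames = 3,
                              coupling_prob = 1, baseline_f = 100) {
  stopifnot(inherits(config, "synth_config"))
  Y <- config$image_shape[1]; X <- config$image_shape[2]
  T <- round(config$duration_s * config$frame_rate_hz)
  reg_top <- floor(Y / 2) + 1
  region <- matrix(FALSE, Y, X); region[reg_top:Y, ] <- TRUE
  half_px <- config$event_footprint_um / config$pixel_scale_um / 2
  if (is.null(events) && 2 * half_px > min(Y - reg_top + 1, X))
    stop("event footprint larger than the ISC region")
  prof <- trapezoid_profile(plateau_frames, decay_frames)
  ihc_y <- reg_top - 6
  ihc_cx <- seq(5, X - 5, length.out = n_ihc)
  ihc_pix <- lapply(ihc_cx, function(cx) ellipse_pixels(Y, X, ihc_y, cx, 4, 2))

  out <- with_local_seed(config$seed, {
    if (is.null(events)) {
      n_ev <- stats::rpois(1, config$event_rate_per_min * config$duration_s / 60)
      events <- vector("list", n_ev)
      for (i in seq_len(n_ev)) {
        r <- half_px * stats::runif(1, 0.8, 1.2)
        events[[i]] <- list(
          cy = stats::runif(1, reg_top + r, Y - r),
          cx = stats::runif(1, 1 + r, X - r),
          ry = r, rx = r,
          start = sample.int(max(1, T - length(prof)), 1),
          amplitude = config$event_amplitude_dff)
      }
    }
    dff <- array(0, dim = c(T, Y, X))
    gt_events <- list()
    for (ev in events) {
      p <- if (is.null(ev$plateau)) prof else trapezoid_profile(ev$plateau, decay_frames)
      if (!is.null(ev$rect)) {
        g <- expand.grid(y = ev$rect[1]:ev$rect[2], x = ev$rect[3]:ev$rect[4])
        pix <- g$y + (g$x - 1) * Y
        xr <- c(ev$rect[3], ev$rect[4])
      } else {
        pix <- ellipse_pixels(Y, X, ev$cy, ev$cx, ev$ry, ev$rx)
        xr <- c(ev$cx - ev$rx, ev$cx + ev$rx)
      }
      pix <- pix[region[pix]]
      frames <- ev$start:min(T, ev$start + length(p) - 1)
      for (k in seq_along(frames))
        dff[frames[k], , ][pix] <- dff[frames[k], , ][pix] + ev$amplitude * p[k]
      coupled <- which(ihc_cx >= xr[1] & ihc_cx <= xr[2])
      coupled <- coupled[stats::runif(length(coupled)) <= coupling_prob]
      for (j in coupled) for (k in seq_along(frames))
        dff[frames[k], , ][ihc_pix[[j]]] <-
          dff[frames[k], , ][ihc_pix[[j]]] + ev$amplitude * p[k]
      gt_events[[length(gt_events) + 1]] <-
        list(start_frame = ev$start, end_frame = frames[length(frames)],
             pixels = pix, peak_dff = ev$amplitude, ihc_ids = coupled)
    }
    t_s <- (seq_len(T) - 1) / config$frame_rate_hz
    bleach <- if (config$bleach_tau_s > 0) exp(-t_s / config$bleach_tau_s) else rep(1, T)
    data <- baseline_f * (1 + dff) * bleach
    if (config$noise_sd_dff > 0)
      data <- data + stats::rnorm(length(data), 0, config$noise_sd_dff * baseline_f)
    data[data < 0] <- 0
    list(data = data, gt_events = gt_events)
  })
  movie <- calcium_movie(out$data, config$frame_rate_hz, config$pixel_scale_um)
  M <- matrix(out$data, nrow = T)
  ihc_traces <- do.call(rbind, lapply(ihc_pix, function(p)
    rowMeans(M[, p, drop = FALSE])))
  list(movie = movie,
       ihc = list(traces = ihc_traces, centers_x = ihc_cx, center_y = ihc_y,
                  pixels = ihc_pix),
       ground_truth = list(events = out$gt_events, region_mask = region,
                           n_frames = T, config = config))
}

#' Synthetic spiral ganglion neuron traces with a high-K+ control
#'
#' Traces contain correlated burst transients (each shared burst recruits a
#' ROI with probability `rho`, plus independent private bursts at rate
#' `(1 - rho)` x the burst rate) and a terminal sustained high-K+ response in
#' the responsive fraction of ROIs.
#'
#' @param config a [synth_config()] (duration, frame rate, noise used).
#' @param n_rois number of neurons (>= 2).
#' @param kcl_onset_s K+ wash onset (s), within the recording.
#' @param responsive_fraction fraction of ROIs given a supra-criterion K+
#'   response.
#' @param rho burst-sharing probability in [0, 1] controlling pairwise
#'   synchrony.
#' @param burst_rate_per_min shared burst rate.
#' @param burst_amp burst amplitude (dF/F).
#' @param kcl_amp,kcl_amp_nonresponsive K+ response amplitudes (dF/F).
#' @return list with `traces` (ROI x time dF/F), `frame_rate_hz`, and
#'   `ground_truth` (`responsive` logical vector, burst times).
#' @export
gen_sgn_traces <- function(config, n_rois = 30, kcl_onset_s = 540,
                           responsive_fraction = 1, rho = 0.7,
                           burst_rate_per_min = 6, burst_amp = 0.3,
                           kcl_amp = 0.5, kcl_amp_nonresponsive = 0.05) {
  stopifnot(inherits(config, "synth_config"))
  if (n_rois < 2) stop("need at least 2 ROIs")
  T <- round(config$duration_s * config$frame_rate_hz)
  kcl_frame <- round(kcl_onset_s * config$frame_rate_hz)
  if (kcl_frame < 1 || kcl_frame > T) stop("kcl_onset_s outside the recording")
  kernel <- c(0.5, 1, exp(-(1:6) / 2))
  n_resp <- round(responsive_fraction * n_rois)
  with_local_seed(config$seed, {
    n_burst <- stats::rpois(1, burst_rate_per_min * kcl_onset_s / 60)
    burst_frames <- sort(sample.int(max(1, kcl_frame - length(kernel)), n_burst))
    traces <- matrix(0, n_rois, T)
    add_burst <- function(tr, f) {
      idx <- f:min(T, f + length(kernel) - 1)
      tr[idx] <- tr[idx] + burst_amp * kernel[seq_along(idx)]
      tr
    }
    for (i in seq_len(n_rois)) {
      for (f in burst_frames) if (stats::runif(1) <= rho)
        traces[i, ] <- add_burst(traces[i, ], f)
      n_priv <- stats::rpois(1, (1 - rho) * burst_rate_per_min * kcl_onset_s / 60)
      for (f in sample.int(max(1, kcl_frame - length(kernel)), n_priv))
        traces[i, ] <- add_burst(traces[i, ], f)
      amp_k <- if (i <= n_resp) kcl_amp else kcl_amp_nonresponsive
      ramp <- pmin(1, (seq_len(T) - kcl_frame) / (10 * config$frame_rate_hz))
      ramp[ramp < 0] <- 0
      traces[i, ] <- traces[i, ] + amp_k * ramp
    }
    if (config$noise_sd_dff > 0)
      traces <- traces + matrix(stats::rnorm(length(traces), 0, config$noise_sd_dff),
                                n_rois, T)
    list(traces = traces, frame_rate_hz = config$frame_rate_hz,
         ground_truth = list(responsive = seq_len(n_rois) <= n_resp,
                             burst_frames = burst_frames,
                             kcl_frame = kcl_frame))
  })
}

# Oval IC masks and tonotopic axis geometry for the widefield generator.
ic_geometry <- function(Y, X, angle_deg) {
  mk <- function(cx) {
    cy <- Y / 2
    ry <- 0.30 * Y; rx <- 0.22 * X
    g <- expand.grid(y = seq_len(Y), x = seq_len(X))
    mask <- matrix(((g$y - cy) / ry)^2 + ((g$x - cx) / rx)^2 <= 1, Y, X)
    list(center = c(cy, cx), ry = ry, rx = rx, mask = mask,
         angle_deg = angle_deg, axis_len = 1.4 * min(ry, rx))
  }
  list(left = mk(X * 0.27), right = mk(X * 0.73))
}

# Gaussian iso-frequency band image inside one IC oval: amplitude at pixel
# (y, x) depends on its projection u onto the tonotopic axis.  The image is
# scaled so its mean over the oval mask equals `amp`: planted amplitudes are
# ROI-mean dF/F, the quantity the whole-IC peak detector measures.
band_image <- function(Y, X, side, pos_frac, sigma_px, amp) {
  th <- side$angle_deg * pi / 180
  g <- expand.grid(y = seq_len(Y), x = seq_len(X))
  u <- (g$x - side$center[2]) * cos(th) + (g$y - side$center[1]) * sin(th)
  u0 <- (pos_frac - 0.5) * side$axis_len
  img <- matrix(exp(-(u - u0)^2 / (2 * sigma_px^2)), Y, X) * side$mask
  img * (amp / mean(img[side$mask]))
}

#' Synthetic widefield inferior-colliculus movie
#'
#' Spontaneous mode (`tone_schedule = NULL`) plants band-shaped bilateral
#' events: each event has a position drawn along the tonotopic axis, a
#' Gaussian cross-section of `band_sigma_px`, independent log-normal left and
#' right amplitudes, and a Gaussian time course.  Evoked mode plants one
#' response band per scheduled tone whose position is linear in log2
#' frequency and whose amplitude follows a sigmoid of level about the planted
#' threshold (threshold = half-maximum level).
#'
#' @param config a [synth_config()].
#' @param band_angle_deg tonotopic axis angle, in [0, 90] degrees.
#' @param tone_schedule optional data.frame (`freq_hz`, `level_db`,
#'   `onset_frame`) switching to evoked mode.
#' @param band_sigma_px Gaussian cross-section sigma (px).
#' @param amp_meanlog,amp_sdlog log-normal amplitude parameters for
#'   spontaneous events (dF/F).
#' @param event_fwhm_s temporal full width at half maximum of a spontaneous
#'   event (s).
#' @param planted_threshold_db,level_slope_db,resp_amp_max evoked rate-level
#'   sigmoid: amplitude = `resp_amp_max * plogis((level - threshold) /
#'   slope)`.
#' @param baseline_f baseline fluorescence.
#' @return list with `movie`, `stim_log` (evoked mode, else NULL) and
#'   `ground_truth` (event table or tone response table, axis geometry per
#'   side, masks).
#' @export
gen_widefield_ic <- function(config, band_angle_deg = 50, tone_schedule = NULL,
                             band_sigma_px = 5, amp_meanlog = log(0.05),
                             amp_sdlog = 0.4, event_fwhm_s = 2,
                             planted_threshold_db = 70, level_slope_db = 5,
                             resp_amp_max = 0.2, baseline_f = 100) {
  stopifnot(inherits(config, "synth_config"))
  if (band_angle_deg < 0 || band_angle_deg > 90)
    stop("band_angle_deg must lie in [0, 90]")
  Y <- config$image_shape[1]; X <- config$image_shape[2]
  T <- round(config$duration_s * config$frame_rate_hz)
  geo <- ic_geometry(Y, X, band_angle_deg)
  sig_t <- event_fwhm_s * config$frame_rate_hz / 2.355
  out <- with_local_seed(config$seed, {
    dff <- array(0, dim = c(T, Y, X))
    if (is.null(tone_schedule)) {
      n_ev <- stats::rpois(1, config$event_rate_per_min * config$duration_s / 60)
      ev <- data.frame(
        frame = sort(sample.int(T, n_ev, replace = TRUE)),
        pos_frac = stats::runif(n_ev, 0.15, 0.85),
        left_amp = stats::rlnorm(n_ev, amp_meanlog, amp_sdlog),
        right_amp = stats::rlnorm(n_ev, amp_meanlog, amp_sdlog))
      for (i in seq_len(nrow(ev))) {
        imgL <- band_image(Y, X, geo$left, ev$pos_frac[i], band_sigma_px, ev$left_amp[i])
        imgR <- band_image(Y, X, geo$right, ev$pos_frac[i], band_sigma_px, ev$right_amp[i])
        img <- imgL + imgR
        fr <- max(1, ev$frame[i] - ceiling(3 * sig_t)):min(T, ev$frame[i] + ceiling(3 * sig_t))
        w <- exp(-(fr - ev$frame[i])^2 / (2 * sig_t^2))
        for (k in seq_along(fr)) dff[fr[k], , ] <- dff[fr[k], , ] + w[k] * img
      }
      gt <- list(mode = "spontaneous", events = ev, band_sigma_px = band_sigma_px)
      log <- NULL
    } else {
      stopifnot(all(c("freq_hz", "level_db", "onset_frame") %in% names(tone_schedule)))
      post <- round(3 * config$frame_rate_hz)
      if (any(tone_schedule$onset_frame + post > T))
        stop("tone schedule frames beyond movie length")
      fr_rng <- log2(range(tone_schedule$freq_hz))
      posmap <- function(f) {
        if (diff(fr_rng) == 0) return(0.5)
        0.15 + 0.7 * (log2(f) - fr_rng[1]) / diff(fr_rng)
      }
      decay <- exp(-(0:post) / config$frame_rate_hz)
      for (i in seq_len(nrow(tone_schedule))) {
        amp <- resp_amp_max *
          stats::plogis((tone_schedule$level_db[i] - planted_threshold_db) / level_slope_db)
        img <- band_image(Y, X, geo$left, posmap(tone_schedule$freq_hz[i]),
                          band_sigma_px, amp) +
          band_image(Y, X, geo$right, posmap(tone_schedule$freq_hz[i]),
                     band_sigma_px, amp)
        fr <- tone_schedule$onset_frame[i] + 0:post
        for (k in seq_along(fr)) dff[fr[k], , ] <- dff[fr[k], , ] + decay[k] * img
      }
      gt <- list(mode = "evoked",
                 positions = data.frame(freq_hz = sort(unique(tone_schedule$freq_hz)),
                                        pos_frac = posmap(sort(unique(tone_schedule$freq_hz)))),
                 planted_threshold_db = planted_threshold_db,
                 level_slope_db = level_slope_db, resp_amp_max = resp_amp_max,
                 band_sigma_px = band_sigma_px)
      log <- tone_schedule
    }
    data <- baseline_f * (1 + dff)
    if (config$bleach_tau_s > 0) {
      t_s <- (seq_len(T) - 1) / config$frame_rate_hz
      data <- data * exp(-t_s / config$bleach_tau_s)
    }
    if (config$noise_sd_dff > 0)
      data <- data + stats::rnorm(length(data), 0, config$noise_sd_dff * baseline_f)
    data[data < 0] <- 0
    list(data = data, gt = gt, log = log)
  })
  gt <- out$gt
  gt$geometry <- lapply(geo, function(s) s[c("center", "angle_deg", "axis_len")])
  gt$left_mask <- geo$left$mask; gt$right_mask <- geo$right$mask
  list(movie = calcium_movie(out$data, config$frame_rate_hz, config$pixel_scale_um),
       stim_log = out$log, ground_truth = gt)
}

#' Synthetic averaged ABR waveform family
#'
#' One averaged waveform per stimulus level: a damped-sine wavelet in the
#' post-stimulus analysis window whose peak-to-peak amplitude grows linearly
#' with level, plus pre-stimulus background segments whose peak-to-peak
#' amplitudes are drawn with the stated mean and SD.  The planted threshold is
#' the level at which the expected signal amplitude crosses the expected
#' detection criterion (background mean + 2 SD), so threshold recovery error
#' reflects criterion estimation alone.
#'
#' @param levels_db ascending stimulus levels.
#' @param planted_threshold_db planted threshold, strictly inside the level
#'   range.
#' @param growth_uv_per_db amplitude growth slope (> 0).
#' @param background_pp_sd_uv background peak-to-peak SD (uV).
#' @param seed RNG seed.
#' @param background_pp_mean_uv background peak-to-peak mean (uV).
#' @param fs_hz,dur_ms,onset_ms waveform timing; background segments of 1 ms
#'   tile the pre-stimulus interval.
#' @return list with `series` ([abr_series()]) and `ground_truth`
#'   (`planted_threshold_db`, `criterion_true_uv`, `growth_uv_per_db`).
#' @export
gen_abr_series <- function(levels_db, planted_threshold_db,
                           growth_uv_per_db = 0.1, background_pp_sd_uv = 1,
                           seed = 1, background_pp_mean_uv = 3,
                           fs_hz = 25000, dur_ms = 10, onset_ms = 5) {
  if (growth_uv_per_db <= 0) stop("growth must be positive")
  if (is.unsorted(levels_db)) stop("levels must be ascending")
  if (planted_threshold_db <= min(levels_db) || planted_threshold_db >= max(levels_db))
    stop("planted threshold must lie strictly inside the level range")
  n <- round(dur_ms * fs_hz / 1000)
  onset <- round(onset_ms * fs_hz / 1000)
  seg_len <- round(fs_hz / 1000)  # 1 ms
  n_seg <- onset %/% seg_len
  bg_windows <- lapply(seq_len(n_seg), function(i) ((i - 1) * seg_len + 1):(i * seg_len))
  sig_window <- (onset + 1):n
  tw <- seq_along(sig_window) / fs_hz
  wavelet <- sin(2 * pi * 1000 * tw) * exp(-tw / 0.002)
  wavelet <- wavelet / (max(wavelet) - min(wavelet))  # unit peak-to-peak
  crit_true <- background_pp_mean_uv + 2 * background_pp_sd_uv
  onset_level <- planted_threshold_db - crit_true / growth_uv_per_db
  with_local_seed(seed, {
    wf <- matrix(0, length(levels_db), n)
    for (i in seq_along(levels_db)) {
      s <- max(0, growth_uv_per_db * (levels_db[i] - onset_level))
      wf[i, sig_window] <- s * wavelet
      for (w in bg_windows) {
        # one positive and one negative excursion with exact peak-to-peak pp
        pp <- max(0, stats::rnorm(1, background_pp_mean_uv, background_pp_sd_uv))
        at <- sample(w, 2)
        wf[i, at[1]] <- pp / 2
        wf[i, at[2]] <- -pp / 2
      }
    }
    list(series = abr_series(levels_db, wf, fs_hz, sig_window, bg_windows),
         ground_truth = list(planted_threshold_db = planted_threshold_db,
                             criterion_true_uv = crit_true,
                             growth_uv_per_db = growth_uv_per_db,
                             onset_level_db = onset_level))
  })
}

#' Synthetic DPOAE spectrum family
#'
#' Per-level spectra with primaries at `f1 = 0.909 fc` and `f2 = 1.09 fc`, a
#' cubic distortion product at `2 f1 - f2` whose level grows above the planted
#' threshold, and a flat noise floor with the stated SD.  As with
#' [gen_abr_series()], the planted threshold is the level at which the
#' expected DP amplitude crosses the expected noise criterion (floor + 2 SD).
#'
#' @param fc_hz center frequency (1-50 kHz).
#' @param levels_db ascending primary levels.
#' @param planted_threshold_db planted threshold inside the level range, or
#'   `Inf` for an absent distortion product.
#' @param noise_floor_db flat noise floor (dB SPL).
#' @param seed RNG seed.
#' @param growth_db_per_db DP growth above threshold (default 1).
#' @param noise_sd_db noise floor SD (dB).
#' @param primary_level_db displayed primary level.
#' @return list with `series` ([dpoae_series()]) and `ground_truth`.
#' @export
gen_dpoae_spectra <- function(fc_hz, levels_db, planted_threshold_db,
                              noise_floor_db = 0, seed = 1,
                              growth_db_per_db = 1, noise_sd_db = 1,
                              primary_level_db = 60) {
  if (fc_hz < 1000 || fc_hz > 50000) stop("fc outside the audio range (1-50 kHz)")
  if (is.unsorted(levels_db)) stop("levels must be ascending")
  fr <- dpoae_frequencies(fc_hz)
  freqs <- seq(0.4 * fc_hz, 1.4 * fc_hz, length.out = 401)
  crit_true <- noise_floor_db + 2 * noise_sd_db
  with_local_seed(seed, {
    sp <- matrix(stats::rnorm(length(levels_db) * length(freqs),
                              noise_floor_db, noise_sd_db),
                 length(levels_db), length(freqs))
    i1 <- nearest_index(freqs, fr$f1); i2 <- nearest_index(freqs, fr$f2)
    idp <- nearest_index(freqs, fr$f_dp)
    sp[, i1] <- primary_level_db
    sp[, i2] <- primary_level_db
    for (i in seq_along(levels_db)) {
      d <- crit_true + growth_db_per_db * (levels_db[i] - planted_threshold_db)
      if (is.finite(d) && d > noise_floor_db) sp[i, idp] <- d
    }
    list(series = dpoae_series(fc_hz, freqs, levels_db, sp),
         ground_truth = list(planted_threshold_db = planted_threshold_db,
                             criterion_true_db = crit_true,
                             f_dp = fr$f_dp, dp_bin = idp))
  })
}

#' Synthetic transmitted-light crenation movie
#'
#' A bright-field movie at 1 frame/s in which square patches darken over
#' `rise_s` seconds at staggered onsets, emulating osmotic crenation of the
#' supporting-cell epithelium.  Patches are laid out on a grid with at least
#' `min_separation_px` between borders; configurations that cannot be placed
#' are rejected.
#'
#' @param config a [synth_config()] (duration, image shape, pixel scale,
#'   noise used; frame rate forced to 1 Hz).
#' @param n_regions number of crenation patches.
#' @param region_area_um2 planted patch area (um^2).
#' @param depth_frac fractional darkening at full crenation (default 0.3).
#' @param rise_s darkening time course (s).
#' @param min_separation_px minimum border-to-border patch separation.
#' @param baseline_f baseline transmitted intensity.
#' @return list with `movie` (1 Hz [calcium_movie()]) and `ground_truth`
#'   (per-region pixel sets, onset frames, areas).
#' @export
gen_crenation_movie <- function(config, n_regions = 5, region_area_um2 = 2500,
                                depth_frac = 0.3, rise_s = 4,
                                min_separation_px = 50, baseline_f = 100) {
  stopifnot(inherits(config, "synth_config"))
  Y <- config$image_shape[1]; X <- config$image_shape[2]
  T <- round(config$duration_s)  # 1 frame per second
  side <- round(sqrt(region_area_um2) / config$pixel_scale_um)
  pitch <- side + min_separation_px
  ncol_fit <- max(0, (X - min_separation_px - side) %/% pitch + 1)
  nrow_fit <- max(0, (Y - min_separation_px - side) %/% pitch + 1)
  if (n_regions > ncol_fit * nrow_fit)
    stop("cannot place ", n_regions, " patches of side ", side,
         " px without overlap; enlarge the frame or shrink the patches")
  regions <- list()
  if (n_regions > 0) {
    slots <- expand.grid(r = seq_len(nrow_fit), c = seq_len(ncol_fit))[seq_len(n_regions), ]
    onsets <- round(seq(6, max(7, T - rise_s - 6), length.out = max(1, n_regions)))
    for (i in seq_len(n_regions)) {
      y0 <- min_separation_px %/% 2 + (slots$r[i] - 1) * pitch + 1
      x0 <- min_separation_px %/% 2 + (slots$c[i] - 1) * pitch + 1
      g <- expand.grid(y = y0:(y0 + side - 1), x = x0:(x0 + side - 1))
      regions[[i]] <- list(pixels = g$y + (g$x - 1) * Y, onset_frame = onsets[i],
                           area_um2 = side^2 * config$pixel_scale_um^2)
    }
  }
  data <- with_local_seed(config$seed, {
    d <- array(baseline_f, dim = c(T, Y, X))
    for (rg in regions) {
      ramp <- pmin(1, pmax(0, (seq_len(T) - rg$onset_frame) / rise_s))
      for (t in which(ramp > 0))
        d[t, , ][rg$pixels] <- d[t, , ][rg$pixels] - depth_frac * baseline_f * ramp[t]
    }
    if (config$noise_sd_dff > 0)
      d <- d + stats::rnorm(length(d), 0, config$noise_sd_dff * baseline_f)
    d[d < 0] <- 0
    d
  })
  list(movie = calcium_movie(data, 1, config$pixel_scale_um),
       ground_truth = list(regions = regions, side_px = side,
                           depth_frac = depth_frac, rise_s = rise_s))
}

#' Synthetic two-photon tuning tensor
#'
#' Per-cell peak responses `amp * Gauss(log2 f; BF, sigma) * plogis((level -
#' threshold)/slope)` plus Gaussian noise.  Cells either share one parameter
#' set with BFs sampled from the tested frequencies, or are drawn from
#' `archetypes` (a list of parameter sets with `n` cells each) for response-
#' pattern clustering studies.
#'
#' @param n_cells number of cells (ignored when `archetypes` given).
#' @param freqs_hz tested frequencies (default 4-64 kHz, 9 half-octave steps).
#' @param levels_db tested levels (default 30-90 dB SPL in 20 dB steps).
#' @param sigma_octaves,threshold_db,slope_db,amp shared tuning parameters.
#' @param noise_sd_frac noise SD as a fraction of `amp`.
#' @param seed RNG seed.
#' @param archetypes optional list of lists, each with `n`, `bf_hz`,
#'   `sigma_octaves`, `threshold_db`, `slope_db`, `amp`.
#' @return list with `tensor` ([tuning_tensor()]) and `ground_truth` (per-cell
#'   `bf_hz`, `sigma_octaves`, `threshold_db`, `group`).
#' @export
gen_2p_tuning <- function(n_cells = 200,
                          freqs_hz = 4000 * 2^seq(0, 4, by = 0.5),
                          levels_db = seq(30, 90, by = 20),
                          sigma_octaves = 0.5, threshold_db = 50,
                          slope_db = 10, amp = 1, noise_sd_frac = 0.05,
                          seed = 1, archetypes = NULL) {
  if (length(freqs_hz) < 2 || length(levels_db) < 2)
    stop("need at least 2 frequencies and 2 levels")
  with_local_seed(seed, {
    if (is.null(archetypes)) {
      bf <- sample(freqs_hz[2:(length(freqs_hz) - 1)], n_cells, replace = TRUE)
      pars <- data.frame(bf_hz = bf, sigma_octaves = sigma_octaves,
                         threshold_db = threshold_db, slope_db = slope_db,
                         amp = amp, group = 1L)
    } else {
      pars <- do.call(rbind, lapply(seq_along(archetypes), function(g) {
        a <- archetypes[[g]]
        data.frame(bf_hz = a$bf_hz, sigma_octaves = a$sigma_octaves,
                   threshold_db = a$threshold_db, slope_db = a$slope_db,
                   amp = a$amp, group = g)[rep(1, a$n), ]
      }))
      n_cells <- nrow(pars)
    }
    resp <- array(0, dim = c(n_cells, length(freqs_hz), length(levels_db)))
    for (i in seq_len(n_cells)) {
      tune_f <- exp(-(log2(freqs_hz) - log2(pars$bf_hz[i]))^2 /
                      (2 * pars$sigma_octaves[i]^2))
      gain_l <- stats::plogis((levels_db - pars$threshold_db[i]) / pars$slope_db[i])
      resp[i, , ] <- pars$amp[i] * outer(tune_f, gain_l)
    }
    if (noise_sd_frac > 0)
      resp <- resp + array(stats::rnorm(length(resp), 0,
                                        noise_sd_frac * mean(pars$amp)),
                           dim = dim(resp))
    list(tensor = tuning_tensor(resp, freqs_hz, levels_db),
         ground_truth = pars)
  })
}
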