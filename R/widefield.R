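#' Detect spontaneous bilateral inferior-colliculus events
#'
#' Mean dF/F traces are formed over the left and right IC ROI masks, peaks are
#' detected on each with a fixed threshold and minimum amplitude (1% dF/F by
#' default), and peaks on opposite sides within `match_window_s` are paired
#' into one bilateral event.  The dominant side is the larger amplitude; the
#' half-width is the full width at half maximum of the dominant-side
#' transient.
#'
#' @param dff 3D dF/F array (time x y x x).
#' @param left_mask,right_mask disjoint logical ROI masks.
#' @param frame_rate_hz frame rate (Hz).
#' @param threshold,min_amp fixed peak threshold and minimum amplitude (dF/F).
#' @param match_window_s bilateral matching window (default 1 s).
#' @return data.frame, one row per event: `peak_frame`, `left_amp`,
#'   `right_amp`, `dominant` ("left"/"right"), `half_width_s`.
#' @export
detect_ic_events <- function(dff, left_mask, right_mask, frame_rate_hz,
                             threshold = 0.01, min_amp = 0.01,
                             match_window_s = 1) {
  dff <- dff_values(dff)
  stopifnot(length(dim(dff)) == 3)
  if (any(left_mask & right_mask)) stop("left and right ROIs must be disjoint")
  T <- dim(dff)[1]
  M <- matrix(dff, nrow = T)
  lt <- rowMeans(M[, as.vector(left_mask), drop = FALSE])
  rt <- rowMeans(M[, as.vector(right_mask), drop = FALSE])
  lp <- detect_peaks(lt, threshold = threshold, min_amplitude = min_amp)
  rp <- detect_peaks(rt, threshold = threshold, min_amplitude = min_amp)
  win <- round(match_window_s * frame_rate_hz)
  used_r <- rep(FALSE, nrow(rp))
  rows <- list()
  for (i in seq_len(nrow(lp))) {
    j <- which(!used_r & abs(rp$frame - lp$frame[i]) <= win)
    if (length(j)) {
      j <- j[which.min(abs(rp$frame[j] - lp$frame[i]))]
      used_r[j] <- TRUE
      la <- lp$amplitude[i]; ra <- rp$amplitude[j]
      pf <- if (la >= ra) lp$frame[i] else rp$frame[j]
    } else {
      la <- lp$amplitude[i]; ra <- rt[lp$frame[i]]
      pf <- lp$frame[i]
    }
    rows[[length(rows) + 1]] <- c(pf, la, ra)
  }
  for (j in which(!used_r)) rows[[length(rows) + 1]] <-
      c(rp$frame[j], lt[rp$frame[j]], rp$amplitude[j])
  if (!length(rows)) return(data.frame(peak_frame = integer(), left_amp = numeric(),
                                       right_amp = numeric(), dominant = character(),
                                       half_width_s = numeric()))
  m <- do.call(rbind, rows)
  ord <- order(m[, 1])
  m <- m[ord, , drop = FALSE]
  dominant <- ifelse(m[, 2] >= m[, 3], "left", "right")
  hw <- vapply(seq_len(nrow(m)), function(i) {
    tr <- if (dominant[i] == "left") lt else rt
    fwhm_frames(tr, m[i, 1]) / frame_rate_hz
  }, 1)
  data.frame(peak_frame = m[, 1], left_amp = m[, 2], right_amp = m[, 3],
             dominant = dominant, half_width_s = hw)
}

# Full width at half max of the transient around `frame` (contiguous run
# above half the peak value).
fwhm_frames <- function(trace, frame) {
  half <- trace[frame] / 2
  l <- frame; while (l > 1 && trace[l - 1] > half) l <- l - 1
  r <- frame; while (r < length(trace) && trace[r + 1] > half) r <- r + 1
  r - l + 1
}

#' Rotated rectangular line scan along the tonotopic axis
#'
#' Samples a rotated rectangle (long axis = tonotopic axis) from each frame by
#' bilinear interpolation and averages across the short axis, producing a
#' positions-by-time line-scan profile.
#'
#' @param dff 3D dF/F array (time x y x x) or a single y-by-x frame.
#' @param center (y, x) rectangle center in pixels.
#' @param length_px long-axis length in sample positions (default 100).
#' @param width_px short-axis width in samples (default 25).
#' @param angle_deg rotation of the long axis from the image x-axis, degrees.
#' @param interp `"bilinear"` (default) or `"nearest"`.
#' @return object of class `linescan_profile`: matrix positions x frames plus
#'   geometry attributes.
#' @export
tonotopic_linescan <- function(dff, center, length_px = 100, width_px = 25,
                               angle_deg = 50, interp = c("bilinear", "nearest")) {
  interp <- match.arg(interp)
  dff <- dff_values(dff)
  if (length(dim(dff)) == 2) dff <- array(dff, dim = c(1, dim(dff)))
  stopifnot(length(dim(dff)) == 3, length(center) == 2)
  th <- angle_deg * pi / 180
  u <- seq_len(length_px) - (length_px + 1) / 2
  v <- seq_len(width_px) - (width_px + 1) / 2
  g <- expand.grid(u = u, v = v)
  # long axis direction (cos, sin) in (x, y); short axis perpendicular
  xs <- center[2] + g$u * cos(th) - g$v * sin(th)
  ys <- center[1] + g$u * sin(th) + g$v * cos(th)
  if (interp == "nearest") { xs <- round(xs); ys <- round(ys) }
  ny <- dim(dff)[2]; nx <- dim(dff)[3]
  if (any(ys < 1 | ys > ny | xs < 1 | xs > nx))
    stop("rotated rectangle falls outside the frame")
  T <- dim(dff)[1]
  prof <- matrix(NA_real_, length_px, T)
  for (t in seq_len(T)) {
    vals <- bilinear_sample(dff[t, , ], ys, xs)
    prof[, t] <- rowMeans(matrix(vals, nrow = length_px))
  }
  structure(prof, class = c("linescan_profile", "matrix"),
            center = center, angle_deg = angle_deg, width_px = width_px)
}

#' Detect band events as regional maxima of a line-scan profile
#'
#' 2D regional maxima (8-neighborhood, plateaus counted once at their
#' centroid) of the positions-by-time profile above a fixed threshold; each
#' maximum is one event sample.
#'
#' @param profile positions x time matrix (e.g. from [tonotopic_linescan()]).
#' @param threshold fixed dF/F threshold (default 0.02).
#' @return data.frame with `position`, `frame`, `amplitude`.
#' @export
detect_band_events <- function(profile, threshold = 0.02) {
  m <- unclass(profile)
  rm_ <- regional_maxima(m, threshold = threshold)
  data.frame(position = rm_$row, frame = rm_$col, amplitude = rm_$value)
}

#' Band width above the 75th percentile of the peak
#'
#' The spatial profile is normalized to its maximum and the band width is the
#' number of contiguous positions about the peak whose normalized value
#' exceeds `frac` (default 0.75), optionally converted to physical length.
#'
#' @param profile numeric vector (spatial profile at the event frame).
#' @param frac normalized cut level (default 0.75).
#' @param spacing physical distance between positions (default 1 position).
#' @return width in `spacing` units.
#' @export
band_width <- function(profile, frac = 0.75, spacing = 1) {
  if (all(profile <= 0)) stop("profile peak must be positive")
  norm <- profile / max(profile)
  i0 <- which.max(norm)
  l <- i0; while (l > 1 && norm[l - 1] > frac) l <- l - 1
  r <- i0; while (r < length(norm) && norm[r + 1] > frac) r <- r + 1
  (r - l + 1) * spacing
}

#' Trapezoidal spatial integral of a profile
#'
#' @param profile numeric vector (dF/F per position).
#' @param spacing position spacing (default 1).
#' @return integral in dF/F x position units.
#' @export
spatial_integral <- function(profile, spacing = 1) {
  stopifnot(all(is.finite(profile)))
  pracma::trapz(seq_along(profile) * spacing, profile)
}

#' Unmix and average tone-evoked responses
#'
#' Splits a dF/F movie by stimulus, aligns segments from `pre_s` before to
#' `post_s` after each tone onset, and averages across the repeats of each
#' (frequency, level) combination.  The summary amplitude is the peak of the
#' mean ROI trace in the post-onset window minus the mean of the pre-onset
#' baseline.
#'
#' @param dff 3D dF/F array (time x y x x).
#' @param stim_log data.frame with columns `freq_hz`, `level_db`,
#'   `onset_frame` (a `stim_id` column is optional).
#' @param frame_rate_hz frame rate (Hz).
#' @param pre_s,post_s alignment window (defaults 1 s and 3 s).
#' @param roi_mask optional logical mask for the summary trace (default whole
#'   frame).
#' @return list of class `tone_response_map`: `responses` data.frame
#'   (`freq_hz`, `level_db`, `n_repeats`, `amplitude`) and `segments`, a list
#'   of mean aligned movie segments in the same order.
#' @export
unmix_tone_responses <- function(dff, stim_log, frame_rate_hz,
                                 pre_s = 1, post_s = 3, roi_mask = NULL) {
  dff <- dff_values(dff)
  stopifnot(length(dim(dff)) == 3,
            all(c("freq_hz", "level_db", "onset_frame") %in% names(stim_log)))
  T <- dim(dff)[1]
  pre <- round(pre_s * frame_rate_hz); post <- round(post_s * frame_rate_hz)
  on <- sort(stim_log$onset_frame)
  if (any(diff(on) < pre + post + 1)) stop("overlapping analysis windows")
  if (any(stim_log$onset_frame - pre < 1 | stim_log$onset_frame + post > T))
    stop("aligned window outside the recording")
  if (is.null(roi_mask)) roi_mask <- matrix(TRUE, dim(dff)[2], dim(dff)[3])
  combos <- unique(stim_log[, c("freq_hz", "level_db")])
  combos <- combos[order(combos$freq_hz, combos$level_db), , drop = FALSE]
  segs <- list(); amp <- numeric(nrow(combos)); nrep <- integer(nrow(combos))
  for (i in seq_len(nrow(combos))) {
    sel <- stim_log$freq_hz == combos$freq_hz[i] &
      stim_log$level_db == combos$level_db[i]
    onsets <- stim_log$onset_frame[sel]
    nrep[i] <- length(onsets)
    acc <- NULL
    for (o in onsets) {
      seg <- dff[(o - pre):(o + post), , , drop = FALSE]
      acc <- if (is.null(acc)) seg else acc + seg
    }
    seg <- acc / nrep[i]
    segs[[i]] <- seg
    Tm <- dim(seg)[1]
    tr <- rowMeans(matrix(seg, nrow = Tm)[, as.vector(roi_mask), drop = FALSE])
    amp[i] <- max(tr[(pre + 1):Tm]) - mean(tr[1:pre])
  }
  structure(list(responses = cbind(combos, n_repeats = nrep, amplitude = amp),
                 segments = segs, pre_frames = pre, post_frames = post),
            class = "tone_response_map")
}

#' Tone-evoked response threshold from a rate-level function
#'
#' The threshold is the lowest level at which the evoked amplitude exceeds the
#' criterion (`baseline_mean + 2 * baseline_sd` unless `criterion` is given),
#' with linear interpolation between the bracketing levels, mirroring the ABR
#' rule; a censored no-response sentinel is returned when no level crosses.
#'
#' @param levels_db tested levels (dB SPL).
#' @param amplitudes evoked summary amplitudes, one per level.
#' @param baseline_mean,baseline_sd pre-stimulus baseline statistics.
#' @param k SD multiplier (default 2).
#' @param criterion optional explicit criterion overriding the baseline rule.
#' @return `threshold_result` list, see [abr_threshold()].
#' @export
response_threshold <- function(levels_db, amplitudes, baseline_mean = 0,
                               baseline_sd = 0, k = 2, criterion = NULL) {
  crit <- criterion %||% (baseline_mean + k * baseline_sd)
  res <- interp_threshold(levels_db, amplitudes, crit)
  structure(res, class = "threshold_result")
}

#' Tone-activated area above a fixed dF/F threshold
#'
#' @param image mean response image (y x x, dF/F).
#' @param pixel_scale_um micrometres per pixel.
#' @param threshold fixed binarization threshold (default 0.15 dF/F).
#' @return activated area in mm^2.
#' @export
activated_area <- function(image, pixel_scale_um, threshold = 0.15) {
  stopifnot(is.matrix(image), pixel_scale_um > 0)
  sum(image > threshold) * pixel_scale_um^2 / 1e6
}

#' Tonotopic peak response locations and shifts
#'
#' For each stimulus frequency's spatial profile, finds the peak position
#' along the tonotopic axis (ties resolve to the first position, flagged) and
#' reports shifts against both supported references: absolute position and
#' position relative to the lowest-frequency peak.
#'
#' @param profiles matrix frequency x position (one spatial profile per row).
#' @param freqs_hz stimulus frequencies, one per row.
#' @return data.frame with `freq_hz`, `peak_position`, `shift_absolute`,
#'   `shift_vs_lowest`, `tie`.
#' @export
tonotopic_peak_shift <- function(profiles, freqs_hz) {
  stopifnot(is.matrix(profiles), nrow(profiles) == length(freqs_hz))
  pk <- integer(nrow(profiles)); tie <- logical(nrow(profiles))
  for (i in seq_len(nrow(profiles))) {
    mx <- max(profiles[i, ])
    w <- which(profiles[i, ] == mx)
    pk[i] <- w[1]
    tie[i] <- length(w) > 1
  }
  ref <- pk[which.min(freqs_hz)]
  data.frame(freq_hz = freqs_hz, peak_position = pk,
             shift_absolute = pk, shift_vs_lowest = pk - ref, tie = tie)
}
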