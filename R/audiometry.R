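#' ABR level series container
#'
#' Averaged ABR waveforms across an ascending series of stimulus levels, with
#' an analysis (signal) window and one or more pre-stimulus background
#' segments used for the detection criterion.
#'
#' @param levels_db ascending stimulus levels (dB SPL).
#' @param waveforms matrix, level x sample (microvolts).
#' @param fs_hz sampling rate.
#' @param signal_window integer sample indices of the post-stimulus analysis
#'   window.
#' @param background_windows list of integer index vectors, each one
#'   pre-stimulus background segment.
#' @return object of class `abr_series`.
#' @export
abr_series <- function(levels_db, waveforms, fs_hz, signal_window,
                       background_windows) {
  stopifnot(is.matrix(waveforms), nrow(waveforms) == length(levels_db),
            !is.unsorted(levels_db), length(levels_db) >= 2)
  allbg <- unlist(background_windows)
  if (max(c(signal_window, allbg)) > ncol(waveforms) ||
      min(c(signal_window, allbg)) < 1)
    stop("analysis windows outside the waveform")
  if (length(intersect(signal_window, allbg)))
    stop("signal and background windows must be disjoint")
  structure(list(levels_db = levels_db, waveforms = waveforms, fs_hz = fs_hz,
                 signal_window = signal_window,
                 background_windows = background_windows),
            class = "abr_series")
}

#' Peak-to-peak amplitude within a window
#'
#' @param waveform numeric vector (microvolts).
#' @param window integer sample indices.
#' @return max minus min within the window.
#' @export
abr_peak_to_peak <- function(waveform, window) {
  if (min(window) < 1 || max(window) > length(waveform))
    stop("window outside the trace")
  w <- waveform[window]
  max(w) - min(w)
}

#' Automated ABR threshold
#'
#' The detection criterion is the mean + `k` standard deviations of the
#' peak-to-peak background signal, pooled over every background segment of
#' every level.  The threshold is the lowest stimulus intensity, determined by
#' linear interpolation in level-vs-amplitude space, whose signal-window
#' peak-to-peak amplitude exceeds the criterion with all higher levels also
#' above it; it clamps to the lowest tested level when that level already
#' exceeds the criterion, and a censored no-response sentinel (one level step
#' above the maximum) is returned when no level crosses.
#'
#' @param series an [abr_series()].
#' @param k SD multiplier (default 2).
#' @param criterion optional explicit criterion in microvolts, overriding the
#'   background rule.
#' @return list of class `threshold_result`: `threshold_db`, `no_response`,
#'   `criterion`, `bracket`, `warning`.
#' @export
abr_threshold <- function(series, k = 2, criterion = NULL) {
  stopifnot(inherits(series, "abr_series"))
  if (is.null(criterion)) {
    bg <- unlist(lapply(seq_along(series$levels_db), function(i)
      vapply(series$background_windows, function(w)
        abr_peak_to_peak(series$waveforms[i, ], w), 1)))
    criterion <- mean(bg) + k * stats::sd(bg)
  }
  p2p <- vapply(seq_along(series$levels_db), function(i)
    abr_peak_to_peak(series$waveforms[i, ], series$signal_window), 1)
  res <- interp_threshold(series$levels_db, p2p, criterion)
  res$signal_p2p <- p2p
  structure(res, class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  if (x$no_response)
    cat(sprintf("<threshold_result> no response (censored at %g dB SPL)\n",
                x$threshold_db))
  else cat(sprintf("<threshold_result> %.2f dB SPL (criterion %.3g)\n",
                   x$threshold_db, x$criterion))
  invisible(x)
}

#' DPOAE stimulus and distortion-product frequencies
#'
#' Primary frequencies are fixed ratios of the center frequency
#' (`f1 = 0.909 fc`, `f2 = 1.09 fc`) and the cubic distortion product is
#' `2 f1 - f2`.
#'
#' @param fc_hz center frequency (Hz).
#' @return list with `f1`, `f2`, `f_dp` (Hz).
#' @export
dpoae_frequencies <- function(fc_hz) {
  stopifnot(fc_hz > 0)
  f1 <- 0.909 * fc_hz
  f2 <- 1.09 * fc_hz
  list(f1 = f1, f2 = f2, f_dp = 2 * f1 - f2)
}

#' DPOAE level series container
#'
#' @param fc_hz center frequency (Hz).
#' @param freqs_hz spectral bin frequencies.
#' @param levels_db ascending primary levels (dB SPL).
#' @param spectra_db matrix, level x bin (dB SPL).
#' @return object of class `dpoae_series`.
#' @export
dpoae_series <- function(fc_hz, freqs_hz, levels_db, spectra_db) {
  stopifnot(is.matrix(spectra_db), nrow(spectra_db) == length(levels_db),
            ncol(spectra_db) == length(freqs_hz), !is.unsorted(levels_db))
  fr <- dpoae_frequencies(fc_hz)
  if (fr$f_dp < min(freqs_hz) || fr$f_dp > max(freqs_hz))
    stop("distortion-product frequency outside the spectrum")
  structure(c(list(fc_hz = fc_hz, freqs_hz = freqs_hz, levels_db = levels_db,
                   spectra_db = spectra_db), fr),
            class = "dpoae_series")
}

#' Automated DPOAE threshold
#'
#' Per level, the distortion-product amplitude is the spectrum at the bin
#' nearest `2 f1 - f2`; the noise criterion is the mean + `k` SD of the bins
#' in the adjacent band (within `adjacent_bins` of the DP bin, excluding
#' `guard_bins` on each side).  The threshold is the lowest level, linearly
#' interpolated, at which the DP amplitude exceeds its noise criterion, with
#' the same monotone-crossing and sentinel rules as [abr_threshold()].
#'
#' @param series a [dpoae_series()].
#' @param k SD multiplier (default 2).
#' @param adjacent_bins half-width of the noise band in bins (default 10).
#' @param guard_bins guard bins excluded around the DP bin (default 2).
#' @return `threshold_result` list; `excess_db` holds the per-level DP minus
#'   criterion values used for interpolation.
#' @export
dpoae_threshold <- function(series, k = 2, adjacent_bins = 10, guard_bins = 2) {
  stopifnot(inherits(series, "dpoae_series"))
  dpbin <- nearest_index(series$freqs_hz, series$f_dp)
  nb <- ncol(series$spectra_db)
  band <- setdiff(max(1, dpbin - adjacent_bins):min(nb, dpbin + adjacent_bins),
                  max(1, dpbin - guard_bins):min(nb, dpbin + guard_bins))
  if (length(band) < 3) stop("spectrum too narrow for the adjacent noise band")
  excess <- vapply(seq_along(series$levels_db), function(i) {
    noise <- series$spectra_db[i, band]
    series$spectra_db[i, dpbin] - (mean(noise) + k * stats::sd(noise))
  }, 1)
  res <- interp_threshold(series$levels_db, excess, 0)
  res$excess_db <- excess
  res$dp_bin <- dpbin
  structure(res, class = "threshold_result")
}
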