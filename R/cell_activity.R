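#' Pairwise synchrony matrix and 80th-percentile summary
#'
#' Computes pairwise Pearson correlation coefficients between every possible
#' pair of ROI dF/F traces and a scalar synchrony summary.  The default
#' summary is, for each ROI, the 80th percentile of its correlations with all
#' other ROIs, averaged across ROIs (`mode = "per_roi"`); `mode = "pooled"`
#' instead takes the 80th percentile of all off-diagonal pairs.
#'
#' Zero-variance traces produce `NA` pairs, which are excluded from the
#' summary.
#'
#' @param traces numeric matrix, ROI x time (dF/F).
#' @param probs percentile used for the summary (default 0.8).
#' @param mode `"per_roi"` (default) or `"pooled"`.
#' @return list of class `correlation_summary` with `matrix` and `summary`.
#' @export
correlation_summary <- function(traces, probs = 0.8,
                                mode = c("per_roi", "pooled")) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(traces), nrow(traces) >= 2, ncol(traces) >= 3)
  sds <- apply(traces, 1, stats::sd)
  m <- suppressWarnings(stats::cor(t(traces)))
  m[sds == 0, ] <- NA_real_
  m[, sds == 0] <- NA_real_
  diag(m) <- 1
  offdiag <- m; diag(offdiag) <- NA_real_
  s <- if (mode == "per_roi") {
    per <- apply(offdiag, 1, function(r) {
      r <- r[is.finite(r)]
      if (!length(r)) NA_real_ else stats::quantile(r, probs, names = FALSE)
    })
    mean(per, na.rm = TRUE)
  } else {
    r <- offdiag[upper.tri(offdiag)]
    r <- r[is.finite(r)]
    if (!length(r)) NA_real_ else stats::quantile(r, probs, names = FALSE)
  }
  structure(list(matrix = m, summary = s, probs = probs, mode = mode),
            class = "correlation_summary")
}

#' Assign hair-cell peaks to supporting-cell events
#'
#' Counts, for each ISC event, the IHCs with a peak between the event's start
#' and end frames.  Each peak is used once: a peak falling inside several
#' (temporally overlapping) event windows is assigned to the earliest-starting
#' event, and the IHC is not counted again in subsequent overlapping events.
#'
#' @param ihc_peaks list (one element per IHC) of peak frame vectors, or a
#'   data.frame with columns `roi` and `frame`.
#' @param isc_events list of `activity_event` (any order; sorted internally by
#'   start frame).
#' @return list of class `event_assignment`: `per_event` data.frame (`event`,
#'   `start_frame`, `end_frame`, `n_ihcs`), `ihc_ids` list per event,
#'   `unassigned_peaks` count.
#' @export
assign_ihc_to_isc_events <- function(ihc_peaks, isc_events) {
  if (is.data.frame(ihc_peaks)) {
    rois <- sort(unique(ihc_peaks$roi))
    ihc_peaks <- lapply(rois, function(r) ihc_peaks$frame[ihc_peaks$roi == r])
    names(ihc_peaks) <- rois
  }
  ids <- names(ihc_peaks) %||% as.character(seq_along(ihc_peaks))
  ord <- order(vapply(isc_events, function(e) e$start_frame, 1))
  isc_events <- isc_events[ord]
  ne <- length(isc_events)
  starts <- vapply(isc_events, function(e) e$start_frame, 1)
  ends <- vapply(isc_events, function(e) e$end_frame, 1)
  members <- vector("list", ne)
  assigned <- 0L; total <- 0L
  for (i in seq_along(ihc_peaks)) {
    for (p in ihc_peaks[[i]]) {
      total <- total + 1L
      hit <- which(p >= starts & p <= ends)
      if (length(hit)) {  # earliest-starting containing event
        e <- hit[1]
        members[[e]] <- unique(c(members[[e]], ids[i]))
        assigned <- assigned + 1L
      }
    }
  }
  structure(list(
    per_event = data.frame(event = seq_len(ne), start_frame = starts,
                           end_frame = ends,
                           n_ihcs = vapply(members, length, 1L)),
    ihc_ids = members,
    assigned_peaks = assigned,
    unassigned_peaks = total - assigned), class = "event_assignment")
}

#' Linear regression of IHC recruitment on ISC event size
#'
#' Ordinary least squares fit of the number of activated IHCs against the
#' number of activated ISC grid ROIs per event.
#'
#' @param n_isc_rois,n_ihcs numeric vectors, one entry per event.
#' @return list with `slope`, `intercept`, `r_squared` and the `lm` fit.
#' @export
isc_ihc_regression <- function(n_isc_rois, n_ihcs) {
  stopifnot(length(n_isc_rois) == length(n_ihcs))
  if (length(unique(n_isc_rois)) < 2) stop("need at least 2 distinct x values")
  fit <- stats::lm(n_ihcs ~ n_isc_rois)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = summary(fit)$r.squared,
       fit = fit)
}

#' Filter neurons by their high-potassium control response
#'
#' Keeps ROIs whose maximum dF/F inside the K+ wash window exceeds
#' `min_response` (default 10% dF/F), the standard viability control for
#' spiral ganglion neuron recordings.
#'
#' @param traces matrix ROI x time (dF/F).
#' @param kcl_window integer frame indices of the wash window.
#' @param min_response inclusion criterion (strictly greater than).
#' @return integer vector of included ROI row indices.
#' @export
filter_sgn_by_kcl <- function(traces, kcl_window, min_response = 0.10) {
  stopifnot(is.matrix(traces))
  kcl_window <- as.integer(kcl_window)
  if (!length(kcl_window)) stop("empty K+ window")
  if (min(kcl_window) < 1 || max(kcl_window) > ncol(traces))
    stop("K+ window outside the recording")
  resp <- apply(traces[, kcl_window, drop = FALSE], 1, max)
  which(resp > min_response)
}

#' Event rates before and after a pharmacological manipulation
#'
#' Splits event times at the drug onset; the post-drug analysis window starts
#' `washin_delay_s` after the perfusion change (bath wash-in time), and events
#' inside the wash-in gap belong to neither window.
#'
#' @param event_times_s event times in seconds from recording start.
#' @param drug_onset_s perfusion-change time (s).
#' @param recording_end_s recording length (s).
#' @param washin_delay_s wash-in delay (default 90 s).
#' @return list with `rate_before`, `rate_after` (events/s), the window
#'   durations, and `short_post_window` flag when the post window is < 60 s.
#' @export
pharmacology_window_compare <- function(event_times_s, drug_onset_s,
                                        recording_end_s, washin_delay_s = 90) {
  stopifnot(drug_onset_s > 0, recording_end_s > drug_onset_s)
  post_start <- drug_onset_s + washin_delay_s
  if (post_start >= recording_end_s) stop("recording does not span the post-drug window")
  dur_pre <- drug_onset_s
  dur_post <- recording_end_s - post_start
  short <- dur_post < 60
  if (short) warning("post-drug analysis window shorter than 60 s")
  list(rate_before = sum(event_times_s < drug_onset_s) / dur_pre,
       rate_after = sum(event_times_s >= post_start) / dur_post,
       window_pre_s = dur_pre, window_post_s = dur_post,
       short_post_window = short)
}
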