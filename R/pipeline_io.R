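#' Write a calcium movie as multi-page TIFF with a JSON sidecar
#'
#' Frames are stored as 32-bit float TIFF pages, rescaled to [0, 1]; the
#' sidecar (`<path>.json`) records the scale, offset, frame rate and pixel
#' scale so [read_movie()] restores physical units (at float32 precision).
#'
#' @param movie a [calcium_movie()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_movie <- function(movie, path) {
  stopifnot(inherits(movie, "calcium_movie"))
  rng <- range(movie$data)
  scale <- if (diff(rng) > 0) diff(rng) else 1
  frames <- lapply(seq_len(dim(movie$data)[1]), function(t)
    (movie$data[t, , ] - rng[1]) / scale)
  tiff::writeTIFF(frames, path, bits.per.sample = 32, reduce = FALSE)
  jsonlite::write_json(
    list(frame_rate_hz = movie$frame_rate_hz,
         pixel_scale_um = movie$pixel_scale_um,
         offset = rng[1], scale = scale),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a movie written by [write_movie()]
#'
#' @param path TIFF path (expects `<path>.json` sidecar alongside).
#' @return a [calcium_movie()].
#' @export
read_movie <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  frames <- tiff::readTIFF(path, all = TRUE)
  data <- array(0, dim = c(length(frames), dim(frames[[1]])[1], dim(frames[[1]])[2]))
  for (t in seq_along(frames)) data[t, , ] <- frames[[t]] * meta$scale + meta$offset
  data[data < 0] <- 0
  calcium_movie(data, meta$frame_rate_hz, meta$pixel_scale_um)
}

#' Trace table I/O (long CSV: roi_id, frame, value)
#'
#' @param traces matrix, ROI x time.
#' @param path CSV path.
#' @return `write_traces`: `path` invisibly; `read_traces`: ROI x time matrix
#'   with ROI ids as rownames.
#' @export
write_traces <- function(traces, path) {
  stopifnot(is.matrix(traces))
  ids <- rownames(traces) %||% as.character(seq_len(nrow(traces)))
  df <- data.frame(roi_id = rep(ids, each = ncol(traces)),
                   frame = rep(seq_len(ncol(traces)), nrow(traces)),
                   value = as.vector(t(traces)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  df <- utils::read.csv(path)
  need <- c("roi_id", "frame", "value")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("trace CSV is missing column(s): ", paste(miss, collapse = ", "))
  ids <- unique(df$roi_id)
  T <- max(df$frame)
  m <- matrix(NA_real_, length(ids), T, dimnames = list(ids, NULL))
  m[cbind(match(df$roi_id, ids), df$frame)] <- df$value
  m
}

#' Stimulus log I/O (CSV: stim_id, freq_hz, level_db, onset_frame)
#'
#' @param log data.frame with columns `freq_hz`, `level_db`, `onset_frame`
#'   (`stim_id` added when absent).
#' @param path CSV path.
#' @export
write_stim_log <- function(log, path) {
  if (is.null(log$stim_id)) log$stim_id <- seq_len(nrow(log))
  utils::write.csv(log[, c("stim_id", "freq_hz", "level_db", "onset_frame")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_stim_log
#' @export
read_stim_log <- function(path) {
  df <- utils::read.csv(path)
  need <- c("freq_hz", "level_db", "onset_frame")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("stimulus log is missing column(s): ", paste(miss, collapse = ", "))
  if (is.unsorted(df$onset_frame, strictly = TRUE))
    stop("stimulus onsets must be strictly increasing")
  df
}

#' Ground-truth serialization (JSON)
#'
#' @param gt ground-truth list from a generator.
#' @param path JSON path.
#' @export
write_ground_truth <- function(gt, path) {
  jsonlite::write_json(gt, path, auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' ABR level-series I/O (long CSV plus JSON sidecar for windows)
#'
#' @param series an [abr_series()].
#' @param path CSV path.
#' @export
write_abr_series <- function(series, path) {
  stopifnot(inherits(series, "abr_series"))
  df <- data.frame(level_db = rep(series$levels_db, each = ncol(series$waveforms)),
                   sample = rep(seq_len(ncol(series$waveforms)),
                                length(series$levels_db)),
                   value_uv = as.vector(t(series$waveforms)))
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(list(fs_hz = series$fs_hz,
                            signal_window = series$signal_window,
                            background_windows = series$background_windows),
                       paste0(path, ".json"), digits = NA)
  invisible(path)
}

#' @rdname write_abr_series
#' @export
read_abr_series <- function(path) {
  df <- utils::read.csv(path)
  need <- c("level_db", "sample", "value_uv")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("ABR CSV is missing column(s): ", paste(miss, collapse = ", "))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  levels <- sort(unique(df$level_db))
  n <- max(df$sample)
  wf <- matrix(NA_real_, length(levels), n)
  wf[cbind(match(df$level_db, levels), df$sample)] <- df$value_uv
  abr_series(levels, wf, meta$fs_hz, meta$signal_window,
             if (is.list(meta$background_windows)) meta$background_windows
             else apply(meta$background_windows, 1, identity, simplify = FALSE))
}

#' DPOAE level-series I/O (long CSV plus JSON sidecar for fc)
#'
#' @param series a [dpoae_series()].
#' @param path CSV path.
#' @export
write_dpoae_series <- function(series, path) {
  stopifnot(inherits(series, "dpoae_series"))
  df <- data.frame(level_db = rep(series$levels_db, each = length(series$freqs_hz)),
                   freq_hz = rep(series$freqs_hz, length(series$levels_db)),
                   amplitude_db = as.vector(t(series$spectra_db)))
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(list(fc_hz = series$fc_hz), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_dpoae_series
#' @export
read_dpoae_series <- function(path) {
  df <- utils::read.csv(path)
  need <- c("level_db", "freq_hz", "amplitude_db")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("DPOAE CSV is missing column(s): ", paste(miss, collapse = ", "))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  levels <- sort(unique(df$level_db))
  freqs <- sort(unique(df$freq_hz))
  sp <- matrix(NA_real_, length(levels), length(freqs))
  sp[cbind(match(df$level_db, levels), match(df$freq_hz, freqs))] <- df$amplitude_db
  dpoae_series(meta$fc_hz, freqs, levels, sp)
}

#' Event table serialization
#'
#' @param events list of `activity_event`.
#' @param path CSV path.
#' @export
write_events <- function(events, path) {
  if (!length(events)) {
    utils::write.csv(data.frame(event = integer(), start_frame = integer(),
                                end_frame = integer(), n_rois = integer(),
                                duration_s = numeric(), area_mm2 = numeric(),
                                peak_dff = numeric()), path, row.names = FALSE)
    return(invisible(path))
  }
  df <- do.call(rbind, lapply(seq_along(events), function(i) {
    e <- events[[i]]
    data.frame(event = i, start_frame = e$start_frame, end_frame = e$end_frame,
               n_rois = e$n_rois, duration_s = e$duration_s,
               area_mm2 = e$area_mm2, peak_dff = e$peak_dff)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Run the ISC event pipeline end to end
#'
#' Generates (or loads) an ISC movie, overlays the ROI grid, binarizes,
#' extracts and summarizes events, and writes per-stage tables together with
#' a provenance manifest (configuration, hashes, seed, package version).
#' Re-running with the same configuration reproduces identical outputs.
#'
#' @param config named list: `seed`, optional `synth` (arguments to
#'   [synth_config()]), optional `grid_px`, `min_frames`, `min_rois`,
#'   `connectivity`, and `out_dir` (no files written when NULL).  Unknown keys
#'   are an error.
#' @return list with `events`, `metrics`, `grid`, `manifest`.
#' @export
run_pipeline <- function(config = list()) {
  known <- c("seed", "synth", "grid_px", "min_frames", "min_rois",
             "connectivity", "out_dir")
  bad <- setdiff(names(config), known)
  if (length(bad)) stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  seed <- config$seed %||% 1
  sc <- do.call(synth_config, c(list(seed = seed), config$synth))
  grid_px <- config$grid_px %||% 10
  min_frames <- config$min_frames %||% 3
  min_rois <- config$min_rois %||% 5
  connectivity <- config$connectivity %||% 26
  sim <- gen_isc_ihc_movie(sc)
  grid <- make_grid_rois(sim$movie, sim$ground_truth$region_mask, grid_px)
  raster <- binarize_activity(grid)
  events <- extract_events(raster, min_frames, min_rois, connectivity,
                           frame_rate_hz = sc$frame_rate_hz,
                           grid_px = grid_px, pixel_scale_um = sc$pixel_scale_um,
                           dff = grid)
  region_area_mm2 <- sum(sim$ground_truth$region_mask) * sc$pixel_scale_um^2 / 1e6
  metrics <- summarize_events(events, sc$duration_s, region_area_mm2)
  manifest <- list(
    package_version = as.character(utils::packageVersion("tonotopy")),
    seed = seed,
    config = config[setdiff(names(config), "out_dir")],
    config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
    results_hash = rlang::hash(list(raster = raster, metrics = metrics)))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_events(events, file.path(config$out_dir, "events.csv"))
    jsonlite::write_json(metrics, file.path(config$out_dir, "event_metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(events = events, metrics = metrics, grid = grid, manifest = manifest)
}
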