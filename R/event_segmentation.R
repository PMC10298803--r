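#' Calcium movie container
#'
#' @param data 3D numeric array, time x y x x, raw fluorescence (>= 0).
#' @param frame_rate_hz frame rate in Hz.
#' @param pixel_scale_um pixel size in micrometres per pixel.
#' @return object of class `calcium_movie`.
#' @export
calcium_movie <- function(data, frame_rate_hz, pixel_scale_um) {
  stopifnot(length(dim(data)) == 3, frame_rate_hz > 0, pixel_scale_um > 0)
  if (any(data < 0)) stop("raw fluorescence must be non-negative")
  structure(list(data = data, frame_rate_hz = frame_rate_hz,
                 pixel_scale_um = pixel_scale_um),
            class = "calcium_movie")
}

#' @export
print.calcium_movie <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<calcium_movie> %d frames, %d x %d px, %.3g Hz, %.3g um/px\n",
              d[1], d[2], d[3], x$frame_rate_hz, x$pixel_scale_um))
  invisible(x)
}

#' Overlay a grid of square ROIs on a region of a movie
#'
#' Tiles the bounding box of `region_mask` with `grid_px`-sided squares
#' (anchored at the top-left of the bounding box), intersects each square with
#' the mask, and keeps ROIs covering at least half a full square.  Each ROI
#' trace is the mean of its member pixels per frame, normalized to dF/F with a
#' 10th-percentile baseline.
#'
#' @param movie a [calcium_movie()].
#' @param region_mask logical y-by-x matrix selecting the region (e.g. the ISC
#'   sheet).
#' @param grid_px square side in pixels (default 10).
#' @return object of class `grid_roi_set`: ROI table (`rois`: roi, row, col,
#'   n_px), member pixel indices, dF/F `traces` (roi x time), and geometry
#'   metadata.
#' @export
make_grid_rois <- function(movie, region_mask, grid_px = 10) {
  stopifnot(inherits(movie, "calcium_movie"), grid_px >= 2)
  d <- dim(movie$data); T <- d[1]; Y <- d[2]; X <- d[3]
  if (!is.logical(region_mask) || !identical(dim(region_mask), c(Y, X)))
    stop("region_mask must be a logical matrix matching the frame size")
  if (!any(region_mask)) stop("empty region mask")
  ys <- range(which(rowSums(region_mask) > 0))
  xs <- range(which(colSums(region_mask) > 0))
  rows <- seq(ys[1], ys[2], by = grid_px)
  cols <- seq(xs[1], xs[2], by = grid_px)
  M <- matrix(movie$data, nrow = T)  # columns ordered (y, x)
  rois <- list(); pixels <- list(); traces <- list()
  half <- grid_px^2 / 2
  ri <- 0
  for (i in seq_along(rows)) for (j in seq_along(cols)) {
    yy <- rows[i]:min(rows[i] + grid_px - 1, Y)
    xx <- cols[j]:min(cols[j] + grid_px - 1, X)
    sub <- region_mask[yy, xx, drop = FALSE]
    if (sum(sub) < half) next  # edge ROIs under half a square are discarded
    idx <- as.matrix(expand.grid(y = yy, x = xx))[as.vector(sub), , drop = FALSE]
    lin <- idx[, 1] + (idx[, 2] - 1) * Y
    ri <- ri + 1
    rois[[ri]] <- data.frame(roi = ri, row = i, col = j, n_px = length(lin))
    pixels[[ri]] <- lin
    traces[[ri]] <- rowMeans(M[, lin, drop = FALSE])
  }
  if (!ri) stop("no grid ROI covers at least half a square inside the mask")
  raw <- do.call(rbind, traces)
  nd <- normalize_dff(raw, method = "pixel_p10")
  structure(list(grid_px = grid_px,
                 rois = do.call(rbind, rois),
                 pixels = pixels,
                 traces = nd$values,
                 f0 = nd$f0,
                 n_rows = length(rows), n_cols = length(cols),
                 frame_rate_hz = movie$frame_rate_hz,
                 pixel_scale_um = movie$pixel_scale_um),
            class = "grid_roi_set")
}

#' Binarize grid-ROI activity at median + 3 SD
#'
#' Each ROI's dF/F trace is thresholded at its own median + `k` standard
#' deviations (SD over the entire recording, single pass); a frame is active
#' when strictly above threshold.
#'
#' @param grid a `grid_roi_set`.
#' @param k SD multiplier (default 3).
#' @return logical array, frame x grid-row x grid-col; ROIs absent from the
#'   grid are always inactive.
#' @export
binarize_activity <- function(grid, k = 3) {
  stopifnot(inherits(grid, "grid_roi_set"))
  T <- ncol(grid$traces)
  raster <- array(FALSE, dim = c(T, grid$n_rows, grid$n_cols))
  for (i in seq_len(nrow(grid$rois))) {
    tr <- grid$traces[i, ]
    thr <- stats::median(tr) + k * stats::sd(tr)
    raster[, grid$rois$row[i], grid$rois$col[i]] <- tr > thr
  }
  raster
}

neighbor_offsets <- function(connectivity) {
  off <- as.matrix(expand.grid(dt = -1:1, dr = -1:1, dc = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  if (connectivity == 6) off <- off[rowSums(abs(off)) == 1, , drop = FALSE]
  off
}

#' Extract spatiotemporal activity events from a binarized raster
#'
#' Events are connected components of active voxels in (frame, row, col) under
#' 26- (default) or 6-neighborhood connectivity; components lasting fewer than
#' `min_frames` frames or touching fewer than `min_rois` distinct ROIs are
#' removed.
#'
#' @param raster logical array (frame x row x col) from [binarize_activity()].
#' @param min_frames minimum event duration in frames (default 3).
#' @param min_rois minimum number of distinct ROIs (default 5).
#' @param connectivity 26 or 6.
#' @param frame_rate_hz,grid_px,pixel_scale_um optional metadata used to fill
#'   `duration_s` and `area_mm2`; `dff` (ROI-major matrix or the raster-aligned
#'   grid) fills `peak_dff` when given as a `grid_roi_set`.
#' @return list of `activity_event` objects, each with `voxels`
#'   (frame/row/col), `start_frame`, `end_frame`, `n_rois`, `duration_s`,
#'   `area_mm2`, `peak_dff`.  Attribute `dropped_voxels` counts active voxels
#'   removed by the size filters (voxel conservation).
#' @export
extract_events <- function(raster, min_frames = 3, min_rois = 5,
                           connectivity = 26, frame_rate_hz = NULL,
                           grid_px = NULL, pixel_scale_um = NULL, dff = NULL) {
  stopifnot(is.logical(raster), length(dim(raster)) == 3,
            connectivity %in% c(6, 26))
  d <- dim(raster); T <- d[1]; R <- d[2]; C <- d[3]
  act <- which(raster)
  if (!length(act)) {
    out <- list(); attr(out, "dropped_voxels") <- 0L
    return(out)
  }
  tt <- (act - 1) %% T + 1
  rr <- ((act - 1) %/% T) %% R + 1
  cc <- (act - 1) %/% (T * R) + 1
  id <- match(act, act)  # identity; vertex ids are positions in `act`
  pos <- integer(T * R * C); pos[act] <- seq_along(act)
  off <- neighbor_offsets(connectivity)
  # keep one direction per offset pair to avoid duplicate edges
  off <- off[off[, 1] > 0 | (off[, 1] == 0 & off[, 2] > 0) |
               (off[, 1] == 0 & off[, 2] == 0 & off[, 3] > 0), , drop = FALSE]
  edges <- list()
  for (i in seq_len(nrow(off))) {
    t2 <- tt + off[i, 1]; r2 <- rr + off[i, 2]; c2 <- cc + off[i, 3]
    ok <- t2 >= 1 & t2 <= T & r2 >= 1 & r2 <= R & c2 >= 1 & c2 <= C
    lin <- t2[ok] + (r2[ok] - 1) * T + (c2[ok] - 1) * T * R
    nb <- pos[lin]
    hit <- nb > 0
    if (any(hit)) edges[[length(edges) + 1]] <-
        cbind(which(ok)[hit], nb[hit])
  }
  g <- igraph::make_empty_graph(n = length(act), directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, t(do.call(rbind, edges)))
  comp <- igraph::components(g)$membership
  events <- list(); dropped <- 0L
  for (k in seq_len(max(comp))) {
    sel <- comp == k
    ev <- new_activity_event(
      data.frame(frame = tt[sel], row = rr[sel], col = cc[sel]),
      min_frames = min_frames, min_rois = min_rois,
      frame_rate_hz = frame_rate_hz, grid_px = grid_px,
      pixel_scale_um = pixel_scale_um, dff = dff)
    if (is.null(ev)) dropped <- dropped + sum(sel)
    else events[[length(events) + 1]] <- ev
  }
  events <- events[order(vapply(events, function(e) e$start_frame, 1))]
  attr(events, "dropped_voxels") <- dropped
  events
}

# Build one event from its voxel table, applying the size filters.
# Returns NULL when the component fails min_frames/min_rois.
new_activity_event <- function(vox, min_frames, min_rois, frame_rate_hz = NULL,
                               grid_px = NULL, pixel_scale_um = NULL, dff = NULL) {
  start <- min(vox$frame); end <- max(vox$frame)
  nfr <- end - start + 1
  n_rois <- nrow(unique(vox[, c("row", "col")]))
  if (nfr < min_frames || n_rois < min_rois) return(NULL)
  dur <- if (!is.null(frame_rate_hz)) nfr / frame_rate_hz else NA_real_
  area <- if (!is.null(grid_px) && !is.null(pixel_scale_um))
    n_rois * (grid_px * pixel_scale_um)^2 / 1e6 else NA_real_
  peak <- NA_real_
  if (inherits(dff, "grid_roi_set")) {
    key <- paste(dff$rois$row, dff$rois$col)
    ri <- match(paste(vox$row, vox$col), key)
    ok <- !is.na(ri)
    if (any(ok)) peak <- max(dff$traces[cbind(ri[ok], vox$frame[ok])])
  }
  structure(list(voxels = vox, start_frame = start, end_frame = end,
                 n_rois = n_rois, duration_s = dur, area_mm2 = area,
                 peak_dff = peak),
            class = "activity_event")
}

#' @export
print.activity_event <- function(x, ...) {
  cat(sprintf("<activity_event> frames %d-%d, %d ROIs, %d voxels\n",
              x$start_frame, x$end_frame, x$n_rois, nrow(x$voxels)))
  invisible(x)
}

#' Split a merged event by k-means clustering of its voxels
#'
#' Voxels are partitioned by k-means on (frame * w_t, row, col) coordinates;
#' each part is re-checked against the duration and ROI-count filters and
#' returned as a separate event.  `w_t = 1` scales one frame to one grid unit.
#'
#' @param event an `activity_event`.
#' @param k number of clusters; `k = 1` returns the event unchanged.
#' @param seed RNG seed for the k-means initialization (deterministic output).
#' @param w_t temporal scaling weight.
#' @inheritParams extract_events
#' @return list of `activity_event` (possibly empty after re-filtering).
#' @export
split_overlapping_events <- function(event, k, seed = 1, w_t = 1,
                                     min_frames = 3, min_rois = 5,
                                     frame_rate_hz = NULL, grid_px = NULL,
                                     pixel_scale_um = NULL, dff = NULL) {
  stopifnot(inherits(event, "activity_event"), k >= 1)
  vox <- event$voxels
  if (k > nrow(vox)) stop("k exceeds the event's voxel count")
  if (k == 1) return(list(event))
  xyz <- cbind(vox$frame * w_t, vox$row, vox$col)
  cl <- with_local_seed(seed, stats::kmeans(xyz, centers = k, nstart = 10))
  parts <- split(seq_len(nrow(vox)), cl$cluster)
  out <- list()
  for (p in parts) {
    ev <- new_activity_event(vox[p, , drop = FALSE], min_frames, min_rois,
                             frame_rate_hz, grid_px, pixel_scale_um, dff)
    if (!is.null(ev)) out[[length(out) + 1]] <- ev
  }
  out[order(vapply(out, function(e) e$start_frame, 1))]
}

#' Suggest a cluster count for event splitting
#'
#' Heuristic trigger for [split_overlapping_events()]: the event's active-ROI
#' count per frame is scanned for local maxima separated by a trough at least
#' `trough_frac` below the smaller flanking maximum; the suggested `k` is the
#' number of such maxima (1 = no split).
#'
#' @param event an `activity_event`.
#' @param trough_frac required fractional trough depth (default 0.3).
#' @return integer k >= 1.
#' @export
suggest_split_k <- function(event, trough_frac = 0.3) {
  vox <- event$voxels
  frames <- event$start_frame:event$end_frame
  counts <- vapply(frames, function(f) sum(vox$frame == f), 1L)
  r <- rle(as.numeric(counts))
  v <- r$values
  firsts <- cumsum(r$lengths) - r$lengths + 1
  m <- length(v)
  if (m == 1) return(1L)
  # run is a local maximum; event boundaries count as troughs
  ismax <- (c(-Inf, v[-m]) < v) & (c(v[-1], -Inf) < v)
  pk <- firsts[ismax]
  if (length(pk) < 2) return(1L)
  keep <- pk[1]
  for (i in 2:length(pk)) {
    prev <- keep[length(keep)]
    trough <- min(counts[prev:pk[i]])
    lower <- min(counts[prev], counts[pk[i]])
    if (trough <= (1 - trough_frac) * lower) keep <- c(keep, pk[i])
  }
  length(keep)
}

#' Summary metrics over a set of events
#'
#' @param events list of `activity_event`.
#' @param recording_duration_s recording length in seconds.
#' @param region_area_mm2 analysed region area in mm^2.
#' @return list with `frequency` (events per 0.01 mm^2 per minute),
#'   `mean_duration_s`, `mean_area_mm2`, `n_events`; the means are `NA` when
#'   there are no events.
#' @export
summarize_events <- function(events, recording_duration_s, region_area_mm2) {
  stopifnot(recording_duration_s > 0, region_area_mm2 > 0)
  n <- length(events)
  freq <- n / (region_area_mm2 / 0.01) / (recording_duration_s / 60)
  list(frequency = freq,
       mean_duration_s = if (n) mean(vapply(events, function(e) e$duration_s, 1)) else NA_real_,
       mean_area_mm2 = if (n) mean(vapply(events, function(e) e$area_mm2, 1)) else NA_real_,
       n_events = n)
}
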