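# Independent reference implementations used to cross-check the package.
# These deliberately share no code with the implementation paths they verify.

# Brute-force flood fill over a logical (frame x row x col) raster.
# Returns an integer label array (0 = inactive).
flood_fill_oracle <- function(raster, connectivity = 26) {
  d <- dim(raster)
  labels <- array(0L, dim = d)
  nxt <- 0L
  offs <- expand.grid(dt = -1:1, dr = -1:1, dc = -1:1)
  offs <- offs[rowSums(abs(offs)) > 0, ]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, ]
  for (t in seq_len(d[1])) for (r in seq_len(d[2])) for (c in seq_len(d[3])) {
    if (!raster[t, r, c] || labels[t, r, c] > 0) next
    nxt <- nxt + 1L
    queue <- list(c(t, r, c))
    labels[t, r, c] <- nxt
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      for (i in seq_len(nrow(offs))) {
        w <- v + unlist(offs[i, ])
        if (any(w < 1) || any(w > d)) next
        if (raster[w[1], w[2], w[3]] && labels[w[1], w[2], w[3]] == 0L) {
          labels[w[1], w[2], w[3]] <- nxt
          queue <- c(queue, list(w))
        }
      }
    }
  }
  labels
}

# Events from an oracle label array, applying the same size filters.
oracle_events <- function(labels, min_frames = 3, min_rois = 5) {
  out <- list()
  for (k in seq_len(max(labels))) {
    idx <- which(labels == k, arr.ind = TRUE)
    nfr <- max(idx[, 1]) - min(idx[, 1]) + 1
    nroi <- nrow(unique(idx[, 2:3, drop = FALSE]))
    if (nfr >= min_frames && nroi >= min_rois)
      out[[length(out) + 1]] <- idx[order(idx[, 1], idx[, 2], idx[, 3]), , drop = FALSE]
  }
  out
}

# Canonical string form of an event's voxel set, for set comparison.
voxel_key <- function(vox) {
  paste(sort(paste(vox[, 1], vox[, 2], vox[, 3], sep = ",")), collapse = ";")
}

# Type-7 percentile by explicit sort-and-interpolate.
percentile_oracle <- function(x, p) {
  s <- sort(x)
  h <- (length(s) - 1) * p + 1
  lo <- floor(h)
  if (lo == length(s)) return(s[lo])
  s[lo] + (h - lo) * (s[lo + 1] - s[lo])
}

# Map a ground-truth ISC event to grid-ROI voxels (frames x grid row/col),
# using only the ground truth and the grid geometry.
gt_event_grid_voxels <- function(ev, grid, Y) {
  px_y <- (ev$pixels - 1) %% Y + 1
  px_x <- (ev$pixels - 1) %/% Y + 1
  hits <- unique(unlist(lapply(seq_along(grid$pixels), function(i) {
    if (any(ev$pixels %in% grid$pixels[[i]])) i else NULL
  })))
  expand.grid(frame = ev$start_frame:ev$end_frame,
              row = grid$rois$row[hits], col = grid$rois$col[hits])
}

# Fraction of planted events matched by at least one detected event (voxel
# overlap in grid coordinates), and the converse for precision.  Recall is
# taken over the `passing` subset (events large/long enough to survive the
# size filters); precision is taken against every planted event, since a
# borderline planted event may still be legitimately detected.
event_recovery <- function(gt_events, detected, grid, Y,
                           passing = rep(TRUE, length(gt_events))) {
  gt_keys <- lapply(gt_events, function(ev) {
    v <- gt_event_grid_voxels(ev, grid, Y)
    paste(v$frame, v$row, v$col)
  })
  det_keys <- lapply(detected, function(e)
    paste(e$voxels$frame, e$voxels$row, e$voxels$col))
  gt_hit <- vapply(gt_keys, function(g)
    any(vapply(det_keys, function(d) any(g %in% d), TRUE)), TRUE)
  det_hit <- vapply(det_keys, function(d)
    any(vapply(gt_keys, function(g) any(d %in% g), TRUE)), TRUE)
  list(recall = if (any(passing)) mean(gt_hit[passing]) else NA_real_,
       precision = if (length(det_hit)) mean(det_hit) else NA_real_)
}

# Reproduce the single Poisson draw a seeded generator makes first, without
# running the generator.
with_seed_pois <- function(seed, lambda) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(seed)
  n <- stats::rpois(1, lambda)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  n
}

# Vectorized independent connected-components oracle: iterative minimum-label
# relaxation over the declared neighborhood until fixpoint.  Each active voxel
# starts with its own linear index as label; a component converges to the
# minimum index it contains.  Independent of the graph-based implementation.
label_prop_oracle <- function(raster, connectivity = 26) {
  d <- dim(raster)
  lab <- array(Inf, d)
  lab[raster] <- which(raster)
  offs <- expand.grid(dt = -1:1, dr = -1:1, dc = -1:1)
  offs <- as.matrix(offs[rowSums(abs(offs)) > 0, ])
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  rng <- function(n, o) list(dst = max(1, 1 + o):min(n, n + o),
                             src = max(1, 1 - o):min(n, n - o))
  repeat {
    new <- lab
    for (i in seq_len(nrow(offs))) {
      t_ <- rng(d[1], offs[i, 1]); r_ <- rng(d[2], offs[i, 2]); c_ <- rng(d[3], offs[i, 3])
      sh <- array(Inf, d)
      sh[t_$dst, r_$dst, c_$dst] <- lab[t_$src, r_$src, c_$src]
      new <- pmin(new, sh)
    }
    new[!raster] <- Inf
    # pointer jumping: labels are voxel indices, so composing the label map
    # (new[v] <- new[new[v]]) compresses chains without leaving the component
    act <- which(is.finite(new))
    repeat {
      jumped <- new
      jumped[act] <- new[new[act]]
      if (identical(jumped, new)) break
      new <- jumped
    }
    if (identical(new, lab)) break
    lab <- new
  }
  out <- array(0L, d)
  act <- is.finite(lab)
  out[act] <- as.integer(factor(lab[act]))
  out
}

# Ground-truth-side size filter: a planted event can survive the 3-frame /
# 5-ROI detection filters only if it lasts >= min_frames and covers at least
# min_rois grid squares at >= half coverage (half-covered squares carry half
# the event amplitude, comfortably above per-ROI binarization thresholds).
gt_passes_filters <- function(ev, grid, min_frames = 3, min_rois = 5) {
  if (ev$end_frame - ev$start_frame + 1 < min_frames) return(FALSE)
  cover <- vapply(seq_along(grid$pixels), function(i)
    sum(ev$pixels %in% grid$pixels[[i]]) >= length(grid$pixels[[i]]) / 2, TRUE)
  sum(cover) >= min_rois
}
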