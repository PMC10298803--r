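make_movie <- function(T = 20, Y = 40, X = 40, value = 100) {
  calcium_movie(array(value, dim = c(T, Y, X)), 2, 1)
}

test_that("grid ROI construction tiles the mask and drops small edge ROIs", {
  mv <- make_movie(Y = 120, X = 120)
  mask <- matrix(FALSE, 120, 120); mask[11:110, 11:110] <- TRUE
  g <- make_grid_rois(mv, mask, 10)
  expect_equal(nrow(g$rois), 100)
  expect_equal(unique(g$rois$n_px), 100)
  # ROIs partition the mask
  expect_equal(sum(g$rois$n_px), sum(mask))
  expect_equal(anyDuplicated(unlist(g$pixels)), 0)

  # mask smaller than one square: kept only if at least half a square
  mask2 <- matrix(FALSE, 120, 120); mask2[1:5, 1:10] <- TRUE   # 50 px = half
  expect_equal(nrow(make_grid_rois(mv, mask2, 10)$rois), 1)
  mask3 <- matrix(FALSE, 120, 120); mask3[1:4, 1:10] <- TRUE   # 40 px < half
  expect_error(make_grid_rois(mv, mask3, 10), "half")
  expect_error(make_grid_rois(mv, matrix(FALSE, 120, 120)), "empty")
})

test_that("checkerboard masks yield one ROI per surviving tile", {
  mv <- make_movie(Y = 60, X = 60)
  mask <- matrix(FALSE, 60, 60)
  tiles <- 0
  for (i in 0:5) for (j in 0:5) if ((i + j) %% 2 == 0) {
    mask[i * 10 + 1:10, j * 10 + 1:10] <- TRUE
    tiles <- tiles + 1
  }
  expect_equal(nrow(make_grid_rois(mv, mask, 10)$rois), tiles)
})

test_that("binarization thresholds each ROI at its own median + 3 SD", {
  mv <- make_movie(T = 100, Y = 20, X = 20)
  mask <- matrix(TRUE, 20, 20)
  g <- make_grid_rois(mv, mask, 10)
  expect_false(any(binarize_activity(g)))  # constant: SD 0, strict inequality

  # hand-computed threshold for a single spike of height 1 in n frames
  n <- 100
  g2 <- g
  g2$traces[1, ] <- 0; g2$traces[1, 37] <- 1
  mu <- 1 / n
  s <- sqrt(((1 - mu)^2 + (n - 1) * mu^2) / (n - 1))
  ras <- binarize_activity(g2)
  expect_identical(ras[37, 1, 1], 1 > 0 + 3 * s)
  expect_equal(sum(ras[, 1, 1]), as.integer(1 > 3 * s))
})

test_that("event extraction matches a brute-force flood fill with filters", {
  set.seed(21)
  for (rep in 1:20) {
    d <- c(sample(5:20, 1), sample(4:12, 1), sample(4:12, 1))
    ras <- array(runif(prod(d)) < 0.25, dim = d)
    for (conn in c(26, 6)) {
      ev <- extract_events(ras, min_frames = 3, min_rois = 5, connectivity = conn)
      orc <- oracle_events(flood_fill_oracle(ras, conn))
      expect_equal(length(ev), length(orc))
      expect_setequal(vapply(ev, function(e) voxel_key(as.matrix(e$voxels)), ""),
                      vapply(orc, voxel_key, ""))
    }
  }
})

test_that("size filters are monotone and active voxels are conserved", {
  set.seed(5)
  ras <- array(runif(20 * 10 * 10) < 0.3, dim = c(20, 10, 10))
  ev0 <- extract_events(ras, min_frames = 1, min_rois = 1)
  expect_equal(sum(vapply(ev0, function(e) nrow(e$voxels), 1L)) +
                 attr(ev0, "dropped_voxels"), sum(ras))
  n_prev <- length(ev0)
  for (mf in c(2, 3, 5)) {
    n <- length(extract_events(ras, min_frames = mf, min_rois = 1))
    expect_lte(n, n_prev); n_prev <- n
  }
  n_prev <- length(ev0)
  for (mr in c(3, 5, 10)) {
    n <- length(extract_events(ras, min_frames = 1, min_rois = mr))
    expect_lte(n, n_prev); n_prev <- n
  }
  # conservation holds with filters active
  ev <- extract_events(ras, min_frames = 3, min_rois = 5)
  expect_equal(sum(vapply(ev, function(e) nrow(e$voxels), 1L)) +
                 attr(ev, "dropped_voxels"), sum(ras))
})

test_that("simple blobs pass or fail the duration/size filters as specified", {
  ras <- array(FALSE, dim = c(12, 8, 8))
  ras[3:6, 2:3, 2:4] <- TRUE  # 4 frames, 6 ROIs
  ev <- extract_events(ras, frame_rate_hz = 2, grid_px = 10, pixel_scale_um = 1)
  expect_length(ev, 1)
  expect_equal(ev[[1]]$n_rois, 6)
  expect_equal(ev[[1]]$duration_s, 2)
  expect_equal(ev[[1]]$area_mm2, 6 * 100 / 1e6)

  ras2 <- array(FALSE, dim = c(12, 8, 8))
  ras2[3:4, 1:8, 1:8] <- TRUE  # only 2 frames
  expect_length(extract_events(ras2), 0)

  # two blobs separated in time and space
  ras3 <- array(FALSE, dim = c(20, 8, 8))
  ras3[2:5, 1:3, 1:3] <- TRUE
  ras3[8:11, 6:8, 6:8] <- TRUE
  expect_length(extract_events(ras3), 2)
})

test_that("k-means splitting recovers fused blobs and respects filters", {
  ev <- extract_events(array(TRUE, dim = c(4, 3, 3)), min_rois = 1)[[1]]
  expect_identical(split_overlapping_events(ev, 1), list(ev))
  expect_error(split_overlapping_events(ev, nrow(ev$voxels) + 1), "voxel count")

  # two blobs fused by a thin diagonal bridge of single voxels
  ras <- array(FALSE, dim = c(30, 20, 20))
  ras[3:8, 2:6, 2:6] <- TRUE
  ras[15:20, 13:17, 13:17] <- TRUE
  for (i in 0:5) ras[9 + i, 7 + i, 7 + i] <- TRUE
  fused <- extract_events(ras, min_frames = 3, min_rois = 5)
  expect_length(fused, 1)
  parts <- split_overlapping_events(fused[[1]], 2, seed = 7)
  expect_length(parts, 2)
  in_part <- function(p, blob_frames) sum(p$voxels$frame %in% blob_frames)
  n1 <- vapply(parts, in_part, 1, blob_frames = 3:8)
  n2 <- vapply(parts, in_part, 1, blob_frames = 15:20)
  # best-permutation matching of parts to planted blobs
  acc <- max(n1[1] + n2[2], n1[2] + n2[1]) / (sum(n1) + sum(n2))
  expect_gte(acc, 0.95)
  # deterministic given the seed
  parts2 <- split_overlapping_events(fused[[1]], 2, seed = 7)
  expect_identical(lapply(parts, function(e) e$voxels),
                   lapply(parts2, function(e) e$voxels))

  # fusing two 2-frame blobs then splitting drops both parts
  ras4 <- array(FALSE, dim = c(10, 10, 10))
  ras4[4:5, 1:3, 1:3] <- TRUE
  ras4[5:6, 4:6, 4:6] <- TRUE
  fused4 <- extract_events(ras4, min_frames = 3, min_rois = 5)
  expect_length(fused4, 1)  # union spans 3 frames
  expect_length(split_overlapping_events(fused4[[1]], 2, seed = 1), 0)
})

test_that("split trigger counts well-separated activity maxima", {
  ras <- array(FALSE, dim = c(40, 12, 12))
  ras[5:10, 1:4, 1:4] <- TRUE     # 16 ROIs active
  ras[11:13, 4, 4] <- TRUE        # trough: 1 ROI
  ras[14:19, 5:8, 5:8] <- TRUE
  ev <- extract_events(ras, min_rois = 1)
  expect_length(ev, 1)
  expect_equal(suggest_split_k(ev[[1]]), 2)
  # single blob: no split
  ras2 <- array(FALSE, dim = c(20, 6, 6)); ras2[5:9, 1:4, 1:4] <- TRUE
  expect_equal(suggest_split_k(extract_events(ras2, min_rois = 1)[[1]]), 1)
})

test_that("event summary metrics follow the per-0.01-mm2-per-minute convention", {
  mk <- function(d, a) structure(list(duration_s = d, area_mm2 = a),
                                 class = "activity_event")
  evs <- replicate(6, mk(4, 0.001), simplify = FALSE)
  m <- summarize_events(evs, 600, 0.02)
  expect_equal(m$frequency, 6 / 2 / 10)
  expect_equal(m$mean_duration_s, 4)
  m0 <- summarize_events(list(), 600, 0.02)
  expect_equal(m0$frequency, 0)
  expect_true(is.na(m0$mean_duration_s))
  durs <- c(2, 3.5, 6)
  mm <- summarize_events(mapply(mk, durs, 0.002, SIMPLIFY = FALSE), 300, 0.01)
  expect_equal(mm$mean_duration_s, mean(durs))
})
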