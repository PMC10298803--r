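#' Difference movie for transmitted-light crenation imaging
#'
#' Subtracts frames `lag_s` seconds apart: `diff[n] = frame[n + lag] -
#' frame[n]`, highlighting slow transmittance changes such as osmotic
#' crenations.
#'
#' @param movie a [calcium_movie()] (transmitted-light stack, typically 1 Hz).
#' @param lag_s lag in seconds (default 5).
#' @return 3D array with `T - lag` frames.
#' @export
difference_movie <- function(movie, lag_s = 5) {
  stopifnot(inherits(movie, "calcium_movie"))
  lag <- round(lag_s * movie$frame_rate_hz)
  T <- dim(movie$data)[1]
  if (lag < 1 || lag >= T) stop("lag must be positive and shorter than the movie")
  movie$data[(1 + lag):T, , , drop = FALSE] - movie$data[1:(T - lag), , , drop = FALSE]
}

#' Detect crenation regions in a difference movie
#'
#' Per frame: the absolute difference signal is thresholded at its mean +
#' `k` SD, the binary mask is smoothed with a Gaussian filter
#' (`gaussian_sigma` px), re-binarized at half the smoothed maximum, and 2D
#' connected components are labelled.  Detections overlapping a region from an
#' earlier frame by at least `merge_overlap` (fraction of the smaller region)
#' are merged, so a slow crenation spanning several difference frames is
#' counted once, with onset at its first frame.
#'
#' Frames whose smoothed mask peaks below `min_peak` are skipped: an isolated
#' supra-threshold noise pixel smoothed at sigma = 12 peaks near 1e-3, while a
#' filled crenation patch peaks near 1, so the floor rejects speckle without
#' touching real regions.
#'
#' @param diff_stack 3D array from [difference_movie()].
#' @param pixel_scale_um micrometres per pixel.
#' @param k SD multiplier for the per-frame threshold (default 3).
#' @param gaussian_sigma smoothing sigma in pixels (default 12).
#' @param rebinarize_frac re-binarization level as a fraction of the smoothed
#'   maximum (default 0.5, i.e. half-max).
#' @param merge_overlap cross-frame merge criterion (default 0.25).
#' @param min_peak smoothed-mask peak floor (default 0.1).
#' @return list of `crenation_region`: `pixels` (linear indices into a frame),
#'   `onset_frame`, `area_um2`.
#' @export
detect_crenations <- function(diff_stack, pixel_scale_um, k = 3,
                              gaussian_sigma = 12, rebinarize_frac = 0.5,
                              merge_overlap = 0.25, min_peak = 0.1) {
  stopifnot(length(dim(diff_stack)) == 3, pixel_scale_um > 0)
  T <- dim(diff_stack)[1]
  regions <- list()
  for (fr in seq_len(T)) {
    d <- abs(diff_stack[fr, , ])
    thr <- mean(d) + k * stats::sd(d)
    mask <- d > thr
    if (!any(mask)) next
    sm <- EBImage::gblur(mask * 1, sigma = gaussian_sigma)
    mx <- max(sm)
    if (mx < min_peak) next
    lab <- EBImage::bwlabel(sm > rebinarize_frac * mx)
    for (lb in seq_len(max(lab))) {
      pix <- which(lab == lb)
      merged <- FALSE
      for (i in seq_along(regions)) {
        ov <- length(intersect(pix, regions[[i]]$pixels))
        if (ov >= merge_overlap * min(length(pix), length(regions[[i]]$pixels))) {
          regions[[i]]$pixels <- union(regions[[i]]$pixels, pix)
          regions[[i]]$area_um2 <- crenation_area(length(regions[[i]]$pixels),
                                                  pixel_scale_um)
          merged <- TRUE
          break
        }
      }
      if (!merged) regions[[length(regions) + 1]] <-
          structure(list(pixels = pix, onset_frame = fr,
                         area_um2 = crenation_area(length(pix), pixel_scale_um)),
                    class = "crenation_region")
    }
  }
  regions
}

#' Crenation area from pixel count
#'
#' Number of pixels within the region border multiplied by the squared pixel
#' scale.
#'
#' @param n_pixels pixel count.
#' @param pixel_scale_um micrometres per pixel.
#' @return area in um^2.
#' @export
crenation_area <- function(n_pixels, pixel_scale_um) {
  n_pixels * pixel_scale_um^2
}

#' Automated centroid counting in a masked region
#'
#' Binarizes an image (Otsu threshold by default), restricts to a region mask,
#' labels 2D connected components and counts those at or above a minimum area
#' floor.  Touching cells merge into one component (no watershed; documented
#' behavior).
#'
#' @param image numeric y-by-x matrix.
#' @param region_mask logical matrix of the same size (e.g. the OHC region).
#' @param threshold optional absolute binarization threshold; default Otsu on
#'   the min-max normalized image.
#' @param min_area_px minimum component area in pixels (default 10).
#' @return integer count.
#' @export
count_centroids <- function(image, region_mask, threshold = NULL,
                            min_area_px = 10) {
  stopifnot(is.matrix(image), identical(dim(image), dim(region_mask)))
  if (!any(region_mask)) stop("empty region mask")
  if (is.null(threshold)) {
    rng <- range(image)
    if (diff(rng) == 0) return(0L)
    norm <- (image - rng[1]) / diff(rng)
    thr <- EBImage::otsu(EBImage::Image(norm))
    bin <- norm > thr
  } else bin <- image > threshold
  bin[!region_mask] <- FALSE
  lab <- EBImage::bwlabel(bin)
  if (max(lab) == 0) return(0L)
  sizes <- tabulate(lab[lab > 0])
  sum(sizes >= min_area_px)
}
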