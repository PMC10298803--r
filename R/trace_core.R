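#' Delta-F-over-F normalization
#'
#' Normalizes raw fluorescence to a baseline \eqn{F_o} computed over the full
#' recording, returning \eqn{\Delta F/F_o = (F - F_o)/F_o}.  Two baseline
#' conventions are supported, matching common practice for pixelwise movies and
#' per-cell ROI traces respectively:
#' \describe{
#'   \item{`pixel_p10`}{\eqn{F_o} is the 10th percentile of each pixel's (or
#'     trace's) values over time, with linear interpolation between order
#'     statistics (R quantile type 7).}
#'   \item{`roi_median`}{\eqn{F_o} is the median of each trace over time.}
#' }
#'
#' @param raw numeric vector (one trace), matrix (ROI x time), or 3D array
#'   (time x y x x) of raw fluorescence.  Values must be finite and
#'   non-negative.
#' @param method baseline convention, see Details.
#' @return list of class `dff` with elements `values` (same shape as `raw`),
#'   `f0` (the per-trace/per-pixel baseline) and `method`.
#' @export
normalize_dff <- function(raw, method = c("pixel_p10", "roi_median")) {
  method <- match.arg(method)
  if (!all(is.finite(raw))) stop("raw fluorescence must be finite")
  bl_fun <- switch(method,
    pixel_p10 = function(x) stats::quantile(x, 0.10, names = FALSE, type = 7),
    roi_median = function(x) stats::median(x))
  if (is.null(dim(raw))) {
    f0 <- bl_fun(raw)
    if (f0 <= 0) stop("baseline F0 <= 0 for the trace")
    values <- (raw - f0) / f0
  } else if (length(dim(raw)) == 2) {
    f0 <- apply(raw, 1, bl_fun)
    bad <- which(f0 <= 0)
    if (length(bad)) stop("baseline F0 <= 0 for ROI(s): ", paste(bad, collapse = ", "))
    values <- sweep(sweep(raw, 1, f0, "-"), 1, f0, "/")
  } else if (length(dim(raw)) == 3) {
    f0 <- apply(raw, c(2, 3), bl_fun)
    bad <- which(f0 <= 0, arr.ind = TRUE)
    if (nrow(bad)) stop("baseline F0 <= 0 at pixel (y,x) = (",
                        bad[1, 1], ",", bad[1, 2], ")")
    values <- raw
    for (t in seq_len(dim(raw)[1])) values[t, , ] <- (raw[t, , ] - f0) / f0
  } else stop("raw must be a vector, matrix, or 3D array")
  structure(list(values = values, f0 = f0, method = method), class = "dff")
}

# Accept either a bare numeric object or a `dff` result.
dff_values <- function(x) if (inherits(x, "dff")) x$values else x

#' Photobleach correction by single-exponential subtraction
#'
#' Fits \eqn{a e^{-t/\tau} + c} to the trace by least squares (Levenberg-
#' Marquardt, initialized from a log-linear regression of the decaying part)
#' and subtracts the exponential component, retaining the offset.  Traces with
#' no net decay, or fits that fail to converge, are returned unchanged with
#' `converged = FALSE`.
#'
#' @param trace numeric vector (raw or dF/F).
#' @param frame_rate_hz sampling rate used to build the time axis (s).
#' @return list with `trace` (corrected), `a`, `tau_s`, `offset`, `converged`.
#' @export
correct_photobleach <- function(trace, frame_rate_hz = 1) {
  trace <- dff_values(trace)
  n <- length(trace)
  if (n < 10) stop("trace must have at least 10 frames")
  t_s <- (seq_len(n) - 1) / frame_rate_hz
  out <- list(trace = trace, a = 0, tau_s = Inf, offset = 0, converged = FALSE)
  decay <- trace[1] - trace[n]
  if (!is.finite(decay) || decay <= 0) return(out)  # no decay to remove
  y <- trace - min(trace)
  pos <- y > max(y) * 1e-6
  if (sum(pos) < 3) return(out)
  ll <- stats::lm(log(y[pos]) ~ t_s[pos])
  slope <- unname(stats::coef(ll)[2])
  tau0 <- if (is.finite(slope) && slope < 0) -1 / slope else t_s[n] / 2
  fit <- tryCatch(
    minpack.lm::nlsLM(trace ~ a * exp(-t_s / tau) + c0,
                      start = list(a = decay, tau = tau0, c0 = min(trace)),
                      lower = c(0, 1e-6, -Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    warning("photobleach fit did not converge; trace returned unchanged")
    return(out)
  }
  p <- stats::coef(fit)
  out$trace <- trace - p[["a"]] * exp(-t_s / p[["tau"]])
  out$a <- p[["a"]]; out$tau_s <- p[["tau"]]; out$offset <- p[["c0"]]
  out$converged <- TRUE
  out
}

#' Peak detection with fixed threshold and minimum amplitude
#'
#' Finds strict local maxima of a trace that exceed both a peak threshold and
#' a minimum amplitude.  The threshold is either a fixed value or the per-trace
#' rule median + k standard deviations (single-pass SD over the entire
#' recording, events included).  Plateau ties resolve to the first frame of the
#' plateau; trace endpoints are not peaks.
#'
#' @param trace numeric vector (dF/F or current).
#' @param k multiplier for the median + k*SD rule (ignored when `threshold`
#'   given).
#' @param min_amplitude minimum peak amplitude (same units as the trace).
#' @param threshold optional fixed absolute threshold overriding the
#'   median + k*SD rule.
#' @return data.frame with columns `frame`, `amplitude`, sorted by frame.
#' @export
detect_peaks <- function(trace, k = 3, min_amplitude = 0.10, threshold = NULL) {
  trace <- dff_values(trace)
  stopifnot(all(is.finite(trace)))
  thr <- threshold %||% (stats::median(trace) + k * stats::sd(trace))
  n <- length(trace)
  empty <- data.frame(frame = integer(), amplitude = numeric())
  if (n < 3) return(empty)
  r <- rle(trace)
  v <- r$values
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  m <- length(v)
  if (m < 3) return(empty)
  ispeak <- c(FALSE, v[2:(m - 1)] > v[1:(m - 2)] & v[2:(m - 1)] > v[3:m], FALSE)
  keep <- ispeak & v > thr & v > min_amplitude
  data.frame(frame = starts[keep], amplitude = v[keep])
}

#' Neuropil subtraction
#'
#' Subtracts scaled neuropil fluorescence from a soma trace
#' (`soma - r * neuropil`), the standard correction for two-photon somatic
#' signals contaminated by surrounding neuropil.
#'
#' @param soma,neuropil numeric vectors of equal length.
#' @param r contamination factor (default 0.7).
#' @return corrected numeric vector.
#' @export
subtract_neuropil <- function(soma, neuropil, r = 0.7) {
  if (length(soma) != length(neuropil)) stop("soma and neuropil traces differ in length")
  soma - r * neuropil
}
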