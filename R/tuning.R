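#' Two-photon tuning tensor container
#'
#' Maximum tone-evoked dF/F responses per (cell, frequency, level).
#'
#' @param responses 3D array, cell x frequency x level.
#' @param freqs_hz strictly increasing stimulus frequencies.
#' @param levels_db strictly increasing sound levels.
#' @return object of class `tuning_tensor`.
#' @export
tuning_tensor <- function(responses, freqs_hz, levels_db) {
  stopifnot(length(dim(responses)) == 3,
            dim(responses)[2] == length(freqs_hz),
            dim(responses)[3] == length(levels_db),
            all(diff(freqs_hz) > 0), all(diff(levels_db) > 0))
  if (length(freqs_hz) < 2 || length(levels_db) < 2)
    stop("need at least 2 frequencies and 2 levels")
  structure(list(responses = responses, freqs_hz = freqs_hz,
                 levels_db = levels_db), class = "tuning_tensor")
}

#' Best frequency of a cell
#'
#' The frequency eliciting the largest response at any sound level (global
#' argmax over the frequency-by-level response surface); ties resolve to the
#' lower frequency and are flagged.
#'
#' @param tensor a [tuning_tensor()].
#' @param cell cell index.
#' @return list with `bf_hz` and `tie`.
#' @export
best_frequency <- function(tensor, cell) {
  stopifnot(inherits(tensor, "tuning_tensor"))
  surf <- tensor$responses[cell, , ]
  if (all(is.na(surf))) stop("all responses missing for cell ", cell)
  fmax <- apply(surf, 1, max, na.rm = TRUE)
  w <- which(fmax == max(fmax))
  list(bf_hz = tensor$freqs_hz[w[1]], tie = length(w) > 1)
}

#' Gaussian tuning bandwidth (Gauss1 fit)
#'
#' Least-squares fit of a single-term Gaussian
#' \eqn{a \exp(-((x - b)/c)^2)} to the maximum evoked amplitudes at each
#' frequency (typically at the top sound level), with \eqn{x = \log_2 f}.
#' The bandwidth is reported as \eqn{\sigma = c/\sqrt{2}} octaves.  Cells are
#' excluded (not an error) when the fit does not converge, the response is
#' flat, the fitted peak lies outside the tested frequency range, or the
#' fitted width exceeds the tested span (no curvature).
#'
#' @param amplitudes maximum evoked amplitude per frequency.
#' @param freqs_hz stimulus frequencies (>= 4 finite amplitudes required).
#' @return list with `sigma_octaves`, coefficients `a`, `b`, `c`, `excluded`,
#'   `reason`.
#' @export
bandwidth_gaussian <- function(amplitudes, freqs_hz) {
  stopifnot(length(amplitudes) == length(freqs_hz))
  ok <- is.finite(amplitudes)
  if (sum(ok) < 4) stop("need at least 4 frequencies with finite amplitude")
  x <- log2(freqs_hz[ok]); y <- amplitudes[ok]
  excl <- function(reason) list(sigma_octaves = NA_real_, a = NA_real_,
                                b = NA_real_, c = NA_real_, excluded = TRUE,
                                reason = reason)
  if (stats::sd(y) == 0) return(excl("flat response"))
  span <- diff(range(x))
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * exp(-((x - b) / cc)^2),
                      start = list(a = max(y), b = x[which.max(y)], cc = 1),
                      lower = c(0, -Inf, 1e-4),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(excl("fit did not converge"))
  p <- stats::coef(fit)
  if (p[["b"]] < min(x) || p[["b"]] > max(x)) return(excl("peak outside tested range"))
  if (p[["cc"]] > 2 * span) return(excl("no curvature"))
  list(sigma_octaves = p[["cc"]] / sqrt(2), a = p[["a"]], b = p[["b"]],
       c = p[["cc"]], excluded = FALSE, reason = NA_character_)
}

#' Principal components of peak response patterns
#'
#' PCA with cells as observations and the flattened (frequency x level) peak
#' responses as features, mean-centered but not rescaled; the three major
#' component scores are returned.
#'
#' @param tensor a [tuning_tensor()] or a cell-by-feature matrix.
#' @return list with `scores` (cell x 3), `explained_variance` (all
#'   components), `rotation`.
#' @export
pca_response_features <- function(tensor) {
  X <- if (inherits(tensor, "tuning_tensor"))
    matrix(tensor$responses, nrow = dim(tensor$responses)[1]) else tensor
  stopifnot(is.matrix(X), nrow(X) >= 4)
  if (all(apply(X, 2, stats::sd) == 0)) stop("constant feature matrix")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  k <- min(3, ncol(pc$x))
  scores <- matrix(0, nrow(X), 3)
  scores[, seq_len(k)] <- pc$x[, seq_len(k)]
  list(scores = scores,
       explained_variance = pc$sdev^2 / sum(pc$sdev^2),
       rotation = pc$rotation)
}

#' Responsiveness flag per cell
#'
#' A cell is responsive when its maximum response exceeds the baseline mean +
#' `k` baseline SD for at least one stimulus.
#'
#' @param tensor a [tuning_tensor()].
#' @param baseline_mean,baseline_sd baseline statistics (dF/F).
#' @param k SD multiplier (default 3).
#' @return logical vector, one flag per cell.
#' @export
is_responsive <- function(tensor, baseline_mean = 0, baseline_sd = 0, k = 3) {
  stopifnot(inherits(tensor, "tuning_tensor"))
  apply(tensor$responses, 1, max, na.rm = TRUE) > baseline_mean + k * baseline_sd
}

#' Histogram of best frequencies among responsive cells
#'
#' @param bf_hz best frequency per cell.
#' @param responsive logical responsiveness flag per cell.
#' @param bins bin centers, typically the tested frequencies.
#' @return list with `counts` (per bin), `bins`, `fraction_responsive`.
#' @export
best_frequency_histogram <- function(bf_hz, responsive, bins) {
  stopifnot(length(bf_hz) == length(responsive), length(bf_hz) > 0)
  kept <- bf_hz[responsive]
  idx <- vapply(kept, function(f) nearest_index(bins, f), 1L)
  counts <- tabulate(idx, nbins = length(bins))
  list(counts = stats::setNames(counts, signif(bins, 4)), bins = bins,
       fraction_responsive = mean(responsive))
}
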