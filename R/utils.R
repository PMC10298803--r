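# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores the caller's RNG state so that seeded generators never
#' perturb the global random stream.
#' @keywords internal
#' @noRd
with_local_seed <- function(seed, expr) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Threshold by monotone criterion crossing with linear interpolation
#'
#' Shared rule for ABR, DPOAE and tone-evoked thresholds: the threshold is the
#' lowest stimulus level whose response exceeds `criterion` with all higher
#' levels also above it, linearly interpolated in level-vs-response space
#' between that level and the next lower one.  When the lowest tested level is
#' already above criterion, the threshold clamps to it; when no level crosses,
#' a censored no-response sentinel (one level step above the maximum) is
#' returned.
#' @keywords internal
#' @noRd
interp_threshold <- function(levels_db, values, criterion) {
  stopifnot(length(levels_db) == length(values), length(levels_db) >= 2)
  o <- order(levels_db)
  levels_db <- levels_db[o]; values <- values[o]
  step <- stats::median(diff(levels_db))
  above <- values > criterion
  res <- list(threshold_db = NA_real_, no_response = FALSE, criterion = criterion,
              bracket = c(NA_real_, NA_real_), warning = character(0))
  if (!any(above)) {
    res$threshold_db <- max(levels_db) + step
    res$no_response <- TRUE
    return(res)
  }
  # lowest level above criterion with all higher levels also above
  ok <- rev(cumprod(rev(above))) > 0
  i <- which(ok)[1]
  if (sum(above) > sum(ok)) res$warning <- "non-monotone crossings; using highest crossing"
  if (i == 1) {
    res$threshold_db <- levels_db[1]
    res$bracket <- c(levels_db[1], levels_db[1])
    return(res)
  }
  l0 <- levels_db[i - 1]; l1 <- levels_db[i]
  v0 <- values[i - 1]; v1 <- values[i]
  thr <- if (v1 == v0) l1 else l0 + (criterion - v0) * (l1 - l0) / (v1 - v0)
  res$threshold_db <- min(max(thr, l0), l1)
  res$bracket <- c(l0, l1)
  res
}

#' Bilinear interpolation of an image at fractional coordinates
#'
#' `img` is a y-by-x matrix; `xs`/`ys` are column/row coordinates (1-based).
#' Out-of-range coordinates are an error.
#' @keywords internal
#' @noRd
bilinear_sample <- function(img, ys, xs) {
  ny <- nrow(img); nx <- ncol(img)
  if (any(ys < 1 | ys > ny | xs < 1 | xs > nx))
    stop("sample coordinates fall outside the image")
  y0 <- pmin(floor(ys), ny - 1); x0 <- pmin(floor(xs), nx - 1)
  fy <- ys - y0; fx <- xs - x0
  img[cbind(y0, x0)] * (1 - fy) * (1 - fx) +
    img[cbind(y0 + 1, x0)] * fy * (1 - fx) +
    img[cbind(y0, x0 + 1)] * (1 - fy) * fx +
    img[cbind(y0 + 1, x0 + 1)] * fy * fx
}

#' Regional maxima of a matrix (8-neighborhood, plateau-aware)
#'
#' A regional maximum is a connected set of equal-valued cells none of whose
#' neighbors has a strictly greater value; a plateau is reported once at its
#' (rounded) centroid.  Only maxima strictly above `threshold` are returned.
#' @return data.frame with columns row, col, value
#' @keywords internal
#' @noRd
regional_maxima <- function(m, threshold = -Inf) {
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(-Inf, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- m
  nmax <- matrix(-Inf, nr, nc)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    nmax <- pmax(nmax, pad[(2:(nr + 1)) + dy, (2:(nc + 1)) + dx])
  }
  cand <- which(m > threshold & m >= nmax)
  if (!length(cand)) return(data.frame(row = integer(), col = integer(), value = numeric()))
  visited <- matrix(FALSE, nr, nc)
  out <- list()
  for (s in cand) {
    if (visited[s]) next
    v <- m[s]
    # flood the equal-valued plateau containing s
    comp <- integer(0); queue <- s; visited[s] <- TRUE
    is_max <- TRUE
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      comp <- c(comp, cur)
      r <- (cur - 1) %% nr + 1; cc <- (cur - 1) %/% nr + 1
      for (dy in -1:1) for (dx in -1:1) {
        if (dy == 0 && dx == 0) next
        rr <- r + dy; ccc <- cc + dx
        if (rr < 1 || rr > nr || ccc < 1 || ccc > nc) next
        idx <- rr + (ccc - 1) * nr
        if (m[idx] > v) is_max <- FALSE
        else if (m[idx] == v && !visited[idx]) { visited[idx] <- TRUE; queue <- c(queue, idx) }
      }
    }
    if (is_max) {
      rows <- (comp - 1) %% nr + 1; cols <- (comp - 1) %/% nr + 1
      out[[length(out) + 1]] <- data.frame(row = round(mean(rows)), col = round(mean(cols)), value = v)
    }
  }
  if (!length(out)) return(data.frame(row = integer(), col = integer(), value = numeric()))
  do.call(rbind, out)
}

# First index of the value nearest to x in v.
nearest_index <- function(v, x) which.min(abs(v - x))
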