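# Time synchronisation of sensor pairs: jump/tap marker detection for
# coarse alignment, then normalised cross-correlation for the residual
# integer-sample lag caused by cloth dynamics.

#' Detect the jump synchronisation marker
#'
#' The wear protocol opens and closes each recording with a jump, leaving a
#' distinctive high-magnitude spike.  Returns the sample index of the
#' maximum acceleration magnitude within the window.
#'
#' @param series an \code{\link{accel_series}}.
#' @param window numeric \code{c(start, end)} in seconds from the start of
#'   the series.
#' @param floor_g minimum peak magnitude in g to accept as a marker.
#' @return integer sample index (1-based).
#' @export
detect_jump_marker <- function(series, window = c(0, 5), floor_g = 2) {
  idx <- window_indices(series, window)
  mag <- magnitude(series)[idx]
  i <- which.max(mag)
  if (mag[i] < floor_g)
    fm_no_marker_error(sprintf(
      "no jump marker: peak magnitude %.3f g below floor %.2f g",
      mag[i], floor_g))
  idx[i]
}

window_indices <- function(series, window) {
  fs <- series$fs
  n <- n_samples(series)
  from <- max(1L, as.integer(floor(window[1L] * fs)) + 1L)
  to <- min(n, as.integer(ceiling(window[2L] * fs)))
  if (from > to) fm_validation_error("window lies outside the series")
  from:to
}

#' Detect the synchronisation taps
#'
#' Each sensor pair is tapped synchronously (four times in the protocol)
#' after the opening jump.  Finds the \code{n} largest-magnitude local
#' maxima within the window, separated by at least \code{min_sep_s}, and
#' returns their indices in time order.
#'
#' @param series an \code{\link{accel_series}}.
#' @param n number of taps expected (protocol default 4).
#' @param window numeric \code{c(start, end)} in seconds.
#' @param min_sep_s minimum separation between accepted peaks in seconds.
#' @param floor_g minimum peak magnitude in g.
#' @return sorted integer vector of \code{n} sample indices.
#' @export
detect_taps <- function(series, n = 4L, window = c(1, 4),
                        min_sep_s = 0.2, floor_g = 2) {
  if (n < 1L) fm_validation_error("n must be at least 1")
  idx <- window_indices(series, window)
  mag <- magnitude(series)[idx]
  m <- length(mag)
  if (m < 3L) fm_no_marker_error("window too short to contain taps")
  is_peak <- c(FALSE, mag[2:(m - 1L)] > mag[1:(m - 2L)] &
                      mag[2:(m - 1L)] >= mag[3:m], FALSE) & mag >= floor_g
  cand <- idx[is_peak]
  cand <- cand[order(mag[is_peak], decreasing = TRUE)]
  sep <- as.integer(round(min_sep_s * series$fs))
  picked <- integer(0)
  for (ci in cand) {
    if (!length(picked) || all(abs(picked - ci) >= sep))
      picked <- c(picked, ci)
    if (length(picked) == n) break
  }
  if (length(picked) < n)
    fm_no_marker_error(sprintf(
      "found only %d of %d qualifying tap peaks", length(picked), n))
  sort(picked)
}

#' Coarsely align a pair on the opening jump markers
#'
#' Detects the start jump in each stream, shifts so the jump indices
#' coincide, and trims both streams to their equal-length overlap.
#'
#' @param pair a \code{\link{sensor_pair}} whose streams both contain a
#'   detectable start jump.
#' @param window search window in seconds for the jump, per stream.
#' @param floor_g marker detection floor in g.
#' @return the aligned, equal-length \code{sensor_pair}.
#' @export
coarse_align <- function(pair, window = c(0, 5), floor_g = 2) {
  stopifnot(inherits(pair, "sensor_pair"))
  jb <- detect_jump_marker(pair$body, window, floor_g)
  jc <- detect_jump_marker(pair$clothing, window, floor_g)
  # Drop leading samples so both jumps land on the same index.
  drop_b <- max(0L, jb - jc)
  drop_c <- max(0L, jc - jb)
  nb <- n_samples(pair$body) - drop_b
  nc <- n_samples(pair$clothing) - drop_c
  n <- min(nb, nc)
  if (n < 1L) fm_validation_error("streams do not overlap after alignment")
  sensor_pair(slice_series(pair$body, drop_b + 1L, drop_b + n),
              slice_series(pair$clothing, drop_c + 1L, drop_c + n))
}

#' Estimate the inter-sensor lag by normalised cross-correlation
#'
#' For every integer shift in \code{[-max_lag, max_lag]} the Pearson
#' correlation between the overlapping parts of the two signals is
#' computed; the shift maximising it is the lag estimate.  Positive lag
#' means \code{b} (the clothing channel by convention) lags \code{a}.
#' Normalised correlation makes the estimate robust to the amplitude
#' scaling between body and garment channels; ties are broken toward the
#' smallest absolute lag, favouring the null hypothesis of synchrony.
#'
#' @param a,b equal-length \code{\link{accel_series}} (a = body reference).
#' @param axis which signal to correlate: \code{"y"} (default; the
#'   gravity-aligned axis carries the strongest activity signal), x, z, or
#'   magnitude.
#' @param max_lag search half-range in samples (default 2 s at the stream
#'   rate, comfortably above the sub-second garment lags observed in wear
#'   data).
#' @return list of class \code{lag_estimate}: \code{lag_samples},
#'   \code{lag_seconds}, \code{peak_xcorr}, \code{search_range}.
#' @export
estimate_lag_xcorr <- function(a, b, axis = "y", max_lag = NULL) {
  stopifnot(inherits(a, "accel_series"), inherits(b, "accel_series"))
  if (a$fs != b$fs) fm_validation_error("sampling rates differ")
  x <- axis_signal(a, axis)
  y <- axis_signal(b, axis)
  n <- length(x)
  if (length(y) != n) fm_validation_error("series lengths differ")
  if (is.null(max_lag)) max_lag <- as.integer(round(2 * a$fs))
  max_lag <- as.integer(max_lag)
  if (n < 2L * max_lag)
    fm_validation_error("series shorter than twice the lag search range")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    fm_undefined_correlation_error(
      "zero-variance input: cross-correlation undefined")
  shifts <- 0:max_lag
  shifts <- c(0L, as.vector(rbind(shifts[-1L], -shifts[-1L]))) # by |lag|
  best_r <- -Inf
  best_k <- 0L
  for (k in shifts) {
    # Positive k: y is x delayed by k, so y[i + k] pairs with x[i].
    if (k >= 0L) {
      xs <- x[1:(n - k)]; ys <- y[(1L + k):n]
    } else {
      xs <- x[(1L - k):n]; ys <- y[1:(n + k)]
    }
    if (stats::sd(xs) == 0 || stats::sd(ys) == 0) next
    r <- stats::cor(xs, ys)
    if (r > best_r + 1e-15) { best_r <- r; best_k <- k }
  }
  if (!is.finite(best_r))
    fm_undefined_correlation_error("correlation undefined at every shift")
  structure(list(lag_samples = best_k, lag_seconds = best_k / a$fs,
                 peak_xcorr = best_r, search_range = max_lag, fs = a$fs),
            class = "lag_estimate")
}

#' @export
print.lag_estimate <- function(x, ...) {
  cat(sprintf("<lag_estimate> %d samples (%.4g s) @ peak r = %.4f (search +/- %d)\n",
              x$lag_samples, x$lag_seconds, x$peak_xcorr, x$search_range))
  invisible(x)
}

#' Apply an estimated lag to a stream
#'
#' Drops leading (positive lag) or trailing (negative lag) samples so that
#' the shifted stream lines up with its reference; no fabricated samples
#' are introduced, so the result is shorter by \code{|lag|}.
#'
#' @param series the lagging \code{\link{accel_series}} (clothing channel).
#' @param lag a \code{\link{lag_estimate}} or integer sample count.
#' @return the trimmed, shifted series.
#' @export
apply_lag <- function(series, lag) {
  k <- if (inherits(lag, "lag_estimate")) lag$lag_samples else as.integer(lag)
  n <- n_samples(series)
  if (abs(k) >= n)
    fm_validation_error("lag must be smaller than the series length")
  if (k == 0L) return(series)
  if (k > 0L) slice_series(series, k + 1L, n)
  else slice_series(series, 1L, n + k)
}

#' Lag-correct a pair and trim to the common overlap
#'
#' Shifts the clothing stream by the estimated lag and trims both streams
#' to equal length so only genuinely overlapping samples enter downstream
#' statistics.
#'
#' @param pair a \code{\link{sensor_pair}}.
#' @param lag a \code{\link{lag_estimate}} or integer (positive = clothing
#'   lags body).
#' @return the lag-corrected \code{sensor_pair}.
#' @export
align_pair <- function(pair, lag) {
  k <- if (inherits(lag, "lag_estimate")) lag$lag_samples else as.integer(lag)
  n <- min(n_samples(pair$body), n_samples(pair$clothing))
  if (abs(k) >= n) fm_validation_error("lag exceeds the stream length")
  m <- n - abs(k)
  if (k >= 0L) {
    body <- slice_series(pair$body, 1L, m)
    clothing <- slice_series(pair$clothing, k + 1L, k + m)
  } else {
    body <- slice_series(pair$body, 1L - k, n)
    clothing <- slice_series(pair$clothing, 1L, m)
  }
  # Keep the body timeline: clothing t0 is snapped to the body's so diary
  # lookups remain valid for both streams after correction.
  clothing$t0 <- body$t0
  sensor_pair(body, clothing)
}
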