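# Gravity estimation and orientation correction.  Each stream is rotated so
# its principal gravity direction maps onto the +y axis, using the
# closed-form axis-angle (Rodrigues) rotation: the axis is perpendicular to
# both the gravity estimate and y, and the angle is the angle between them.
# Heading (rotation about gravity) is unobservable with an accelerometer
# alone and is left uncorrected.

# Cross-product (skew-symmetric) matrix of a 3-vector.
skew3 <- function(k) {
  matrix(c(0, k[3L], -k[2L],
           -k[3L], 0, k[1L],
           k[2L], -k[1L], 0), 3L, 3L)
}

# R = I + sin(theta) K + (1 - cos(theta)) K^2 for unit axis k.
rodrigues_matrix <- function(axis, angle) {
  K <- skew3(axis / sqrt(sum(axis^2)))
  diag(3L) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Axis-angle rotation specification
#'
#' @param axis unit 3-vector rotation axis.
#' @param angle rotation angle in radians.
#' @return list of class \code{rotation_spec} with elements \code{axis},
#'   \code{angle} and the 3 x 3 orthonormal \code{matrix}.
#' @export
rotation_spec <- function(axis, angle) {
  nrm <- sqrt(sum(axis^2))
  if (nrm < 1e-12) fm_validation_error("rotation axis must be non-zero")
  axis <- axis / nrm
  structure(list(axis = axis, angle = angle,
                 matrix = rodrigues_matrix(axis, angle)),
            class = "rotation_spec")
}

#' @export
print.rotation_spec <- function(x, ...) {
  cat(sprintf("<rotation_spec> angle = %.4f rad (%.2f deg), axis = (%.4f, %.4f, %.4f)\n",
              x$angle, x$angle * 180 / pi, x$axis[1L], x$axis[2L], x$axis[3L]))
  invisible(x)
}

#' Rotation taking one unit vector onto another
#'
#' Returns the minimal rotation mapping \code{v_from} to \code{v_to}: axis
#' along their cross product, angle \code{atan2(|v_from x v_to|,
#' v_from . v_to)}.  Degenerate cases: (near-)identical vectors give the
#' identity; (near-)antiparallel vectors give a 180-degree rotation about a
#' deterministic perpendicular axis (x, or y when v_from is along x).
#'
#' @param v_from,v_to unit 3-vectors.
#' @return a \code{\link{rotation_spec}} with \code{matrix \%*\% v_from ==
#'   v_to} to 1e-10.
#' @export
rodrigues_from_to <- function(v_from, v_to) {
  v_from <- v_from / sqrt(sum(v_from^2))
  v_to <- v_to / sqrt(sum(v_to^2))
  cr <- c(v_from[2L] * v_to[3L] - v_from[3L] * v_to[2L],
          v_from[3L] * v_to[1L] - v_from[1L] * v_to[3L],
          v_from[1L] * v_to[2L] - v_from[2L] * v_to[1L])
  s <- sqrt(sum(cr^2))
  d <- sum(v_from * v_to)
  if (s < 1e-12) {
    if (d > 0) return(rotation_spec(c(1, 0, 0), 0))
    # Antiparallel: any perpendicular axis works; pick deterministically.
    perp <- if (abs(v_from[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    perp <- perp - sum(perp * v_from) * v_from
    return(rotation_spec(perp / sqrt(sum(perp^2)), pi))
  }
  rotation_spec(cr / s, atan2(s, d))
}

#' Estimate the gravity direction of a stream
#'
#' \code{static_window} takes the mean acceleration over the 2-second window
#' with the lowest total (three-axis) variance -- the most static stretch of
#' the recording.  \code{low_pass_mean} takes the overall mean of the signal
#' low-passed at 0.25 Hz, which averages gravity across postures and is the
#' better choice for long mixed-activity records.  Means over dynamic
#' activity bias the direction along the movement axis, so
#' \code{static_window} is the default.
#'
#' @param series an \code{\link{accel_series}} of duration >= 2 s.
#' @param mode \code{"static_window"} (default) or \code{"low_pass_mean"}.
#' @return unit 3-vector.
#' @export
estimate_gravity <- function(series, mode = c("static_window",
                                              "low_pass_mean")) {
  mode <- match.arg(mode)
  if (duration(series) < 2)
    fm_validation_error("series must be at least 2 s long to estimate gravity")
  fs <- series$fs
  n <- n_samples(series)
  if (mode == "static_window") {
    w <- max(2L, as.integer(round(2 * fs)))
    if (w >= n) {
      g <- colMeans(series$data)
    } else {
      # Total variance of each length-w window via cumulative sums.
      tot <- numeric(n - w + 1L)
      for (j in 1:3) {
        x <- series$data[, j]
        c1 <- cumsum(c(0, x)); c2 <- cumsum(c(0, x^2))
        s1 <- c1[(w + 1L):(n + 1L)] - c1[1L:(n - w + 1L)]
        s2 <- c2[(w + 1L):(n + 1L)] - c2[1L:(n - w + 1L)]
        tot <- tot + (s2 - s1^2 / w) / (w - 1L)
      }
      i0 <- which.min(tot)
      g <- colMeans(series$data[i0:(i0 + w - 1L), , drop = FALSE])
    }
  } else {
    nyq <- fs / 2
    bf <- signal::butter(2, 0.25 / nyq, type = "low")
    g <- vapply(1:3, function(j)
      mean(signal::filtfilt(bf, series$data[, j])), 0)
  }
  nrm <- sqrt(sum(g^2))
  if (nrm < 0.5)
    fm_stop(sprintf(
      "gravity estimate unreliable: mean magnitude %.3f g < 0.5 g", nrm),
      "fm_unreliable_gravity_error")
  unname(g / nrm)
}

#' Rotate a stream so gravity aligns with the +y axis
#'
#' Estimates the gravity direction, builds the Rodrigues rotation taking it
#' to (0, 1, 0) and applies it to every sample.  Rotations preserve the
#' per-sample magnitude exactly.
#'
#' @param series an \code{\link{accel_series}}.
#' @param mode gravity estimation mode, see \code{\link{estimate_gravity}}.
#' @param gravity optional known gravity unit vector, bypassing estimation.
#' @return list with \code{series} (the rotated stream) and \code{rotation}
#'   (the applied \code{\link{rotation_spec}}).
#' @export
gravity_align <- function(series, mode = "static_window", gravity = NULL) {
  g <- if (is.null(gravity)) estimate_gravity(series, mode) else
    gravity / sqrt(sum(gravity^2))
  rot <- rodrigues_from_to(g, c(0, 1, 0))
  out <- set_data(series, series$data %*% t(rot$matrix))
  list(series = out, rotation = rot)
}
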