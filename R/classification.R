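# Threshold decision-tree activity classification on two features of the
# gravity-aligned y-axis: the acceleration itself (posture: ~1 g upright,
# ~0 g with the thigh horizontal) and its 250 ms moving variance (movement
# and transition intensity).  Agreement between the body-worn and
# clothing-mounted classifications is tabulated as a row-normalised
# confusion matrix with the body-worn labels as the reference.

CLASS_LEVELS <- c("walking_running", "transition", "sitting", "standing")

#' Centred moving variance
#'
#' Sliding-window sample variance with the window centred on each sample;
#' edges use the truncated available window so the output has the same
#' length as the input.  The window length in samples is
#' \code{round(window_ms * fs / 1000)} with halves rounded up (250 ms at
#' 50 Hz gives 12.5, rounded to 13 -- an odd window centres cleanly).
#'
#' @param x numeric vector.
#' @param window_ms window size in milliseconds (default 250, short enough
#'   to catch brief transition spikes).
#' @param fs sampling rate in Hz.
#' @return numeric vector of per-sample variances, same length as \code{x}.
#' @export
moving_variance <- function(x, window_ms = 250, fs = 50) {
  w <- as.integer(floor(window_ms * fs / 1000 + 0.5)) # round half up
  if (w < 2L) fm_validation_error("window must span at least 2 samples")
  n <- length(x)
  if (n < w) fm_validation_error("sequence shorter than the window")
  half_lo <- (w - 1L) %/% 2L
  half_hi <- w - 1L - half_lo
  c1 <- cumsum(c(0, x)); c2 <- cumsum(c(0, x^2))
  i <- seq_len(n)
  lo <- pmax(1L, i - half_lo)
  hi <- pmin(n, i + half_hi)
  m <- hi - lo + 1L
  s1 <- c1[hi + 1L] - c1[lo]
  s2 <- c2[hi + 1L] - c2[lo]
  v <- (s2 - s1^2 / m) / (m - 1L)
  pmax(v, 0) # clamp tiny negative rounding residue
}

#' Decision-tree thresholds
#'
#' Defaults are derived from the physics of the features rather than fitted:
#' upright y-axis acceleration sits near 1 g and seated near 0 g, so the
#' posture split points are placed between them; the variance splits
#' separate sensor noise, transition ramps and gait oscillation.
#'
#' @param y_sit_max y-axis acceleration in g at or below which a static
#'   posture is called sitting.
#' @param y_stand_min y-axis acceleration in g at or above which a static
#'   posture is called standing.
#' @param var_trans_min moving variance in g^2 above which a sample is at
#'   least a transition.
#' @param var_move_min moving variance in g^2 above which a sample is
#'   walking/running.
#' @param window_ms moving-variance window in milliseconds.
#' @return list of class \code{classifier_thresholds}.
#' @export
classifier_thresholds <- function(y_sit_max = 0.5, y_stand_min = 0.7,
                                  var_trans_min = 0.005, var_move_min = 0.05,
                                  window_ms = 250) {
  if (!(0 <= var_trans_min && var_trans_min < var_move_min))
    fm_validation_error("need 0 <= var_trans_min < var_move_min")
  if (!(y_sit_max < y_stand_min))
    fm_validation_error("need y_sit_max < y_stand_min")
  structure(list(y_sit_max = y_sit_max, y_stand_min = y_stand_min,
                 var_trans_min = var_trans_min, var_move_min = var_move_min,
                 window_ms = window_ms),
            class = "classifier_thresholds")
}

#' Classify samples with the fixed threshold tree
#'
#' Movement intensity is tested before posture: moving variance at or above
#' \code{var_move_min} gives walking/running (the two gaits are not split);
#' at or above \code{var_trans_min} gives transition; otherwise the static
#' posture is read off the y-axis level (standing at or above
#' \code{y_stand_min}, sitting at or below \code{y_sit_max}, and the
#' ambiguous band between them is labelled transition).
#'
#' @param y_accel gravity-aligned y-axis acceleration in g.
#' @param mov_var matching moving variance in g^2 (see
#'   \code{\link{moving_variance}}).
#' @param thresholds a \code{\link{classifier_thresholds}}.
#' @return character vector of labels drawn from walking_running,
#'   transition, sitting, standing.
#' @export
classify_samples <- function(y_accel, mov_var,
                             thresholds = classifier_thresholds()) {
  if (length(y_accel) != length(mov_var))
    fm_validation_error("y_accel and mov_var lengths differ")
  th <- thresholds
  out <- rep("transition", length(y_accel))
  moving <- mov_var >= th$var_move_min
  trans <- !moving & mov_var >= th$var_trans_min
  static <- !moving & !trans
  out[moving] <- "walking_running"
  out[static & y_accel >= th$y_stand_min] <- "standing"
  out[static & y_accel <= th$y_sit_max] <- "sitting"
  out
}

#' Estimate classifier thresholds from data
#'
#' \code{fixed_default} returns the documented physics-based constants.
#' \code{quantile} is a data-driven surrogate for threshold choice by
#' visual inspection: the variance splits are set from the 50th and 90th
#' percentiles of the moving variance and the posture splits from the two
#' dominant modes of the low-variance y-axis histogram (placed at one third
#' and two thirds of the inter-mode gap).  If the y histogram is unimodal
#' the fixed defaults are returned with a warning.
#'
#' @param y_accel y-axis acceleration in g, at least 60 s of data.
#' @param mov_var matching moving variance in g^2.
#' @param method \code{"fixed_default"} or \code{"quantile"}.
#' @param fs sampling rate in Hz (to enforce the minimum duration).
#' @return a \code{\link{classifier_thresholds}}.
#' @export
estimate_thresholds <- function(y_accel, mov_var,
                                method = c("fixed_default", "quantile"),
                                fs = 50) {
  method <- match.arg(method)
  if (length(y_accel) < 60 * fs)
    fm_validation_error("need at least 60 s of data to estimate thresholds")
  if (method == "fixed_default") return(classifier_thresholds())
  v_trans <- unname(stats::quantile(mov_var, 0.50))
  v_move <- unname(stats::quantile(mov_var, 0.90))
  if (!(v_trans < v_move)) {
    warning("degenerate variance distribution; falling back to fixed defaults")
    return(classifier_thresholds())
  }
  y_static <- y_accel[mov_var < v_trans]
  if (length(y_static) < 100L) y_static <- y_accel
  dens <- stats::density(y_static, n = 512)
  k <- length(dens$y)
  peaks <- which(dens$y[2:(k - 1L)] > dens$y[1:(k - 2L)] &
                 dens$y[2:(k - 1L)] >= dens$y[3:k]) + 1L
  peaks <- peaks[dens$y[peaks] >= 0.1 * max(dens$y[peaks])]
  if (length(peaks) < 2L) {
    warning("unimodal y-axis histogram; falling back to fixed defaults")
    return(classifier_thresholds())
  }
  modes <- sort(dens$x[peaks[order(dens$y[peaks], decreasing = TRUE)][1:2]])
  gap <- modes[2L] - modes[1L]
  classifier_thresholds(y_sit_max = modes[1L] + gap / 3,
                        y_stand_min = modes[2L] - gap / 3,
                        var_trans_min = v_trans, var_move_min = v_move)
}

#' Body-vs-clothing agreement confusion matrix
#'
#' Cross-tabulates two per-sample label sequences with the body-worn
#' classification as the reference (rows) and the clothing-mounted
#' classification as the columns, and row-normalises to percentages.
#'
#' @param ref reference label sequence (body-worn classification).
#' @param test comparison label sequence (clothing-mounted classification).
#' @return list of class \code{confusion_matrix} with \code{classes},
#'   integer \code{counts} and \code{row_pct} (rows sum to 100; all-zero
#'   rows are NA).
#' @export
confusion <- function(ref, test) {
  if (length(ref) != length(test)) fm_validation_error("lengths differ")
  bad <- setdiff(unique(c(ref, test)), CLASS_LEVELS)
  if (length(bad))
    fm_validation_error(sprintf("unknown class label(s): %s",
                                paste(bad, collapse = ", ")))
  counts <- table(factor(ref, CLASS_LEVELS), factor(test, CLASS_LEVELS))
  counts <- matrix(as.integer(counts), 4L, 4L,
                   dimnames = list(ref = CLASS_LEVELS, test = CLASS_LEVELS))
  rs <- rowSums(counts)
  row_pct <- sweep(counts, 1L, ifelse(rs > 0, rs, NA), "/") * 100
  structure(list(classes = CLASS_LEVELS, counts = counts, row_pct = row_pct),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, digits = 1, ...) {
  cat("<confusion_matrix> row = reference (body), column = test (clothing); row %\n")
  print(round(x$row_pct, digits))
  invisible(x)
}

#' Classify a gravity-aligned stream end to end
#'
#' Convenience wrapper: moving variance of the y-axis, then the threshold
#' tree.
#'
#' @param series a gravity-aligned \code{\link{accel_series}}.
#' @param thresholds a \code{\link{classifier_thresholds}}.
#' @return character label vector, one per sample.
#' @export
classify_series <- function(series, thresholds = classifier_thresholds()) {
  y <- axis_signal(series, "y")
  mv <- moving_variance(y, thresholds$window_ms, series$fs)
  classify_samples(y, mv, thresholds)
}
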