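# Per-activity correlation analysis.  Shorter instances (30-40 s, i.e.
# 1500-2000 samples at 50 Hz) of each activity are extracted from the diary
# and the body/clothing Pearson correlation is computed per axis under five
# cumulative preprocessing variants, then summarised per group as
# median +/- variance across instances.

VARIANTS <- c("original", "time_aligned", "rotated", "aligned_rotated",
              "aligned_rotated_activitywise")

#' Extract per-activity analysis segments
#'
#' Carves up to \code{n_instances} non-overlapping segments of a given
#' activity out of the diary entries, each within \code{length_bounds}
#' samples, taken from the interior of the entries (a 0.5 s guard band is
#' kept clear of each entry edge so transition artefacts stay out).
#'
#' @param pair an aligned, equal-length \code{\link{sensor_pair}}; diary
#'   times are interpreted on the body stream's timeline.
#' @param log an \code{\link{activity_log}}.
#' @param label activity to extract.
#' @param n_instances maximum number of segments (study protocol used 3).
#' @param length_bounds numeric \code{c(min, max)} segment length in samples.
#' @param guard_s guard band in seconds at entry edges.
#' @return list of segments, each a list with \code{label},
#'   \code{instance_index}, \code{body}, \code{clothing} and \code{length};
#'   empty (with a warning) when no diary entry qualifies.
#' @export
extract_segments <- function(pair, log, label, n_instances = 3L,
                             length_bounds = c(1500L, 2000L), guard_s = 0.5) {
  stopifnot(inherits(pair, "sensor_pair"), inherits(log, "activity_log"))
  fs <- pair$body$fs
  n <- min(n_samples(pair$body), n_samples(pair$clothing))
  lo <- as.integer(length_bounds[1L]); hi <- as.integer(length_bounds[2L])
  guard <- as.integer(round(guard_s * fs))
  segs <- list()
  for (i in which(log$label == label)) {
    if (length(segs) >= n_instances) break
    s_off <- as.numeric(difftime(log$start[i], pair$body$t0, units = "secs"))
    e_off <- as.numeric(difftime(log$end[i], pair$body$t0, units = "secs"))
    from <- max(1L, as.integer(round(s_off * fs)) + 1L + guard)
    to <- min(n, as.integer(round(e_off * fs)) - guard)
    while (to - from + 1L >= lo && length(segs) < n_instances) {
      len <- min(hi, to - from + 1L)
      seg_to <- from + len - 1L
      segs[[length(segs) + 1L]] <- list(
        label = label, instance_index = length(segs) + 1L,
        body = slice_series(pair$body, from, seg_to),
        clothing = slice_series(pair$clothing, from, seg_to),
        length = len)
      from <- seg_to + 1L
    }
  }
  if (!length(segs))
    warning(sprintf("no qualifying '%s' entry of >= %d samples", label, lo))
  segs
}

#' Pearson product-moment correlation
#'
#' Thin validated wrapper around \code{stats::cor}: equal lengths of at
#' least 3 and nonzero variance in both inputs are required, matching the
#' assumptions of the sensor-pair comparison.
#'
#' @param a,b numeric vectors.
#' @return correlation coefficient in [-1, 1].
#' @export
pearson_r <- function(a, b) {
  if (length(a) != length(b)) fm_validation_error("lengths differ")
  if (length(a) < 3L) fm_validation_error("need at least 3 observations")
  if (anyNA(a) || anyNA(b)) fm_validation_error("missing values not allowed")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    fm_undefined_correlation_error("zero variance: correlation undefined")
  stats::cor(a, b)
}

#' Advisory normality check (Shapiro-Wilk)
#'
#' Applied to the acceleration samples before correlating, as a check on
#' the linear-association interpretation of Pearson's r.  The verdict is
#' advisory only -- it is logged, never used to gate the correlation.
#' Shapiro-Wilk accepts at most 5000 points, so longer inputs are
#' subsampled with a fixed internal seed for reproducibility.
#'
#' @param x numeric vector, length >= 20.
#' @param alpha significance level for the verdict.
#' @return list with \code{statistic}, \code{p_value} and \code{verdict}
#'   ("normal" / "non-normal").
#' @export
normality_check <- function(x, alpha = 0.05) {
  if (length(x) < 20L) fm_validation_error("need at least 20 observations")
  if (stats::sd(x) == 0) {
    warning("constant input: normality check degenerate")
    return(list(statistic = NA_real_, p_value = NA_real_,
                verdict = "non-normal"))
  }
  if (length(x) > 5000L)
    x <- with_seed(20082L, sample(x, 5000L))
  sw <- stats::shapiro.test(x)
  list(statistic = unname(sw$statistic), p_value = sw$p.value,
       verdict = if (sw$p.value < alpha) "non-normal" else "normal")
}

# Gravity-align both streams of a pair (per-stream rotation).
rotate_pair <- function(pair, mode = "static_window") {
  b <- gravity_align(pair$body, mode = mode)
  c <- gravity_align(pair$clothing, mode = mode)
  list(pair = sensor_pair(b$series, c$series),
       rotation_body = b$rotation, rotation_clothing = c$rotation)
}

#' Correlate a sensor pair under the five preprocessing variants
#'
#' The variants are cumulative: \code{original} (raw), \code{time_aligned}
#' (global lag correction by cross-correlation), \code{rotated} (per-segment
#' gravity alignment only), \code{aligned_rotated} (lag correction then
#' per-segment gravity alignment) and \code{aligned_rotated_activitywise}
#' (additionally re-estimating and removing the residual lag within each
#' activity segment, since cloth dynamics make the lag activity-dependent).
#' Pearson's r is reported per instance, per variant, per axis.
#'
#' @param pair a \code{\link{sensor_pair}} (equal lengths; already
#'   coarse-aligned if markers were present).
#' @param log an \code{\link{activity_log}}.
#' @param activity activity label, or a character vector of labels.
#' @param n_instances,length_bounds passed to \code{\link{extract_segments}}.
#' @param axis_lag axis used for lag estimation (default y).
#' @param max_lag lag search half-range in samples (default 2 s).
#' @param gravity_mode gravity estimation mode for the rotation variants.
#' @return data frame with columns activity, instance, variant, axis, r, n.
#' @export
compare_variants <- function(pair, log, activity, n_instances = 3L,
                             length_bounds = c(1500L, 2000L),
                             axis_lag = "y", max_lag = NULL,
                             gravity_mode = "static_window") {
  stopifnot(inherits(pair, "sensor_pair"))
  if (is.null(max_lag)) max_lag <- as.integer(round(2 * pair$body$fs))
  lag <- estimate_lag_xcorr(pair$body, pair$clothing, axis = axis_lag,
                            max_lag = max_lag)
  pair_lagged <- align_pair(pair, lag)

  seg_rows <- function(seg, variant, act) {
    rows <- lapply(c("x", "y", "z"), function(ax) {
      data.frame(activity = act, instance = seg$instance_index,
                 variant = variant, axis = ax,
                 r = pearson_r(axis_signal(seg$body, ax),
                               axis_signal(seg$clothing, ax)),
                 n = seg$length, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
  rotate_segment <- function(seg) {
    seg$body <- gravity_align(seg$body, mode = gravity_mode)$series
    seg$clothing <- gravity_align(seg$clothing, mode = gravity_mode)$series
    seg
  }
  relag_segment <- function(seg, search) {
    l2 <- estimate_lag_xcorr(seg$body, seg$clothing, axis = axis_lag,
                             max_lag = search)
    p2 <- align_pair(sensor_pair(seg$body, seg$clothing), l2)
    seg$body <- p2$body; seg$clothing <- p2$clothing
    seg$length <- n_samples(p2$body)
    seg
  }

  out <- list()
  for (act in activity) {
    raw_segs <- extract_segments(pair, log, act, n_instances, length_bounds)
    lag_segs <- extract_segments(pair_lagged, log, act, n_instances,
                                 length_bounds)
    seg_search <- as.integer(min(max_lag,
      floor(min(c(Inf, vapply(lag_segs, `[[`, 0L, "length"))) / 4)))
    for (seg in raw_segs) {
      out[[length(out) + 1L]] <- seg_rows(seg, "original", act)
      out[[length(out) + 1L]] <- seg_rows(rotate_segment(seg), "rotated", act)
    }
    for (seg in lag_segs) {
      out[[length(out) + 1L]] <- seg_rows(seg, "time_aligned", act)
      rs <- rotate_segment(seg)
      out[[length(out) + 1L]] <- seg_rows(rs, "aligned_rotated", act)
      out[[length(out) + 1L]] <- seg_rows(relag_segment(rs, seg_search),
                                          "aligned_rotated_activitywise", act)
    }
  }
  if (!length(out))
    return(data.frame(activity = character(), instance = integer(),
                      variant = character(), axis = character(),
                      r = numeric(), n = integer(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res$variant <- factor(res$variant, levels = VARIANTS)
  res[order(res$activity, res$instance, res$variant, res$axis), ]
}

#' Aggregate correlations across instances
#'
#' Summarises per-instance correlation coefficients as the median and the
#' population variance (divide by n; switch with \code{var_type}) within
#' each group.  Groups with a single instance report the median only, with
#' \code{NA} variance.
#'
#' @param results data frame from \code{\link{compare_variants}}.
#' @param group_by character vector of grouping columns (default activity,
#'   variant, axis).
#' @param var_type \code{"population"} (default) or \code{"sample"}.
#' @return data frame with the grouping columns plus \code{median_r},
#'   \code{var_r} and \code{n_instances}.
#' @export
aggregate_instances <- function(results,
                                group_by = c("activity", "variant", "axis"),
                                var_type = c("population", "sample")) {
  var_type <- match.arg(var_type)
  if (!nrow(results)) {
    warning("no correlation results to aggregate")
    return(data.frame())
  }
  key <- interaction(results[group_by], drop = TRUE, lex.order = TRUE)
  pieces <- lapply(split(results, key), function(g) {
    r <- g$r
    v <- if (length(r) < 2L) NA_real_
         else if (var_type == "population") mean((r - mean(r))^2)
         else stats::var(r)
    cbind(g[1L, group_by, drop = FALSE],
          data.frame(median_r = stats::median(r), var_r = v,
                     n_instances = length(r)))
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}
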