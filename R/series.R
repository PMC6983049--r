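#' @keywords internal
"_PACKAGE"

# Classed conditions so callers can branch on failure modes.
fm_stop <- function(msg, class, call. = FALSE) {
  stop(structure(
    class = c(class, "fm_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1))
  ))
}

fm_validation_error <- function(msg) fm_stop(msg, "fm_validation_error")
fm_parse_error      <- function(msg) fm_stop(msg, "fm_parse_error")
fm_config_error     <- function(msg) fm_stop(msg, "fm_config_error")
fm_no_marker_error  <- function(msg) fm_stop(msg, "fm_no_marker_error")
fm_undefined_correlation_error <- function(msg)
  fm_stop(msg, "fm_undefined_correlation_error")
fm_io_error         <- function(msg) fm_stop(msg, "fm_io_error")

PLACEMENT_SITES    <- c("waist", "thigh", "ankle")
PLACEMENT_GARMENTS <- c("body", "clothing")
ACTIVITY_LABELS    <- c("walking", "running", "sitting", "bus_ride",
                        "standing", "other")

#' Uniformly sampled tri-axial acceleration stream
#'
#' Container for a single accelerometer recording: an n x 3 matrix of
#' accelerations in g (columns \code{ax}, \code{ay}, \code{az}), a sampling
#' rate \code{fs} in Hz and the timestamp \code{t0} of the first sample.
#' Sample \code{i} (1-based) is at time \code{t0 + (i - 1) / fs}; per-row
#' clock jitter is never stored.  By device convention the y-axis is the
#' nominal gravity axis when the wearer is upright.
#'
#' @param data numeric n x 3 matrix (or data frame) of accelerations in g.
#' @param fs sampling rate in Hz (the study devices record at 50 Hz).
#' @param t0 POSIXct timestamp of the first sample.
#' @param sensor_id free-text sensor identifier.
#' @param placement optional placement string \code{"<site>:<garment>"} with
#'   site one of waist/thigh/ankle and garment one of body/clothing, or NA.
#' @return An object of class \code{accel_series}.
#' @export
accel_series <- function(data, fs,
                         t0 = as.POSIXct("1970-01-01 09:00:00", tz = "UTC"),
                         sensor_id = "sensor", placement = NA_character_) {
  data <- as.matrix(data)
  if (!is.numeric(data) || ncol(data) != 3L)
    fm_validation_error("accel data must be a numeric n x 3 matrix")
  if (nrow(data) == 0L)
    fm_validation_error("accel data must contain at least one sample")
  if (anyNA(data))
    fm_validation_error("accel data must not contain missing values")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    fm_validation_error("fs must be a single positive number")
  if (!is.na(placement)) {
    parts <- strsplit(placement, ":", fixed = TRUE)[[1L]]
    if (length(parts) != 2L || !(parts[1L] %in% PLACEMENT_SITES) ||
        !(parts[2L] %in% PLACEMENT_GARMENTS))
      fm_validation_error(sprintf("invalid placement '%s'", placement))
  }
  colnames(data) <- c("ax", "ay", "az")
  structure(
    list(data = data, fs = as.numeric(fs),
         t0 = as.POSIXct(t0, tz = "UTC"),
         sensor_id = as.character(sensor_id), placement = placement),
    class = "accel_series")
}

#' @export
print.accel_series <- function(x, ...) {
  cat(sprintf("<accel_series> %s (%s): %d samples @ %g Hz (%.1f s), t0 = %s\n",
              x$sensor_id,
              if (is.na(x$placement)) "unplaced" else x$placement,
              n_samples(x), x$fs, duration(x),
              format(x$t0, "%Y-%m-%dT%H:%M:%OS2")))
  invisible(x)
}

#' Number of samples in a series
#' @param series an \code{accel_series}.
#' @return integer sample count.
#' @export
n_samples <- function(series) nrow(series$data)

#' Duration of a series in seconds
#' @param series an \code{accel_series}.
#' @return duration \code{n / fs} in seconds.
#' @export
duration <- function(series) n_samples(series) / series$fs

#' Sample times relative to the first sample
#' @param series an \code{accel_series}.
#' @return numeric vector of times in seconds, starting at 0.
#' @export
sample_times <- function(series) (seq_len(n_samples(series)) - 1L) / series$fs

#' Per-sample acceleration magnitude
#' @param series an \code{accel_series}.
#' @return numeric vector of Euclidean norms in g.
#' @export
magnitude <- function(series) sqrt(rowSums(series$data^2))

#' Extract a single axis (or the magnitude) as a numeric vector
#' @param series an \code{accel_series}.
#' @param axis \code{"x"}, \code{"y"}, \code{"z"} or \code{"magnitude"}.
#' @return numeric vector in g.
#' @export
axis_signal <- function(series, axis = c("y", "x", "z", "magnitude")) {
  axis <- match.arg(axis)
  if (axis == "magnitude") return(magnitude(series))
  series$data[, paste0("a", axis)]
}

# Replace the sample matrix, keeping metadata.
set_data <- function(series, data) {
  series$data <- data
  colnames(series$data) <- c("ax", "ay", "az")
  series
}

# Slice by sample index, shifting t0 so absolute timing stays consistent.
slice_series <- function(series, from, to) {
  n <- n_samples(series)
  if (from < 1L || to > n || from > to)
    fm_validation_error(sprintf("invalid slice [%d, %d] of %d samples",
                                from, to, n))
  out <- series
  out$data <- series$data[from:to, , drop = FALSE]
  out$t0 <- series$t0 + (from - 1L) / series$fs
  out
}

#' Shift a series in time by an integer number of samples
#'
#' Positive \code{k} delays the stream: the first sample is repeated \code{k}
#' times at the head and the tail is dropped.  Negative \code{k} advances it
#' (last sample repeated at the tail).  Length and \code{t0} are unchanged;
#' the padded edge is documented so downstream lag tests can exclude it.
#'
#' @param series an \code{accel_series}.
#' @param k integer shift in samples.
#' @return shifted \code{accel_series} of equal length.
#' @export
shift_series <- function(series, k) {
  k <- as.integer(k)
  n <- n_samples(series)
  if (abs(k) >= n)
    fm_validation_error("shift must be smaller than the series length")
  if (k == 0L) return(series)
  d <- series$data
  if (k > 0L) {
    d <- rbind(d[rep(1L, k), , drop = FALSE], d[1:(n - k), , drop = FALSE])
  } else {
    m <- -k
    d <- rbind(d[(m + 1L):n, , drop = FALSE], d[rep(n, m), , drop = FALSE])
  }
  set_data(series, d)
}

#' Activity diary annotations
#'
#' @param label character vector of activity labels; unknown labels are
#'   replaced by \code{"other"} with a warning.
#' @param start,end POSIXct vectors; each entry must satisfy start < end and
#'   entries must not overlap once sorted by start.
#' @return data frame of class \code{activity_log}, sorted by start.
#' @export
activity_log <- function(label, start, end) {
  label <- tolower(as.character(label))
  unknown <- !(label %in% ACTIVITY_LABELS)
  if (any(unknown)) {
    warning(sprintf("unknown activity label(s) %s replaced by 'other'",
                    paste(unique(label[unknown]), collapse = ", ")))
    label[unknown] <- "other"
  }
  start <- as.POSIXct(start, tz = "UTC")
  end <- as.POSIXct(end, tz = "UTC")
  if (length(label) != length(start) || length(start) != length(end))
    fm_validation_error("label, start and end must have equal length")
  if (any(!(start < end)))
    fm_validation_error("every activity entry must satisfy start < end")
  o <- order(start)
  label <- label[o]; start <- start[o]; end <- end[o]
  if (length(start) > 1L && any(start[-1L] < end[-length(end)]))
    fm_validation_error("activity entries overlap")
  structure(data.frame(label = label, start = start, end = end,
                       stringsAsFactors = FALSE),
            class = c("activity_log", "data.frame"))
}

#' Pair a body-worn and a clothing-mounted stream
#'
#' @param body,clothing \code{accel_series} covering the same wear period at
#'   the same sampling rate.
#' @return object of class \code{sensor_pair}.
#' @export
sensor_pair <- function(body, clothing) {
  stopifnot(inherits(body, "accel_series"), inherits(clothing, "accel_series"))
  if (body$fs != clothing$fs)
    fm_validation_error("body and clothing streams must share a sampling rate")
  structure(list(body = body, clothing = clothing), class = "sensor_pair")
}

#' @export
print.sensor_pair <- function(x, ...) {
  cat("<sensor_pair>\n  body:     "); print(x$body)
  cat("  clothing: "); print(x$clothing)
  invisible(x)
}
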