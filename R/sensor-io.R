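# CSV dialect: optional "# key=value" comment lines (fs, sensor_id,
# placement), then a "timestamp,ax,ay,az" header, then one row per sample
# with an ISO-8601 timestamp and accelerations in g.  After parsing, sample
# times are re-derived from t0 + i/fs; per-row clock jitter is discarded
# because all downstream computation assumes uniform sampling.

#' Read a raw tri-axial accelerometer CSV
#'
#' @param path path to a CSV file in the package dialect (see
#'   \code{\link{write_accel_csv}}).
#' @param fs_expected sampling rate in Hz the caller expects.  If the file
#'   declares a different rate in its \code{# fs=} comment, a configuration
#'   error is raised; if the file declares none, \code{fs_expected} is used.
#' @return an \code{\link{accel_series}}.
#' @export
read_accel_csv <- function(path, fs_expected = 50) {
  if (!file.exists(path)) fm_io_error(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  meta_idx <- grep("^#", lines)
  meta <- list()
  for (ln in lines[meta_idx]) {
    m <- regmatches(ln, regexec("^#\\s*([A-Za-z_]+)\\s*=\\s*(.+?)\\s*$", ln))[[1L]]
    if (length(m) == 3L) meta[[m[2L]]] <- m[3L]
  }
  fs <- if (!is.null(meta$fs)) as.numeric(meta$fs) else fs_expected
  if (is.na(fs) || fs <= 0)
    fm_parse_error(sprintf("invalid fs declaration in %s", path))
  if (abs(fs - fs_expected) > 1e-9)
    fm_config_error(sprintf(
      "sampling rate mismatch: file declares %g Hz, expected %g Hz", fs,
      fs_expected))

  body_lines <- if (length(meta_idx)) lines[-meta_idx] else lines
  body_lines <- body_lines[nzchar(body_lines)]
  if (length(body_lines) < 2L)
    fm_parse_error(sprintf("no data rows in %s", path))
  header <- strsplit(body_lines[1L], ",", fixed = TRUE)[[1L]]
  if (!identical(trimws(header), c("timestamp", "ax", "ay", "az")))
    fm_parse_error(sprintf("unexpected header in %s: %s", path, body_lines[1L]))

  rows <- strsplit(body_lines[-1L], ",", fixed = TRUE)
  nf <- lengths(rows)
  if (any(nf != 4L))
    fm_parse_error(sprintf("malformed row at line %d of %s",
                           which(nf != 4L)[1L] + 1L, path))
  tab <- matrix(unlist(rows), ncol = 4L, byrow = TRUE)
  vals <- suppressWarnings(matrix(as.numeric(tab[, 2:4]), ncol = 3L))
  if (anyNA(vals)) {
    bad <- which(apply(is.na(vals), 1L, any))[1L]
    fm_parse_error(sprintf("malformed row at line %d of %s", bad + 1L, path))
  }
  t0 <- as.POSIXct(tab[1L, 1L], tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS"))
  if (is.na(t0))
    fm_parse_error(sprintf("unparseable first timestamp in %s: %s", path,
                           tab[1L, 1L]))
  accel_series(vals, fs = fs, t0 = t0,
               sensor_id = if (!is.null(meta$sensor_id)) meta$sensor_id
                           else basename(path),
               placement = if (!is.null(meta$placement)) meta$placement
                           else NA_character_)
}

#' Write an accelerometer series to CSV
#'
#' Values are printed with 12 significant digits so that
#' \code{read_accel_csv(write_accel_csv(x))} round-trips to printed
#' precision.
#'
#' @param series an \code{\link{accel_series}}.
#' @param path output file path; the directory must exist.
#' @return \code{path}, invisibly.
#' @export
write_accel_csv <- function(series, path) {
  stopifnot(inherits(series, "accel_series"))
  dir <- dirname(path)
  if (!dir.exists(dir)) fm_io_error(sprintf("directory does not exist: %s", dir))
  ts <- format(series$t0 + sample_times(series), "%Y-%m-%dT%H:%M:%OS3")
  rows <- sprintf("%s,%.12g,%.12g,%.12g", ts,
                  series$data[, 1L], series$data[, 2L], series$data[, 3L])
  hdr <- c(sprintf("# fs=%g", series$fs),
           sprintf("# sensor_id=%s", series$sensor_id),
           if (!is.na(series$placement))
             sprintf("# placement=%s", series$placement),
           "timestamp,ax,ay,az")
  ok <- tryCatch({ writeLines(c(hdr, rows), path); TRUE },
                 error = function(e) FALSE)
  if (!ok) fm_io_error(sprintf("cannot write %s", path))
  invisible(path)
}

#' Read an activity diary file
#'
#' One entry per line in the form \code{label,HH:MM:SS,HH:MM:SS}.  Labels
#' are normalised to lower case; unknown labels become \code{"other"} with a
#' warning; overlapping entries raise a validation error.
#'
#' @param path path to the diary file.
#' @param date calendar date the HH:MM:SS times refer to.
#' @return an \code{\link{activity_log}} sorted by start time.
#' @export
read_activity_log <- function(path, date = as.Date("1970-01-01")) {
  if (!file.exists(path)) fm_io_error(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) fm_parse_error(sprintf("no entries in %s", path))
  parts <- strsplit(lines, ",", fixed = TRUE)
  if (any(lengths(parts) != 3L))
    fm_parse_error(sprintf("malformed diary line %d in %s",
                           which(lengths(parts) != 3L)[1L], path))
  tab <- matrix(trimws(unlist(parts)), ncol = 3L, byrow = TRUE)
  parse_time <- function(hms) {
    t <- as.POSIXct(paste(date, hms), tz = "UTC",
                    tryFormats = "%Y-%m-%d %H:%M:%OS")
    if (anyNA(t)) fm_parse_error(sprintf("unparseable time in %s", path))
    t
  }
  activity_log(tab[, 1L], parse_time(tab[, 2L]), parse_time(tab[, 3L]))
}

#' Write an activity diary file
#' @param log an \code{\link{activity_log}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_activity_log <- function(log, path) {
  stopifnot(inherits(log, "activity_log"))
  writeLines(sprintf("%s,%s,%s", log$label,
                     format(log$start, "%H:%M:%S"),
                     format(log$end, "%H:%M:%S")), path)
  invisible(path)
}
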