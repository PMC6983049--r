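# Paired-stream simulator.  It emulates the statistical structure the
# analysis relies on -- gravity on the y-axis when upright, gravity moved to
# the z-axis when sitting, double-peak-per-stride gait oscillation, sudden
# variance rises at posture transitions, jump/tap synchronisation markers --
# and a clothing channel distorted by integer sample lag, a fixed rotation
# offset, additive fabric-swing oscillation, amplitude scaling and Gaussian
# noise.  It makes no attempt at biomechanical realism or cloth physics.

# Run code with a temporary RNG state seeded by `seed` (NULL = use current).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Configuration for the synthetic body-worn stream
#'
#' @param fs sampling rate in Hz (default 50, the study's device rate).
#' @param schedule data frame (or list of \code{c(label, seconds)} pairs)
#'   with columns \code{label} and \code{duration} in seconds.
#' @param stride_period named numeric: full stride (two steps) period in
#'   seconds per gait label.  Defaults 0.7 s walking, 0.3 s running.
#' @param walk_amp,run_amp peak oscillation amplitude in g superimposed on
#'   gravity during walking / running.
#' @param noise_sd standard deviation of additive Gaussian sensor noise in g.
#' @param seed integer RNG seed; NULL uses the current RNG state.
#' @param markers logical, inject the start jump + four taps and end jump.
#' @param transition_s posture transition ramp length in seconds.
#' @param t0 timestamp of the first sample.
#' @return list of class \code{synth_config}.
#' @export
synth_config <- function(fs = 50,
                         schedule = data.frame(
                           label = c("standing", "walking", "sitting",
                                     "running", "standing"),
                           duration = c(60, 60, 60, 60, 30)),
                         stride_period = c(walking = 0.7, running = 0.3),
                         walk_amp = 0.5, run_amp = 1.0,
                         noise_sd = 0.02, seed = NULL, markers = FALSE,
                         transition_s = 0.5,
                         t0 = as.POSIXct("1970-01-01 09:00:00", tz = "UTC")) {
  if (is.list(schedule) && !is.data.frame(schedule))
    schedule <- data.frame(
      label = vapply(schedule, function(e) as.character(e[[1L]]), ""),
      duration = vapply(schedule, function(e) as.numeric(e[[2L]]), 0))
  if (nrow(schedule) == 0L) fm_validation_error("schedule must be non-empty")
  schedule$label <- tolower(as.character(schedule$label))
  schedule$duration <- as.numeric(schedule$duration)
  if (any(schedule$duration <= 0))
    fm_validation_error("all schedule durations must be positive")
  if (!all(schedule$label %in% ACTIVITY_LABELS))
    fm_validation_error("schedule labels must be known activity labels")
  if (any(stride_period <= 2 / fs))
    fm_validation_error("stride_period must exceed two sample intervals")
  if (noise_sd < 0) fm_validation_error("noise_sd must be non-negative")
  structure(list(fs = fs, schedule = schedule, stride_period = stride_period,
                 walk_amp = walk_amp, run_amp = run_amp, noise_sd = noise_sd,
                 seed = seed, markers = markers, transition_s = transition_s,
                 t0 = as.POSIXct(t0, tz = "UTC")),
            class = "synth_config")
}

# Resting gravity direction (in g) for each activity label: upright postures
# keep gravity on +y; sitting rotates the thigh so y is perpendicular to
# gravity, which moves to +z.
posture_gravity <- function(label) {
  switch(label,
         sitting = , bus_ride = c(0, 0, 1),
         c(0, 1, 0))
}

#' Generate a synthetic body-worn stream and matching diary
#'
#' Static standing yields ay = 1 g; static sitting yields ay = 0, az = 1 g.
#' Gait segments superimpose on gravity a two-harmonic waveform with
#' fundamental period \code{stride_period/2} per step (two peaks per stride)
#' at amplitude \code{walk_amp}/\code{run_amp} on the y-axis and attenuated
#' copies on x and z.  Posture baselines ramp linearly over
#' \code{transition_s} at segment boundaries, producing the abrupt
#' moving-variance rise the classifier keys on.
#'
#' @param config a \code{\link{synth_config}}.
#' @return list with elements \code{series} (an \code{accel_series}) and
#'   \code{log} (an \code{activity_log} matching the schedule exactly).
#' @export
generate_body_stream <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  fs <- config$fs
  sched <- config$schedule
  n_seg <- pmax(1L, as.integer(round(sched$duration * fs)))
  n <- sum(n_seg)
  base <- matrix(0, n, 3L)
  osc <- matrix(0, n, 3L)
  offset <- 0L
  for (i in seq_len(nrow(sched))) {
    idx <- offset + seq_len(n_seg[i])
    lab <- sched$label[i]
    base[idx, ] <- matrix(posture_gravity(lab), n_seg[i], 3L, byrow = TRUE)
    if (lab %in% c("walking", "running")) {
      amp <- if (lab == "walking") config$walk_amp else config$run_amp
      stride <- config$stride_period[[lab]]
      f_step <- 2 / stride               # one peak per step, two per stride
      tt <- (seq_len(n_seg[i]) - 1L) / fs
      env <- pmin(1, tt / config$transition_s,
                  (n_seg[i] / fs - tt) / config$transition_s)
      env <- pmax(env, 0)
      w <- sin(2 * pi * f_step * tt) + 0.5 * sin(2 * pi * 2 * f_step * tt)
      osc[idx, 2L] <- amp * env * w
      osc[idx, 1L] <- 0.5 * amp * env * sin(2 * pi * f_step * tt + pi / 3)
      osc[idx, 3L] <- 0.3 * amp * env * sin(2 * pi * f_step * tt + 2 * pi / 3)
    } else if (lab == "bus_ride") {
      tt <- (seq_len(n_seg[i]) - 1L) / fs
      osc[idx, ] <- 0.05 * sin(2 * pi * 4 * tt) # low-amplitude vehicle hum
    }
    offset <- offset + n_seg[i]
  }
  # Boxcar smoothing of the posture baseline gives exact linear ramps of
  # length transition_s at each boundary and leaves static plateaus intact.
  w <- as.integer(round(config$transition_s * fs))
  if (w > 1L && n > w) {
    pad <- function(v) c(rep(v[1L], w), v, rep(v[length(v)], w))
    kern <- rep(1 / w, w)
    for (j in 1:3) {
      sm <- stats::filter(pad(base[, j]), kern, sides = 2)
      base[, j] <- sm[(w + 1L):(w + n)]
    }
  }
  data <- base + osc
  if (config$noise_sd > 0)
    data <- data + with_seed(config$seed,
      matrix(stats::rnorm(3L * n, 0, config$noise_sd), n, 3L))
  series <- accel_series(data, fs = fs, t0 = config$t0,
                         sensor_id = "synthetic-body",
                         placement = "thigh:body")
  ends <- config$t0 + cumsum(sched$duration)
  starts <- config$t0 + c(0, cumsum(sched$duration)[-nrow(sched)])
  log <- activity_log(sched$label, starts, ends)
  if (config$markers)
    series <- inject_markers(series, at_start = TRUE, at_end = TRUE, taps = 4L)
  list(series = series, log = log)
}

#' Clothing-channel distortion parameters
#'
#' @param lag_samples integer lag of the clothing channel relative to the
#'   body channel, in samples.  Positive = clothing lags the body; negative
#'   values (clothing leads) are accepted for symmetric simulations.
#' @param axis unit 3-vector rotation axis of the fixed orientation offset.
#' @param angle rotation offset in radians.
#' @param swing_amp amplitude in g of the additive fabric-swing oscillation,
#'   applied on the anterior-posterior (x) axis.
#' @param swing_freq swing frequency in Hz (garment pendulum motion is slow;
#'   default 1 Hz).
#' @param amp_scale multiplicative amplitude scaling (loose fabric whips, so
#'   values above 1 emulate the sharper clothing peaks).
#' @param noise_sd additive Gaussian noise in g on the clothing channel.
#' @return list of class \code{clothing_params}.
#' @export
clothing_params <- function(lag_samples = 0L, axis = c(1, 0, 0), angle = 0,
                            swing_amp = 0, swing_freq = 1, amp_scale = 1,
                            noise_sd = 0) {
  nrm <- sqrt(sum(axis^2))
  if (abs(nrm - 1) > 1e-8) {
    if (nrm < 1e-12) fm_validation_error("rotation axis must be non-zero")
    axis <- axis / nrm
  }
  if (amp_scale <= 0) fm_validation_error("amp_scale must be positive")
  if (swing_amp < 0 || noise_sd < 0)
    fm_validation_error("swing_amp and noise_sd must be non-negative")
  structure(list(lag_samples = as.integer(lag_samples), axis = axis,
                 angle = angle, swing_amp = swing_amp,
                 swing_freq = swing_freq, amp_scale = amp_scale,
                 noise_sd = noise_sd),
            class = "clothing_params")
}

#' Distort a body stream into a simulated clothing stream
#'
#' Applies, in order: integer sample delay (edge padded by repeating the
#' first sample), amplitude scaling, the fixed rotation offset, additive
#' fabric swing on the x-axis, and Gaussian noise.  With identity parameters
#' the output equals the input, and with zero swing and noise the transform
#' is exactly invertible away from the padded edge.
#'
#' @param body an \code{\link{accel_series}}.
#' @param params a \code{\link{clothing_params}}.
#' @param seed RNG seed for the noise draw (NULL = current RNG state).
#' @return an \code{accel_series} of the same length and sampling rate.
#' @export
apply_clothing_transform <- function(body, params, seed = NULL) {
  stopifnot(inherits(body, "accel_series"), inherits(params, "clothing_params"))
  n <- n_samples(body)
  if (abs(params$lag_samples) >= n)
    fm_validation_error("lag_samples must be smaller than the series length")
  out <- if (params$lag_samples != 0L) shift_series(body, params$lag_samples)
         else body
  d <- out$data * params$amp_scale
  if (abs(params$angle) > 0) {
    R <- rodrigues_matrix(params$axis, params$angle)
    d <- d %*% t(R)
  }
  if (params$swing_amp > 0) {
    tt <- sample_times(body)
    d[, 1L] <- d[, 1L] +
      params$swing_amp * sin(2 * pi * params$swing_freq * tt)
  }
  if (params$noise_sd > 0)
    d <- d + with_seed(seed,
      matrix(stats::rnorm(3L * n, 0, params$noise_sd), n, 3L))
  out <- set_data(out, d)
  out$sensor_id <- paste0(body$sensor_id, "-clothing")
  if (!is.na(body$placement))
    out$placement <- sub(":body$", ":clothing", body$placement)
  out
}

#' Inject jump and tap synchronisation markers
#'
#' The wear protocol starts each recording with a jump (a distinctive
#' high-magnitude spike), followed by four synchronous taps on each sensor
#' pair, and closes with another jump.  This injects the same morphology: a
#' biphasic jump spike (positive peak \code{jump_amp} >= 4 g) centred 0.5 s
#' in, \code{taps} short spikes 0.5 s apart starting 1.5 s in, and, when
#' \code{at_end}, a closing jump 0.5 s before the end written 10\% larger so
#' it is the global magnitude maximum.
#'
#' @param series an \code{\link{accel_series}}.
#' @param at_start,at_end logical, inject the opening / closing jump.
#' @param taps number of taps after the opening jump (protocol default 4).
#' @param jump_amp,tap_amp spike peak amplitudes in g.
#' @return the series with markers added on the y-axis.
#' @export
inject_markers <- function(series, at_start = TRUE, at_end = FALSE,
                           taps = 4L, jump_amp = 5, tap_amp = 3.5) {
  stopifnot(inherits(series, "accel_series"))
  fs <- series$fs
  n <- n_samples(series)
  taps <- as.integer(taps)
  extent <- if (at_start) (1.5 + 0.5 * taps + 0.5) else 0
  if (at_end) extent <- extent + 1
  if (n / fs < extent + 0.5)
    fm_validation_error("series too short for the requested markers")
  d <- series$data
  add_pulse <- function(center_s, amp, biphasic = FALSE) {
    half <- max(1L, as.integer(round(0.04 * fs)))      # ~40 ms rise
    c0 <- as.integer(round(center_s * fs)) + 1L
    off <- -half:half
    wts <- 1 - abs(off) / (half + 1L)
    idx <- c0 + off
    keep <- idx >= 1L & idx <= n
    d[idx[keep], 2L] <<- d[idx[keep], 2L] + amp * wts[keep]
    if (biphasic) {
      idx2 <- c0 + (half + 1L) + off
      keep2 <- idx2 >= 1L & idx2 <= n
      d[idx2[keep2], 2L] <<- d[idx2[keep2], 2L] - 0.6 * amp * wts[keep2]
    }
  }
  if (at_start) {
    add_pulse(0.5, jump_amp, biphasic = TRUE)
    if (taps > 0L)
      for (k in seq_len(taps)) add_pulse(1.0 + 0.5 * k, tap_amp)
  }
  if (at_end) add_pulse(n / fs - 0.5, 1.1 * jump_amp, biphasic = TRUE)
  set_data(series, d)
}

#' Generate a complete synthetic sensor pair with ground truth
#'
#' Convenience wrapper: generates the body stream, distorts it into the
#' clothing stream and returns the pair, the diary and a ground-truth list
#' (the sidecar written by the \code{synth} CLI subcommand) for validation.
#'
#' @param config a \code{\link{synth_config}}.
#' @param params a \code{\link{clothing_params}}.
#' @return list with \code{pair}, \code{log} and \code{truth}.
#' @export
generate_pair <- function(config, params = clothing_params()) {
  bs <- generate_body_stream(config)
  noise_seed <- if (!is.null(config$seed)) config$seed + 1L else NULL
  clothing <- apply_clothing_transform(bs$series, params, seed = noise_seed)
  if (config$markers) {
    # Markers are struck on both devices simultaneously in real protocol
    # time, i.e. at the same wall-clock instant *before* the clothing lag;
    # the transform above already delays them with the rest of the signal.
  }
  truth <- list(lag_samples = params$lag_samples,
                rotation_axis = params$axis,
                rotation_angle_rad = params$angle,
                swing_amp = params$swing_amp,
                amp_scale = params$amp_scale,
                schedule = config$schedule,
                fs = config$fs, seed = config$seed)
  list(pair = sensor_pair(bs$series, clothing), log = bs$log, truth = truth)
}
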