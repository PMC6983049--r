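# Shared fixtures.  Everything is generated in code; no stored data.

# Constant-orientation stream: every sample equals `vec` (in g).
static_series <- function(vec = c(0, 1, 0), seconds = 10, fs = 50,
                          noise_sd = 0, seed = NULL) {
  n <- as.integer(round(seconds * fs))
  d <- matrix(vec, n, 3L, byrow = TRUE)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    d <- d + matrix(rnorm(3L * n, 0, noise_sd), n, 3L)
  }
  accel_series(d, fs = fs)
}

# Walking-only pair with a known clothing distortion; noise-free default.
walking_pair <- function(lag = 0L, angle = 0, swing_amp = 0, amp_scale = 1,
                         noise_sd = 0, seconds = 40, seed = 11) {
  cfg <- synth_config(seed = seed, noise_sd = noise_sd,
                      schedule = data.frame(label = "walking",
                                            duration = seconds))
  generate_pair(cfg, clothing_params(lag_samples = lag, angle = angle,
                                     swing_amp = swing_amp,
                                     amp_scale = amp_scale,
                                     noise_sd = noise_sd))
}

# Independent brute-force oracle for the normalised cross-correlation lag:
# plain-sum Pearson formula per shift, scanning shifts in ascending order of
# |lag| so ties resolve toward synchrony, as the estimator documents.
bruteforce_lag <- function(x, y, max_lag) {
  n <- length(x)
  pearson_sum <- function(a, b) {
    m <- length(a)
    num <- m * sum(a * b) - sum(a) * sum(b)
    den <- sqrt((m * sum(a^2) - sum(a)^2) * (m * sum(b^2) - sum(b)^2))
    num / den
  }
  shifts <- 0:max_lag
  shifts <- c(0L, as.vector(rbind(shifts[-1L], -shifts[-1L])))
  best <- c(lag = 0L, r = -Inf)
  for (k in shifts) {
    if (k >= 0) { a <- x[1:(n - k)]; b <- y[(1 + k):n] }
    else { a <- x[(1 - k):n]; b <- y[1:(n + k)] }
    r <- pearson_sum(a, b)
    if (is.finite(r) && r > best[["r"]] + 1e-15)
      best <- c(lag = k, r = r)
  }
  best
}

# Independent brute-force oracle for the centred moving variance.
bruteforce_moving_variance <- function(x, w) {
  n <- length(x)
  half_lo <- (w - 1L) %/% 2L
  half_hi <- w - 1L - half_lo
  vapply(seq_len(n), function(i) {
    win <- x[max(1L, i - half_lo):min(n, i + half_hi)]
    stats::var(win)
  }, 0)
}

# Random unit 3-vector.
runit3 <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}
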