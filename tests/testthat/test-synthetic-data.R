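test_that("static postures produce the expected gravity placement", {
  stand <- generate_body_stream(synth_config(
    noise_sd = 0, schedule = data.frame(label = "standing", duration = 10)))
  expect_equal(unname(stand$series$data[, "ay"]), rep(1, 500))
  expect_equal(unname(stand$series$data[, "ax"]), rep(0, 500))
  expect_equal(unname(stand$series$data[, "az"]), rep(0, 500))

  sit <- generate_body_stream(synth_config(
    noise_sd = 0, schedule = data.frame(label = "sitting", duration = 10)))
  expect_equal(unname(sit$series$data[, "ay"]), rep(0, 500))
  expect_equal(unname(sit$series$data[, "az"]), rep(1, 500))

  # static noise-free magnitude is exactly 1 g
  expect_equal(magnitude(stand$series), rep(1, 500))
})

test_that("the diary matches the schedule exactly", {
  sched <- data.frame(label = c("standing", "walking", "sitting"),
                      duration = c(10, 20, 15))
  out <- generate_body_stream(synth_config(seed = 1, schedule = sched))
  expect_equal(out$log$label, sched$label)
  expect_equal(as.numeric(difftime(out$log$end, out$log$start, units = "secs")),
               sched$duration)
  expect_equal(n_samples(out$series), sum(sched$duration) * 50)
})

test_that("gait oscillation peaks at the step frequency (two peaks per stride)", {
  for (case in list(list(label = "walking", stride = 0.7),
                    list(label = "running", stride = 0.3))) {
    s <- generate_body_stream(synth_config(
      noise_sd = 0,
      schedule = data.frame(label = case$label, duration = 30)))$series
    y <- s$data[, "ay"] - mean(s$data[, "ay"])
    sp <- stats::spec.pgram(stats::ts(y, frequency = 50), plot = FALSE,
                            taper = 0, detrend = FALSE)
    f_peak <- sp$freq[which.max(sp$spec)]
    expect_equal(f_peak, 2 / case$stride, tolerance = 0.05)
  }
})

test_that("generation is reproducible under a fixed seed", {
  a <- generate_body_stream(synth_config(seed = 99))$series
  b <- generate_body_stream(synth_config(seed = 99))$series
  expect_identical(a$data, b$data)
  c <- generate_body_stream(synth_config(seed = 100))$series
  expect_false(identical(a$data, c$data))
})

test_that("identity clothing transform returns the input unchanged", {
  body <- walking_pair()$pair$body
  out <- apply_clothing_transform(body, clothing_params())
  expect_equal(out$data, body$data)
})

test_that("injected lag is recoverable by cross-correlation", {
  g <- walking_pair(lag = 38L, noise_sd = 0.02)
  est <- estimate_lag_xcorr(g$pair$body, g$pair$clothing, max_lag = 100)
  expect_identical(est$lag_samples, 38L)
})

test_that("a pure rotation moves a static gravity vector as the closed form says", {
  body <- static_series(c(0, 1, 0), seconds = 5)
  out <- apply_clothing_transform(body,
    clothing_params(angle = 30 * pi / 180, axis = c(1, 0, 0)))
  expect_equal(unname(out$data[1L, ]),
               c(0, cos(30 * pi / 180), sin(30 * pi / 180)),
               tolerance = 1e-12)
})

test_that("with no swing and no noise the clothing transform is invertible", {
  g <- walking_pair(lag = 25L, angle = 20 * pi / 180, amp_scale = 1.3)
  clothing <- g$pair$clothing
  rot <- rotation_spec(c(1, 0, 0), 20 * pi / 180)
  undone <- clothing$data %*% rot$matrix   # R^T applied rowwise
  undone <- undone / 1.3
  recovered <- shift_series(set_data(clothing, undone), -25L)
  n <- n_samples(recovered)
  keep <- 1:(n - 25L)                       # exclude the padded edge
  expect_equal(recovered$data[keep, ], g$pair$body$data[keep, ],
               tolerance = 1e-12)
})

test_that("negative lags (clothing leads) are accepted and recovered", {
  g <- walking_pair(lag = -17L, noise_sd = 0.02)
  est <- estimate_lag_xcorr(g$pair$body, g$pair$clothing, max_lag = 60)
  expect_identical(est$lag_samples, -17L)
})

test_that("markers inject the protocol's spike pattern", {
  s <- static_series(seconds = 60)
  m <- inject_markers(s, at_start = TRUE, at_end = FALSE, taps = 4L)
  mag <- magnitude(m)[1:(5 * 50)]
  k <- length(mag)
  peaks <- which(c(FALSE, mag[2:(k - 1)] > mag[1:(k - 2)] &
                          mag[2:(k - 1)] >= mag[3:k], FALSE) & mag > 3)
  expect_length(peaks, 5L)   # 1 jump + 4 taps in the first 5 s

  # taps = 0, no jumps: identity
  expect_equal(inject_markers(s, at_start = FALSE, at_end = FALSE,
                              taps = 0L)$data, s$data)

  m2 <- inject_markers(s, at_start = TRUE, at_end = TRUE, taps = 4L)
  i_max <- which.max(magnitude(m2))
  expect_gte(i_max, n_samples(m2) - 2 * 50)  # global max in the final 2 s

  expect_error(inject_markers(static_series(seconds = 2), taps = 4L),
               class = "fm_validation_error")
})

test_that("degenerate generator configs are rejected", {
  expect_error(synth_config(schedule = data.frame(label = character(),
                                                  duration = numeric())),
               class = "fm_validation_error")
  expect_error(synth_config(schedule = data.frame(label = "walking",
                                                  duration = -1)),
               class = "fm_validation_error")
  expect_error(synth_config(noise_sd = -0.1), class = "fm_validation_error")
  expect_error(clothing_params(amp_scale = 0), class = "fm_validation_error")
  body <- static_series(seconds = 1)
  expect_error(apply_clothing_transform(body, clothing_params(lag_samples = 50L)),
               class = "fm_validation_error")
})
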