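test_that("the 250 ms window at 50 Hz rounds half up to 13 samples", {
  # constant input: all zeros, and the truncated edges stay defined
  x <- rep(2, 100)
  mv <- moving_variance(x, 250, 50)
  expect_length(mv, 100L)
  expect_equal(mv, rep(0, 100))
  # window length is observable through the shortest valid input
  expect_silent(moving_variance(rep(1, 13), 250, 50))
  expect_error(moving_variance(rep(1, 12), 250, 50),
               class = "fm_validation_error")
})

test_that("moving variance equals the brute-force per-window oracle", {
  set.seed(77)
  for (n in c(50L, 500L, 2000L)) {
    x <- rnorm(n)
    w <- 13L
    expect_equal(moving_variance(x, 250, 50),
                 bruteforce_moving_variance(x, w), tolerance = 1e-10)
  }
  # even window width also matches its oracle
  x <- rnorm(300)
  expect_equal(moving_variance(x, 200, 50),
               bruteforce_moving_variance(x, 10L), tolerance = 1e-10)
})

test_that("static postures classify by y-axis level", {
  n <- 200L
  expect_equal(classify_samples(rep(1, n), rep(0, n)), rep("standing", n))
  expect_equal(classify_samples(rep(0, n), rep(0, n)), rep("sitting", n))
  # ambiguous static level falls into the transition band
  expect_equal(classify_samples(rep(0.6, n), rep(0, n)),
               rep("transition", n))
  # high variance dominates posture
  expect_equal(classify_samples(rep(1, n), rep(0.2, n)),
               rep("walking_running", n))
  expect_equal(classify_samples(rep(1, n), rep(0.01, n)),
               rep("transition", n))
})

test_that("a clean synthetic day is labelled to match its schedule", {
  sched <- data.frame(label = c("standing", "walking", "sitting", "standing"),
                      duration = c(30, 30, 30, 30))
  out <- generate_body_stream(synth_config(seed = 12, noise_sd = 0.01,
                                           schedule = sched))
  labels <- classify_series(out$series)
  fs <- 50
  truth <- rep(c("standing", "walking_running", "sitting", "standing"),
               sched$duration * fs)
  bounds <- cumsum(sched$duration * fs)
  near_boundary <- rep(FALSE, length(truth))
  for (b in bounds[-length(bounds)])
    near_boundary[max(1, b - 25):min(length(truth), b + 25)] <- TRUE
  interior <- !near_boundary
  expect_gte(mean(labels[interior] == truth[interior]), 0.95)
})

test_that("labels are invariant under co-scaling of signal and thresholds", {
  set.seed(9)
  y <- rnorm(500, 0.7, 0.4)
  mv <- moving_variance(y, 250, 50)
  base <- classify_samples(y, mv)
  th <- classifier_thresholds()
  for (alpha in c(0.5, 2, 9.81)) {
    th_s <- classifier_thresholds(y_sit_max = alpha * th$y_sit_max,
                                  y_stand_min = alpha * th$y_stand_min,
                                  var_trans_min = alpha^2 * th$var_trans_min,
                                  var_move_min = alpha^2 * th$var_move_min)
    expect_equal(classify_samples(alpha * y, alpha^2 * mv, th_s), base)
  }
})

test_that("threshold estimation returns defaults and a consistent quantile fit", {
  s <- generate_body_stream(synth_config(seed = 6, noise_sd = 0.02))$series
  y0 <- axis_signal(s, "y")
  mv0 <- moving_variance(y0, 250, s$fs)
  expect_equal(estimate_thresholds(y0, mv0, "fixed_default"),
               classifier_thresholds())

  # The 50th/90th-percentile heuristic assumes a wear day that is about
  # half static, about a tenth gait, and intermediate variance in between
  # (its documented assumption); build such a feature composition directly.
  set.seed(6)
  n <- 6000L
  y <- c(rnorm(n * 0.25, 1, 0.02),      # standing
         rnorm(n * 0.25, 0, 0.02),      # sitting
         rnorm(n * 0.40, 0.8, 0.1),     # vehicle vibration / fidgeting
         rnorm(n * 0.10, 1, 0.3))       # gait
  mv <- c(4e-4 * stats::rchisq(n * 0.25, 12) / 12,
          4e-4 * stats::rchisq(n * 0.25, 12) / 12,
          stats::runif(n * 0.40, 0.008, 0.03),
          stats::runif(n * 0.10, 0.08, 0.4))
  th_q <- estimate_thresholds(y, mv, "quantile")
  agree <- mean(classify_samples(y, mv, th_q) ==
                classify_samples(y, mv, classifier_thresholds()))
  expect_gte(agree, 0.90)

  # all-static input: no second posture mode, falls back with a warning
  st <- static_series(seconds = 70, noise_sd = 0.01, seed = 2)
  y2 <- axis_signal(st, "y")
  mv2 <- moving_variance(y2, 250, 50)
  expect_warning(th_f <- estimate_thresholds(y2, mv2, "quantile"))
  expect_equal(th_f, classifier_thresholds())
  expect_error(estimate_thresholds(y2[1:100], mv2[1:100], "quantile"),
               class = "fm_validation_error")
})

test_that("confusion matrices count, normalise and validate", {
  ref <- rep("walking_running", 10)
  test <- c(rep("walking_running", 9), "transition")
  cm <- confusion(ref, test)
  expect_equal(unname(cm$row_pct["walking_running", ]), c(90, 10, 0, 0))
  expect_equal(unname(cm$counts["walking_running", "walking_running"]), 9L)

  # perfect agreement: 100% diagonal
  labels <- rep(CLASS_LEVELS <- c("walking_running", "transition",
                                  "sitting", "standing"), 5)
  cm2 <- confusion(labels, labels)
  expect_equal(unname(diag(cm2$row_pct)), rep(100, 4))
  # every non-empty row sums to 100
  sums <- rowSums(cm2$row_pct)
  expect_equal(unname(sums), rep(100, 4))

  expect_error(confusion(c("walking_running", "flying"),
                         c("sitting", "sitting")),
               class = "fm_validation_error")
  expect_error(confusion(ref, test[1:5]), class = "fm_validation_error")
})
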