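make_walk_bouts_pair <- function(lag = 0L, angle = 0, noise_sd = 0,
                                 swing_amp = 0, amp_scale = 1, seed = 21) {
  cfg <- synth_config(seed = seed, noise_sd = noise_sd,
                      schedule = data.frame(
                        label = c("walking", "standing", "walking",
                                  "standing", "walking"),
                        duration = c(40, 5, 40, 5, 40)))
  generate_pair(cfg, clothing_params(lag_samples = lag, angle = angle,
                                     swing_amp = swing_amp,
                                     amp_scale = amp_scale,
                                     noise_sd = noise_sd))
}

test_that("segment extraction honours instance count and length bounds", {
  g <- make_walk_bouts_pair(noise_sd = 0.02)
  segs <- extract_segments(g$pair, g$log, "walking")
  expect_length(segs, 3L)
  for (s in segs) {
    expect_true(s$length >= 1500L && s$length <= 2000L)
    expect_equal(n_samples(s$body), n_samples(s$clothing))
  }
  one <- extract_segments(g$pair, g$log, "walking", n_instances = 1L)
  expect_length(one, 1L)

  # a bout shorter than the lower bound is excluded
  short <- generate_pair(synth_config(seed = 3, schedule = data.frame(
    label = c("walking", "standing"), duration = c(10, 60))))
  expect_warning(
    segs2 <- extract_segments(short$pair, short$log, "walking"),
    "no qualifying")
  expect_length(segs2, 0L)
})

test_that("pearson_r agrees with the direct product-moment formula", {
  expect_equal(pearson_r(1:4, 1:4), 1)
  expect_equal(pearson_r(c(1, 2, 3), c(3, 2, 1)), -1)
  a <- c(1, 2, 3, 4, 5); b <- c(2, 1, 4, 3, 6)
  oracle <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(pearson_r(a, b), oracle, tolerance = 1e-12)
  expect_error(pearson_r(rep(1, 5), 1:5),
               class = "fm_undefined_correlation_error")
  expect_error(pearson_r(1:2, 1:2), class = "fm_validation_error")
})

test_that("pearson_r is invariant to positive affine rescaling", {
  set.seed(55)
  a <- rnorm(200); b <- a + rnorm(200, 0, 0.5)
  r0 <- pearson_r(a, b)
  expect_equal(pearson_r(a, 3.7 * b + 11), r0, tolerance = 1e-14)
  expect_equal(pearson_r(a, 0.01 * b - 2), r0, tolerance = 1e-14)
})

test_that("normality check holds its error rates", {
  verdicts_norm <- vapply(1:100, function(s) {
    set.seed(s); normality_check(rnorm(500))$verdict
  }, "")
  expect_gte(mean(verdicts_norm == "normal"), 0.95)

  verdicts_exp <- vapply(1:100, function(s) {
    set.seed(s); normality_check(rexp(500))$verdict
  }, "")
  expect_gte(mean(verdicts_exp == "non-normal"), 0.99)

  expect_warning(v <- normality_check(rep(1, 50)), "degenerate")
  expect_equal(v$verdict, "non-normal")
})

test_that("the variant ladder behaves on a pure-lag pair", {
  g <- make_walk_bouts_pair(lag = 38L)
  res <- compare_variants(g$pair, g$log, "walking")
  y <- res[res$axis == "y", ]
  r_of <- function(v) y$r[y$variant == v]
  # exact alignment removes all mismatch on a zero-noise pure-lag pair
  expect_true(all(r_of("time_aligned") > 1 - 1e-9))
  expect_true(all(r_of("original") < 1 - 1e-4))
})

test_that("all five variants coincide under an identity clothing transform", {
  g <- make_walk_bouts_pair()
  res <- compare_variants(g$pair, g$log, "walking", n_instances = 1L)
  for (ax in c("x", "y", "z")) {
    r <- res$r[res$axis == ax]
    expect_lt(max(r) - min(r), 1e-9)
  }
})

test_that("full correction dominates every other variant on the y-axis", {
  g <- make_walk_bouts_pair(lag = 38L, angle = 20 * pi / 180,
                            amp_scale = 1.2)
  res <- compare_variants(g$pair, g$log, "walking")
  agg <- aggregate_instances(res)
  y <- agg[agg$axis == "y", ]
  r_full <- y$median_r[y$variant == "aligned_rotated_activitywise"]
  expect_true(all(r_full + 1e-9 >= y$median_r))
  expect_gt(r_full, 0.9999)
})

test_that("instance aggregation computes median and population variance", {
  res <- data.frame(activity = "walking", instance = 1:3,
                    variant = "original", axis = "y",
                    r = c(0.9, 0.95, 1.0), n = 1500L)
  agg <- aggregate_instances(res)
  expect_equal(agg$median_r, 0.95)
  expect_equal(agg$var_r, 0.001666667, tolerance = 1e-6)
  expect_equal(agg$n_instances, 3L)

  # single instance: median only
  agg1 <- aggregate_instances(res[1L, ])
  expect_equal(agg1$median_r, 0.9)
  expect_true(is.na(agg1$var_r))

  # equal instances: zero variance
  res$r <- 0.8
  expect_equal(aggregate_instances(res)$var_r, 0)

  # sample variance available on request
  res$r <- c(0.9, 0.95, 1.0)
  expect_equal(aggregate_instances(res, var_type = "sample")$var_r,
               stats::var(res$r))
})

test_that("garment swing growing with impact degrades running more than walking", {
  # fabric whip is superlinear in impact, so the running channel carries
  # disproportionately more swing than the walking channel
  walk <- generate_pair(
    synth_config(seed = 31, noise_sd = 0.02,
                 schedule = data.frame(label = "walking", duration = 40)),
    clothing_params(swing_amp = 0.2 * 0.5, noise_sd = 0.02))
  run <- generate_pair(
    synth_config(seed = 31, noise_sd = 0.02,
                 schedule = data.frame(label = "running", duration = 40)),
    clothing_params(swing_amp = 0.5 * 1.0, swing_freq = 1.5,
                    noise_sd = 0.02))
  r_walk <- compare_variants(walk$pair, walk$log, "walking")
  r_run <- compare_variants(run$pair, run$log, "running")
  med <- function(res) stats::median(
    res$r[res$axis == "x" & res$variant == "aligned_rotated_activitywise"])
  expect_gt(med(r_walk), med(r_run))
})
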