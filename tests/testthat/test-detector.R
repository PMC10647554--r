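test_that("binarize uses a strict above-threshold rule and scale equivariance", {
  sig <- activity_signal(c(0.01, 0.06, 0.05), fs = 100)
  expect_equal(binarize(sig, 0.05)$label, c(0L, 1L, 0L))
  zero <- activity_signal(rep(0, 50), fs = 100)
  expect_equal(binarize(zero, 0.05)$label, rep(0L, 50))
  set.seed(2)
  x <- abs(rnorm(500, 0, 0.1))
  expect_equal(binarize(activity_signal(x, 100), 0.05)$label,
               binarize(activity_signal(2 * x, 100), 0.10)$label)
  expect_error(binarize(sig, 0), class = "gaitbouts_error_parameter")
})

test_that("find_gaps extracts maximal zero runs with boundary flags", {
  g1 <- find_gaps(label_series(c(1, 1, 0, 0, 0, 1), 100))
  expect_equal(g1$start_frame, 2L)
  expect_equal(g1$end_frame, 5L)
  expect_false(g1$boundary)
  expect_equal(nrow(find_gaps(label_series(rep(1, 10), 100))), 0L)
  g3 <- find_gaps(label_series(rep(0, 10), 100))
  expect_equal(g3$start_frame, 0L)
  expect_equal(g3$end_frame, 10L)
  expect_true(g3$boundary)
})

test_that("gap retention flips exactly at the minimum gap count", {
  fs <- 100
  n <- 860L
  lab <- c(rep(1L, 400), rep(0L, 60), rep(1L, 400))
  gaps <- find_gaps(label_series(lab, fs))
  for (k in c(30L, 55L)) {
    # craft a likelihood with exactly k low samples inside the gap
    lik <- rep(1, n)
    lik[401:(400 + k)] <- 0.1
    likelihood <- activity_signal(lik, fs)
    at_k <- filter_gaps(gaps, likelihood,
                        detector_config(min_gap_frames = k))
    above_k <- filter_gaps(gaps, likelihood,
                           detector_config(min_gap_frames = k + 1L))
    expect_equal(nrow(at_k), 2L)     # count == min_gap: gap retained, split
    expect_equal(nrow(above_k), 1L)  # count < min_gap: absorbed, merged
    expect_equal(above_k$start_frame, 0L)
    expect_equal(above_k$end_frame, n)
  }
})

test_that("gap filtering follows the smoothed likelihood of a real binary signal", {
  fs <- 100
  lab <- c(rep(1L, 400), rep(0L, 60), rep(1L, 400))
  kernel <- default_kernel(fs)
  lik <- gaussian_smooth(activity_signal(lab, fs), kernel)
  count <- sum(lik$value[401:460] < 0.2)
  gaps <- find_gaps(label_series(lab, fs))
  merged <- filter_gaps(gaps, lik, detector_config(min_gap_frames = count + 1L))
  split <- filter_gaps(gaps, lik, detector_config(min_gap_frames = max(1L, count)))
  expect_equal(nrow(merged), 1L)
  if (count >= 1L) expect_equal(nrow(split), 2L)
  # long cold gap always retained; warm gap always absorbed
  cold <- activity_signal(c(rep(1, 400), rep(0, 300), rep(1, 400)), fs)
  gaps2 <- find_gaps(binarize(cold, 0.5))
  expect_equal(nrow(filter_gaps(gaps2, activity_signal(c(rep(1, 400), rep(0, 300), rep(1, 400)), fs),
                                detector_config())), 2L)
  warm <- c(rep(1L, 400), rep(0L, 30), rep(1L, 400))
  expect_equal(nrow(filter_gaps(find_gaps(label_series(warm, fs)),
                                activity_signal(rep(0.9, 830), fs),
                                detector_config())), 1L)
  expect_error(filter_gaps(gaps2, activity_signal(rep(1.5, 1100), fs),
                           detector_config()),
               class = "gaitbouts_error_contract")
})

test_that("transition rejection flips exactly at the heuristic fraction", {
  fs <- 100
  cfg <- detector_config()
  mk <- function(n_above, n) {
    sm <- activity_signal(c(rep(0.5, n_above), rep(0.1, n - n_above)), fs)
    bouts <- gaitbouts:::new_bout_set(0L, n, "activity", n = n, fs = fs)
    reject_transitions(bouts, sm, cfg)$kind
  }
  expect_equal(mk(0L, 200L), "walking")
  expect_equal(mk(10L, 100L), "rejected_transition")   # 10% >= 2.5%
  expect_equal(mk(25L, 1000L), "rejected_transition")  # exactly 2.5%: rejected
  expect_equal(mk(24L, 1000L), "walking")              # 2.4% < 2.5%: kept
})

test_that("minimum duration rejection flips exactly at 2 s", {
  fs <- 100
  cfg <- detector_config()
  mk <- function(frames) {
    bouts <- gaitbouts:::new_bout_set(0L, frames, "walking",
                                      n = frames, fs = fs)
    enforce_min_duration(bouts, cfg)$kind
  }
  expect_equal(mk(150L), "rejected_short")
  expect_equal(mk(199L), "rejected_short")
  expect_equal(mk(200L), "walking")
  empty <- gaitbouts:::new_bout_set(integer(0), integer(0), character(0),
                                    n = 100L, fs = fs)
  expect_equal(nrow(enforce_min_duration(empty, cfg)), 0L)
})

test_that("a stationary trace yields no walking bouts", {
  spec <- scenario_spec(list(list(kind = "stationary", duration_s = 300)),
                        noise_sigma_g = 0.005, seed = 8)
  fit <- detect_walking(build_scenario(spec)$trace)
  expect_equal(glance(fit)$n_walking_bouts, 0L)
  expect_equal(sum(fit$labels$label), 0L)
})

test_that("an isolated walking burst is recovered with sub-half-second boundaries", {
  sim <- build_scenario(burst_scenario(seed = 3))
  fit <- detect_walking(sim$trace)
  walking <- fit$bouts[fit$bouts$kind == "walking", ]
  expect_equal(nrow(walking), 1L)
  expect_lt(abs(walking$start_frame - 6000) / 100, 0.5)
  expect_lt(abs(walking$end_frame - 9000) / 100, 0.5)
})

test_that("detection is invariant to fixed sensor orientation", {
  sim <- build_scenario(burst_scenario(seed = 3))
  base <- detect_walking(sim$trace)
  withr::with_seed(31, {
    for (i in 1:3) {
      rot <- random_rotation()
      fit <- detect_walking(rotate_trace(sim$trace, rot))
      expect_same_bouts(base$bouts, fit$bouts)
    }
  })
})

test_that("raising the activity threshold never increases labelled walking time", {
  sim <- build_scenario(corridor_protocol(seed = 13))
  walking_s <- vapply(c(0.03, 0.05, 0.08, 0.12, 0.2), function(thr) {
    fit <- detect_walking(sim$trace, detector_config(activity_threshold_g = thr))
    glance(fit)$walking_seconds
  }, numeric(1))
  expect_true(all(diff(walking_s) <= 1e-9))
})

test_that("every walking bout lies inside exactly one activity bout", {
  sim <- build_scenario(corridor_protocol(seed = 17))
  cfg <- detector_config()
  fs <- trace_fs(sim$trace)
  kernel <- gaitbouts:::default_kernel(fs)
  mag <- magnitude3d(detrend(sim$trace))
  binary <- binarize(mag, cfg$activity_threshold_g)
  lik <- gaussian_smooth(activity_signal(binary$label, fs), kernel)
  activity <- filter_gaps(find_gaps(binary), lik, cfg)
  fit <- detect_walking(sim$trace, cfg)
  walking <- fit$bouts[fit$bouts$kind == "walking", ]
  for (i in seq_len(nrow(walking))) {
    containing <- sum(activity$start_frame <= walking$start_frame[i] &
                        activity$end_frame >= walking$end_frame[i])
    expect_equal(containing, 1L)
  }
})

test_that("label series and bout sets round trip losslessly", {
  withr::with_seed(23, {
    for (i in 1:5) {
      lab <- label_series(sample(0:1, 300, replace = TRUE, prob = c(0.7, 0.3)),
                          fs = 100)
      bouts <- labels_to_bouts(lab)
      expect_equal(bouts_to_labels(bouts)$label, lab$label)
    }
  })
})

test_that("the detector is deterministic", {
  sim <- build_scenario(corridor_protocol(seed = 19))
  f1 <- detect_walking(sim$trace)
  f2 <- detect_walking(sim$trace)
  expect_identical(f1$bouts, f2$bouts)
  expect_identical(f1$labels$label, f2$labels$label)
})

test_that("frame-count parameters rescale away from 100 Hz", {
  sim50 <- build_scenario(scenario_spec(list(
    list(kind = "stationary", duration_s = 60),
    list(kind = "walk", duration_s = 30, step_hz = 2, amp_g = 0.15),
    list(kind = "stationary", duration_s = 60)
  ), fs = 50, noise_sigma_g = 0.005, seed = 3))
  fit <- detect_walking(sim50$trace)
  walking <- fit$bouts[fit$bouts$kind == "walking", ]
  expect_equal(nrow(walking), 1L)
  expect_lt(abs(walking$start_frame / 50 - 60), 0.5)
  expect_lt(abs(walking$end_frame / 50 - 90), 0.5)
  expect_equal(gaitbouts:::scale_frames(50L, 50), 25L)
  expect_equal(gaitbouts:::scale_frames(50L, 200), 100L)
})

test_that("stage failures carry their stage name", {
  short <- accel_trace(rnorm(30), rnorm(30), rnorm(30), fs = 100)
  expect_error(detect_walking(short), "\\[detrend\\]")
})

test_that("tidy and glance expose the bout table and summary", {
  sim <- build_scenario(corridor_protocol(seed = 7))
  fit <- detect_walking(sim$trace)
  td <- tidy(fit)
  expect_true(all(c("start_frame", "end_frame", "kind", "start_s",
                    "duration_s") %in% names(td)))
  expect_equal(td$duration_s, (td$end_frame - td$start_frame) / 100)
  g <- glance(fit)
  expect_equal(g$n_walking_bouts, sum(td$kind == "walking"))
  expect_gt(g$walking_seconds, 0)
  expect_s3_class(autoplot(fit), "ggplot")
})
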