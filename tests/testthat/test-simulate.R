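test_that("scenario generation is reproducible and seed-sensitive", {
  spec <- corridor_protocol(seed = 4)
  a <- build_scenario(spec)
  b <- build_scenario(spec)
  expect_identical(a$trace$ax, b$trace$ax)
  expect_identical(a$truth$label, b$truth$label)
  expect_identical(a$segments, b$segments)
  other <- build_scenario(corridor_protocol(seed = 5))
  expect_false(identical(a$trace$ax, other$trace$ax))
  expect_identical(a$segments, other$segments)
})

test_that("generation leaves the global RNG untouched", {
  set.seed(123); before <- .Random.seed
  invisible(build_scenario(corridor_protocol(seed = 4)))
  expect_identical(before, .Random.seed)
})

test_that("truth labels mark walk segments exactly and segments tile the trace", {
  sim <- build_scenario(corridor_protocol(seed = 4))
  segs <- sim$segments
  expect_equal(segs$start_frame[1], 0L)
  expect_equal(segs$end_frame[nrow(segs)], nrow(sim$trace))
  expect_equal(segs$start_frame[-1], segs$end_frame[-nrow(segs)])
  expected <- integer(nrow(sim$trace))
  for (i in which(segs$kind == "walk")) {
    expected[(segs$start_frame[i] + 1):segs$end_frame[i]] <- 1L
  }
  expect_identical(sim$truth$label, expected)
  expect_equal(sum(segs$kind == "walk"), 2L)
})

test_that("stationary segments carry gravity plus chi-distributed magnitude", {
  withr::with_seed(10, {
    quiet <- gen_stationary(60, fs = 100, noise_sigma_g = 0,
                            gravity_dir = c(1, 2, 2))
    expect_equal(sqrt(quiet$ax^2 + quiet$ay^2 + quiet$az^2),
                 rep(1, 6000), tolerance = 1e-12)
    noisy <- gen_stationary(600, fs = 100, noise_sigma_g = 0.01)
    tr <- accel_trace(noisy$ax, noisy$ay, noisy$az, fs = 100)
    med <- median(magnitude3d(detrend(tr))$value)
    expect_equal(med, chi3_median(0.01), tolerance = 0.05)
  })
})

test_that("walking bursts are detected iff their amplitude clears the threshold", {
  strong <- build_scenario(burst_scenario(seed = 3, amp_g = 0.15, step_hz = 2))
  expect_equal(glance(detect_walking(strong$trace))$n_walking_bouts, 1L)
  weak <- build_scenario(burst_scenario(seed = 3, amp_g = 0.02,
                                        noise_sigma_g = 0.003))
  expect_equal(glance(detect_walking(weak$trace))$n_walking_bouts, 0L)
  slow <- build_scenario(burst_scenario(seed = 6, amp_g = 0.12, step_hz = 0.9,
                                        walk_s = 40))
  expect_equal(glance(detect_walking(slow$trace))$n_walking_bouts, 1L)
})

test_that("a full stop splits a walking bout in two", {
  spec <- scenario_spec(list(
    list(kind = "stationary", duration_s = 60),
    list(kind = "walk", duration_s = 40, step_hz = 1.8, amp_g = 0.15,
         pauses = list(c(18, 3))),
    list(kind = "stationary", duration_s = 60)
  ), noise_sigma_g = 0.005, seed = 15)
  sim <- build_scenario(spec)
  fit <- detect_walking(sim$trace)
  expect_equal(glance(fit)$n_walking_bouts, 2L)
})

test_that("sit-stand pulses form bouts that the heuristic rejects", {
  spec <- scenario_spec(list(
    list(kind = "stationary", duration_s = 60),
    list(kind = "transition", duration_s = 1.5, peak_g = 0.8),
    list(kind = "stationary", duration_s = 60)
  ), noise_sigma_g = 0.005, seed = 16)
  fit <- detect_walking(build_scenario(spec)$trace)
  expect_equal(glance(fit)$n_walking_bouts, 0L)
  expect_gte(glance(fit)$n_rejected_transition, 1L)
  # a gentle 0.25 g pulse clears the heuristic but dies on duration
  spec2 <- scenario_spec(list(
    list(kind = "stationary", duration_s = 60),
    list(kind = "transition", duration_s = 1.0, peak_g = 0.25),
    list(kind = "stationary", duration_s = 60)
  ), noise_sigma_g = 0.005, seed = 16)
  fit2 <- detect_walking(build_scenario(spec2)$trace)
  expect_equal(glance(fit2)$n_walking_bouts, 0L)
  expect_gte(glance(fit2)$n_rejected_short, 1L)
  # zero amplitude: nothing happens at all
  spec3 <- scenario_spec(list(
    list(kind = "stationary", duration_s = 60),
    list(kind = "transition", duration_s = 1.5, peak_g = 0),
    list(kind = "stationary", duration_s = 60)
  ), noise_sigma_g = 0, seed = 16)
  fit3 <- detect_walking(build_scenario(spec3)$trace)
  expect_equal(nrow(fit3$bouts), 0L)
})

test_that("a mounted orientation changes the axes but not the detection", {
  withr::with_seed(52, rot <- random_rotation())
  plain <- build_scenario(burst_scenario(seed = 9))
  tilted <- build_scenario(burst_scenario(seed = 9, orientation = rot))
  expect_false(isTRUE(all.equal(plain$trace$ax, tilted$trace$ax)))
  expect_same_bouts(detect_walking(plain$trace)$bouts,
                    detect_walking(tilted$trace)$bouts)
})

test_that("scenario specs are validated", {
  expect_error(scenario_spec(list(list(kind = "jog", duration_s = 5))),
               class = "gaitbouts_error_parameter")
  expect_error(scenario_spec(list(list(kind = "walk", duration_s = -1))),
               class = "gaitbouts_error_parameter")
  expect_error(scenario_spec(list(list(kind = "walk", duration_s = 5)),
                             orientation = matrix(1, 3, 3)),
               class = "gaitbouts_error_parameter")
  expect_error(gen_walk(10, step_hz = 5), class = "gaitbouts_error_parameter")
  expect_s3_class(autoplot(build_scenario(burst_scenario(seed = 1,
                                                         walk_s = 5,
                                                         flank_s = 5))),
                  "ggplot")
})

test_that("the synthetic cohort reproduces its parameters deterministically", {
  c1 <- synthetic_cohort(n_participants = 3, seed = 99, calibration_hours = 0.1)
  c2 <- synthetic_cohort(n_participants = 3, seed = 99, calibration_hours = 0.1)
  expect_identical(c1$step_hz, c2$step_hz)
  expect_identical(c1$day_sigma_g, c2$day_sigma_g)
  expect_true(all(c1$step_hz >= 0.8 & c1$step_hz <= 2.2))
  expect_true(all(c1$transition_peak_g >= 0.6 & c1$transition_peak_g <= 1.0))
})
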