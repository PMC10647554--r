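# Programmatic fixtures; everything is generated at test time.

burst_scenario <- function(seed = 3, amp_g = 0.15, step_hz = 2,
                           walk_s = 30, flank_s = 60,
                           noise_sigma_g = 0.005, orientation = diag(3)) {
  scenario_spec(list(
    list(kind = "stationary", duration_s = flank_s),
    list(kind = "walk", duration_s = walk_s, step_hz = step_hz, amp_g = amp_g),
    list(kind = "stationary", duration_s = flank_s)
  ), noise_sigma_g = noise_sigma_g, orientation = orientation, seed = seed)
}

# a random short scenario (<= 100 s at 100 Hz, i.e. <= 1e4 samples)
random_scenario <- function(seed) {
  withr::with_seed(seed, {
    k <- sample(3:6, 1)
    segs <- lapply(seq_len(k), function(i) {
      kind <- sample(c("stationary", "walk", "transition"), 1,
                     prob = c(0.4, 0.4, 0.2))
      dur <- runif(1, 4, 100 / k - 1)
      switch(kind,
        stationary = list(kind = "stationary", duration_s = dur),
        walk = list(kind = "walk", duration_s = dur,
                    step_hz = runif(1, 0.6, 2.8),
                    amp_g = runif(1, 0.04, 0.3)),
        transition = list(kind = "transition",
                          duration_s = runif(1, 1, 3),
                          peak_g = runif(1, 0.2, 1.0)))
    })
    scenario_spec(segs, noise_sigma_g = runif(1, 0.003, 0.012),
                  orientation = random_rotation(), seed = seed + 7L)
  })
}

# one shared cohort evaluation for the acceptance checks (memoized: the two
# ordering/level checks read the same study run)
.cohort_cache <- new.env(parent = emptyenv())
cached_cohort_results <- function() {
  if (is.null(.cohort_cache$res)) {
    .cohort_cache$res <- evaluate_cohort(
      synthetic_cohort(n_participants = 10, seed = 424,
                       calibration_hours = 2))
  }
  .cohort_cache$res
}

expect_same_bouts <- function(a, b) {
  expect_equal(nrow(a), nrow(b))
  expect_equal(as.integer(a$start_frame), as.integer(b$start_frame))
  expect_equal(as.integer(a$end_frame), as.integer(b$end_frame))
  expect_equal(as.character(a$kind), as.character(b$kind))
}
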