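# Synthetic-data generator: hypnogram dynamics, stimulation schedule,
# signal rendering and ground-truth bookkeeping.

test_that("sim_config validates its invariants", {
  expect_error(sim_config(sampling_rate = 500), "multiple of 40")
  expect_error(sim_config(night_duration = 90), "at least 120")
  expect_error(sim_config(night_duration = 145), "multiple of 30")
  expect_error(sim_config(duty_cycle = 1), "duty_cycle")
  expect_error(sim_config(stage_ssvep_amplitude = c(W = -1, N2 = 0, N3 = 0,
                                                    REM = 0)),
               "non-negative")
  expect_s3_class(sim_config(), "sim_config")
})

test_that("an absorbing transition matrix keeps the chain in its start state", {
  cfg <- quick_cfg(duration = 600, stage_transitions = identity_transitions(),
                   start_stage = "W", require_n3 = FALSE)
  hyp <- generate_hypnogram(cfg)
  expect_equal(unique(hyp$stages), "W")
  expect_length(hyp$stages, 20)
})

test_that("hypnogram generation is deterministic under a fixed seed", {
  cfg <- quick_cfg(duration = 28800, fs = 200, seed = 11)
  h1 <- generate_hypnogram(cfg)
  h2 <- generate_hypnogram(cfg)
  expect_identical(h1$stages, h2$stages)
  expect_identical(h1$certainty, h2$certainty)
})

test_that("default full nights track a healthy sleeper's stage profile", {
  # %N2 of total sleep time should land near 53% on average
  pct_n2 <- vapply(1:50, function(s) {
    hyp <- generate_hypnogram(sim_config(sampling_rate = 200,
                                         rng_seed = 1000 + s))
    sleep <- hyp$stages != "W"
    100 * sum(hyp$stages == "N2") / sum(sleep)
  }, 0)
  expect_gt(mean(pct_n2), 43)
  expect_lt(mean(pct_n2), 63)
  # every generated night contains N3, so the stimulation trigger can fire
  expect_true(all(vapply(1:50, function(s)
    any(generate_hypnogram(quick_cfg(duration = 28800, fs = 200,
                                     seed = s))$stages == "N3"), NA)))
})

test_that("hypnogram certainty lies in [0, 1] and nights below 120 s are rejected", {
  hyp <- generate_hypnogram(quick_cfg(duration = 1800, seed = 3))
  expect_true(all(hyp$certainty >= 0 & hyp$certainty <= 1))
  expect_error(quick_cfg(duration = 60), "at least 120")
})

test_that("stimulation starts at the first N3 with a complete 300 s ramp", {
  cfg <- quick_cfg(duration = 600, fs = 200)
  hyp <- hypnogram(rep("N3", 20))
  sl <- build_stim_schedule(hyp, cfg)
  expect_equal(nrow(sl$intervals), 1)
  expect_equal(sl$intervals$start, 1L)
  expect_equal(sl$intervals$visible, 1L)
  ill <- stim_illuminance(sl)
  fs <- cfg$sampling_rate
  # raised-cosine ramp: half illuminance at the midpoint, full at 300 s
  expect_equal(ill[150 * fs + 1], 0.5, tolerance = 1e-6)
  expect_equal(ill[300 * fs + 1], 1)
  expect_true(all(ill[(300 * fs + 1):length(ill)] == 1))
})

test_that("arousal triggers a fade-out and six calm epochs gate the restart", {
  cfg <- quick_cfg(duration = 29 * 30, fs = 200)
  hyp <- hypnogram(c(rep("N3", 12), "W", rep("N2", 6), rep("N3", 10)))
  sl <- build_stim_schedule(hyp, cfg)
  fs <- cfg$sampling_rate
  es <- 30 * fs
  expect_equal(nrow(sl$intervals), 2)
  # fade-out begins at the W epoch (epoch index 12) and lasts 5 s
  expect_equal(sl$intervals$end[1], 12 * es + 5 * fs + 1)
  ill <- stim_illuminance(sl)
  expect_gt(ill[12 * es + 1], 0)                  # fading, not yet dark
  expect_equal(ill[12 * es + 5 * fs + 1], 0)      # dark after the fade tail
  # six consecutive non-W/N1 epochs (13..18) -> restart at epoch 19
  expect_equal(sl$intervals$start[2], 19 * es + 1)
})

test_that("a night without N3 leaves the schedule off but flagged", {
  cfg <- quick_cfg(duration = 300, fs = 200, require_n3 = FALSE,
                   stage_transitions = identity_transitions(),
                   start_stage = "N2")
  hyp <- generate_hypnogram(cfg)
  sl <- build_stim_schedule(hyp, cfg)
  expect_true(sl$no_n3)
  expect_equal(nrow(sl$intervals), 0)
  expect_true(all(stim_illuminance(sl) == 0))
})

test_that("illuminance is zero throughout W/N1 epochs once the fade tail passed", {
  cfg <- quick_cfg(duration = 3600, fs = 200, seed = 21)
  hyp <- generate_hypnogram(cfg)
  sl <- build_stim_schedule(hyp, cfg)
  ill <- stim_illuminance(sl)
  fs <- cfg$sampling_rate; es <- 30 * fs
  awake <- which(hyp$stages %in% c("W", "N1"))
  for (i in awake) {
    tail_start <- (i - 1) * es + 5 * fs + 1   # skip the 5 s fade tail
    expect_true(all(ill[tail_start:(i * es)] == 0))
  }
})

test_that("control schedules run the masked LED clock all night", {
  cfg <- quick_cfg(duration = 600, fs = 200, condition = "control")
  hyp <- generate_hypnogram(cfg)
  sl <- build_stim_schedule(hyp, cfg)
  expect_equal(sl$intervals$visible, 0L)
  expect_true(all(stim_illuminance(sl) == 0))
  edges <- led_edges(sl, "on", "active")
  expect_equal(length(edges), 600 * 40)     # 40 ON edges per second
  expect_equal(unique(diff(edges)), sl$period)
})

test_that("noiseless rendering injects an exactly periodic evoked response", {
  A <- 0.5
  cfg <- noiseless_cfg(duration = 300, fs = 1000,
                       stage_ssvep_amplitude = c(W = A, N2 = 0.08,
                                                 N3 = 0.07, REM = 0.09))
  night <- render_night(cfg, hyp = hypnogram(rep("W", 10)))
  x <- night$recording$samples["Oz", ]
  P <- 25  # samples per cycle at 1000 Hz
  expect_equal(max(x) - min(x), A, tolerance = 1e-9)
  expect_equal(x[1:(length(x) - P)], x[(P + 1):length(x)],
               tolerance = 1e-8)
  # mastoids, EOG carry no evoked response
  expect_true(all(night$recording$samples["A1", ] == 0))
})

test_that("the stimulus-locked average of a control night is the LED artifact template", {
  cfg <- noiseless_cfg(duration = 300, fs = 1000, condition = "control",
                       protocol = "sleep", led_artifact_amplitude = 0.8)
  night <- render_night(cfg, hyp = hypnogram(rep("N2", 10)))
  x <- night$recording$samples["Oz", ]   # unit artifact coupling gain
  edges_on <- led_edges(night$stim_log, "on", "active")
  edges_on <- edges_on[edges_on + 24 <= length(x)]
  # oracle: direct summation over segments
  avg <- rowMeans(vapply(edges_on, function(e) x[e:(e + 24)], numeric(25)))
  ss <- segment_at_led_on(x, night$stim_log)
  expect_equal(colMeans(ss$segments), avg, tolerance = 1e-12)
  # biphasic template at the ON edge (samples 1:2) and OFF edge (13:14)
  expect_equal(avg[1:2], c(0.8, -0.8), tolerance = 1e-9)
  expect_equal(avg[13:14], c(0.8, -0.8), tolerance = 1e-9)
  expect_gt(max(avg) - min(avg), 1)  # decidedly non-flat
})

test_that("rendering is bit-identical under a fixed seed", {
  cfg <- quick_cfg(duration = 300, fs = 200, seed = 5,
                   led_artifact_amplitude = 0.3)
  n1 <- render_night(cfg)
  n2 <- render_night(cfg)
  expect_identical(n1$recording$samples, n2$recording$samples)
  expect_identical(n1$hypnogram$stages, n2$hypnogram$stages)
  expect_identical(n1$stim_log$intervals, n2$stim_log$intervals)
})

test_that("ground truth matches the rendered night", {
  cfg <- quick_cfg(duration = 1800, fs = 200, seed = 9)
  night <- render_night(cfg)
  gt <- night$ground_truth
  expect_identical(gt$hypnogram, night$hypnogram$stages)
  expect_false(any(gt$stim_on_mask !=
                     (stim_illuminance(night$stim_log) > 0)))
  # control nights have an everywhere-false stimulation mask
  ctrl <- render_night(quick_cfg(duration = 600, fs = 200,
                                 condition = "control", seed = 9))
  expect_false(any(ctrl$ground_truth$stim_on_mask))
})

test_that("ground-truth JSON sidecar round-trips the key fields", {
  cfg <- quick_cfg(duration = 300, fs = 200, seed = 2)
  night <- render_night(cfg)
  tf <- tempfile(fileext = ".json")
  write_ground_truth_json(night, tf)
  gt <- jsonlite::read_json(tf, simplifyVector = TRUE)
  expect_equal(gt$hypnogram, night$hypnogram$stages)
  expect_equal(gt$stage_amplitudes$N3, 0.07)
  mask <- rep(gt$stim_on_rle$values, gt$stim_on_rle$lengths)
  expect_equal(mask, night$ground_truth$stim_on_mask)
})

test_that("doubling the injected amplitude doubles the recovered SSVEP", {
  # >= 100k segments so the range-statistic noise bias stays inside the
  # Monte-Carlo tolerance; the same seed shares the noise realisation
  render_amp <- function(A) {
    cfg <- sim_config(sampling_rate = 400, night_duration = 2520,
                      protocol = "wake", condition = "experimental",
                      rng_seed = 31,
                      stage_ssvep_amplitude = c(W = A, N2 = 0.08, N3 = 0.07,
                                                REM = 0.09))
    night <- render_night(cfg, hyp = hypnogram(rep("W", 84)))
    pre <- preprocess_night(night$recording, night$hypnogram, night$stim_log,
                            "experimental", 1)
    ss <- reject_segments(segment_at_led_on(pre$roi, night$stim_log,
                                            pre$ssvep_keep))
    average_ssvep(ss)$ssvep_amp
  }
  a1 <- render_amp(0.96)
  a2 <- render_amp(1.92)
  expect_equal(a2 / a1, 2, tolerance = 0.05)
})
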