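# Stimulus-locked segmentation, rejection, averaging, shuffle SNR and the
# LED-artifact interpolation control.

# A minimal wake stim_log over `sec` seconds at `fs` Hz.
wake_stimlog <- function(sec, fs) {
  cfg <- sim_config(sampling_rate = fs, night_duration = max(sec, 300),
                    protocol = "wake", condition = "experimental")
  sl <- build_stim_schedule(hypnogram(rep("W", max(sec, 300) / 30)), cfg)
  sl$n_samples <- sec * fs
  sl$intervals$end <- sec * fs + 1L
  sl$pieces$end <- sec * fs + 1L
  sl
}

test_that("10 s of continuous stimulation yields 400 segments of 25 ms", {
  fs <- 1000
  sl <- wake_stimlog(10, fs)
  x <- rnorm(10 * fs)
  ss <- segment_at_led_on(x, sl)
  expect_equal(dim(ss$segments), c(400, 25))     # 40/s x 10 s, 25 samples
  expect_equal(ncol(ss$segments) / fs, 0.025)    # exactly 25 ms
  # segments are the contiguous non-overlapping cycles of the signal
  expect_equal(as.numeric(t(ss$segments)), x)
})

test_that("fade intervals are excluded and control nights use the LED clock", {
  fs <- 200
  cfg <- quick_cfg(duration = 900, fs = fs, seed = 1)
  hyp <- hypnogram(rep("N3", 30))
  sl <- build_stim_schedule(hyp, cfg)   # 300 s ramp, then 600 s full
  x <- rnorm(900 * fs)
  ss <- segment_at_led_on(x, sl)
  expect_equal(nrow(ss$segments), 600 * 40)
  # control: masked LEDs provide virtual edges across the whole night
  ctl <- build_stim_schedule(hyp, quick_cfg(duration = 900, fs = fs,
                                            condition = "control"))
  ss_c <- segment_at_led_on(x, ctl)
  expect_equal(nrow(ss_c$segments), 900 * 40)
  # a schedule with no stimulation at all yields an empty set with warning
  off <- build_stim_schedule(hypnogram(rep("N2", 30)),
                             quick_cfg(duration = 900, fs = fs,
                                       require_n3 = FALSE))
  expect_warning(ss_o <- segment_at_led_on(x, off), "no stimulus-locked")
  expect_equal(nrow(ss_o$segments), 0)
  # misaligned log is an error
  expect_error(segment_at_led_on(x[1:100], sl), "aligned")
})

test_that("segments inherit their epoch's rejection status", {
  fs <- 200
  sl <- wake_stimlog(90, fs)
  x <- rnorm(90 * fs)
  ss_all <- segment_at_led_on(x, sl)
  ss_kept <- segment_at_led_on(x, sl, keep_epochs = c(0L, 2L))
  expect_equal(nrow(ss_kept$segments), 2 * 1200)
  expect_true(all(ss_kept$epoch_index %in% c(0L, 2L)))
  expect_equal(nrow(ss_all$segments), 3 * 1200)
})

test_that("segment rejection reads the 100 uV boundary strictly", {
  base <- matrix(0, 3, 25)
  base[1, 5] <- 101   # range 101 -> rejected
  base[2, 5] <- 100   # range exactly 100 -> kept
  ss <- structure(list(segments = base, epoch_index = c(0L, 0L, 0L),
                       fs = 1000, n_rejected = 0L), class = "segment_set")
  out <- reject_segments(ss)
  expect_equal(nrow(out$segments), 2)
  expect_equal(out$n_rejected, 1L)
  expect_true(all(out$segments[2, ] == 0))  # the all-zero segment survives
  # monotonicity: stricter thresholds never keep more segments
  set.seed(9)
  noisy <- structure(list(segments = matrix(rnorm(500 * 25, sd = 40), 500),
                          epoch_index = integer(500), fs = 1000,
                          n_rejected = 0L), class = "segment_set")
  kept <- vapply(c(300, 200, 150, 100, 50),
                 function(l) nrow(reject_segments(noisy, l)$segments), 0L)
  expect_true(all(diff(kept) <= 0))
})

test_that("averaging recovers a common waveform and suppresses unlocked noise", {
  w <- sin(2 * pi * (0:24) / 25)
  ss <- structure(list(segments = matrix(rep(w, 10), 10, byrow = TRUE),
                       epoch_index = integer(10), fs = 1000,
                       n_rejected = 0L), class = "segment_set")
  res <- average_ssvep(ss)
  expect_equal(res$waveform, w)
  expect_equal(res$ssvep_amp, max(w) - min(w))
  # sinusoid + zero-mean noise: amplitude converges to the sinusoid's
  set.seed(10)
  n <- 100000
  segs <- matrix(rep(w, n), n, byrow = TRUE) + rnorm(n * 25, sd = 2)
  ssn <- structure(list(segments = segs, epoch_index = integer(n),
                        fs = 1000, n_rejected = 0L), class = "segment_set")
  amp <- average_ssvep(ssn)$ssvep_amp
  expect_equal(amp, max(w) - min(w), tolerance = 0.02)
  # phase-scrambled noise alone averages towards zero
  segs0 <- matrix(rnorm(n * 25, sd = 2), n)
  ss0 <- structure(list(segments = segs0, epoch_index = integer(n),
                        fs = 1000, n_rejected = 0L), class = "segment_set")
  expect_lt(average_ssvep(ss0)$ssvep_amp, 0.05)
  # empty sets are an error
  ss_empty <- structure(list(segments = segs[0, , drop = FALSE],
                             epoch_index = integer(), fs = 1000,
                             n_rejected = 0L), class = "segment_set")
  expect_error(average_ssvep(ss_empty), "cannot average")
})

test_that("the compiled shuffle kernel matches the plain-R reference", {
  set.seed(11)
  segs <- matrix(rnorm(40 * 10), 40)
  set.seed(123)
  a_cpp <- gammaflick:::shuffle_null_amps_cpp(segs, 50)
  set.seed(123)
  a_r <- gammaflick:::shuffle_null_amps_r(segs, 50)
  # same null distribution (not the same draws: permutation order differs)
  expect_equal(mean(a_cpp), mean(a_r), tolerance = 0.1)
  expect_equal(sd(a_cpp), sd(a_r), tolerance = 0.5)
})

test_that("shuffle SNR concentrates near 1 for exchangeable segments", {
  set.seed(12)
  mk <- function(segs) structure(list(segments = segs,
                                      epoch_index = integer(nrow(segs)),
                                      fs = 1000, n_rejected = 0L),
                                 class = "segment_set")
  snr_null <- shuffle_snr(mk(matrix(rnorm(20000 * 25), 20000)), 100,
                          seed = 1)
  expect_gt(snr_null, 0.7)
  expect_lt(snr_null, 1.3)
  # a strong common sinusoid drives the SNR far above 1
  w <- 5 * sin(2 * pi * (0:24) / 25)
  segs <- matrix(rep(w, 5000), 5000, byrow = TRUE) + rnorm(5000 * 25)
  expect_gt(shuffle_snr(mk(segs), 100, seed = 1), 5)
  # determinism under a fixed seed
  s1 <- shuffle_snr(mk(segs), 20, seed = 99)
  s2 <- shuffle_snr(mk(segs), 20, seed = 99)
  expect_identical(as.numeric(s1), as.numeric(s2))
  # degenerate null: constant segments
  expect_error(shuffle_snr(mk(matrix(1, 10, 25)), 10, seed = 1),
               "degenerate null")
  expect_error(shuffle_snr(mk(matrix(1, 1, 25)), 10), "at least 2")
})

test_that("LED-edge interpolation removes spikes and leaves clean signals alone", {
  fs <- 1000
  sl <- wake_stimlog(10, fs)
  x <- rep(1, 10 * fs)
  edges <- led_edges(sl, "both", "active")
  x[edges] <- 50   # 1-sample spike at each edge
  y <- interpolate_led_artifact(x, sl, window = 0.002)
  inner <- 30:(length(y) - 30)
  expect_true(all(abs(y[inner] - 1) < 1e-12))
  # with no edges in range the signal is returned untouched
  z <- sin(2 * pi * 3 * seq_len(10 * fs) / fs)
  off <- build_stim_schedule(hypnogram(rep("N2", 10)),
                             quick_cfg(duration = 300, fs = fs,
                                       require_n3 = FALSE))
  off$n_samples <- length(z)
  expect_identical(interpolate_led_artifact(z, off, window = 0.002), z)
  # on smooth signal, interpolating across edges only nudges the curvature
  expect_equal(interpolate_led_artifact(z, sl, window = 0.002), z,
               tolerance = 1e-3)
  # windows at or beyond half a cycle would overlap
  expect_error(interpolate_led_artifact(x, sl, window = 0.0125), "overlap")
})

test_that("interpolation cancels an injected LED artifact but not the SSVEP", {
  fs <- 1000
  base <- noiseless_cfg(duration = 300, fs = fs, protocol = "wake",
                        led_artifact_amplitude = 0.5)
  night <- render_night(base, hyp = hypnogram(rep("W", 10)))
  x <- night$recording$samples["Oz", ]
  ss_raw <- segment_at_led_on(x, night$stim_log)
  amp_raw <- average_ssvep(ss_raw)$ssvep_amp
  xi <- interpolate_led_artifact(x, night$stim_log, window = 0.002)
  amp_int <- average_ssvep(segment_at_led_on(xi, night$stim_log))$ssvep_amp
  clean <- render_night(noiseless_cfg(duration = 300, fs = fs,
                                      protocol = "wake"),
                        hyp = hypnogram(rep("W", 10)))
  amp_clean <- average_ssvep(
    segment_at_led_on(clean$recording$samples["Oz", ],
                      clean$stim_log))$ssvep_amp
  expect_gt(abs(amp_raw - amp_clean), 0.1)       # artifact distorts the raw amp
  expect_equal(amp_int, amp_clean, tolerance = 0.05)
})
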