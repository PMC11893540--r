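# Shared fixtures: all synthetic, built in code at test time.

# A small, fast night configuration. Noise and artifacts stay at their
# defaults unless overridden.
quick_cfg <- function(duration = 600, fs = 200, condition = "experimental",
                      protocol = "sleep", seed = 1, ...) {
  sim_config(sampling_rate = fs, night_duration = duration,
             condition = condition, protocol = protocol, rng_seed = seed,
             ...)
}

# Config with every stochastic component silenced: pure evoked response.
noiseless_cfg <- function(duration = 300, fs = 1000, protocol = "wake",
                          condition = "experimental", seed = 1, ...) {
  sim_config(sampling_rate = fs, night_duration = duration,
             condition = condition, protocol = protocol, rng_seed = seed,
             background_rms = 0, mastoid_rms = 0, sensor_noise_rms = 0,
             floor_psd = 0, wake_floor_psd = 0,
             stage_band_powers = list(),
             artifact_rates = list(emg = 0, emg_wake_factor = 1, emg_amp = 0,
                                   emg_roi_amp = 0, ocular = 0,
                                   ocular_amp = 0, ocular_roi_amp = 0),
             ...)
}

# Transition matrix pinning the chain to its start state.
identity_transitions <- function() diag(5)

# Hand-built epoch set: `n` clean 30 s epochs of low-amplitude noise at fs,
# certainty 1, full stimulation; individual epochs are then perturbed by
# tests.
toy_epoch_set <- function(n = 20, fs = 200, condition = "experimental",
                          seed = 1) {
  set.seed(seed)
  es_samples <- 30 * fs
  sig <- matrix(rnorm(n * es_samples, sd = 5), nrow = n)
  meta <- data.frame(epoch_index = seq_len(n) - 1L,
                     stage = rep("N3", n), certainty = rep(1, n),
                     condition = condition, session = 3L,
                     stim_seconds = rep(30, n), rejected = FALSE,
                     reason = NA_character_, stringsAsFactors = FALSE)
  structure(list(signal = sig, meta = meta, fs = fs), class = "epoch_set")
}

# Direct O(N^2) Hamming-window DFT periodogram: the brute-force oracle for
# epoch_psd (density scaling, one-sided, dB re 1 V^2/Hz).
dft_psd_oracle <- function(x, fs) {
  n <- length(x)
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))
  xw <- x * w
  nb <- n %/% 2 + 1
  p <- numeric(nb)
  tt <- 0:(n - 1)
  for (k in seq_len(nb)) {
    re <- sum(xw * cos(2 * pi * (k - 1) * tt / n))
    im <- -sum(xw * sin(2 * pi * (k - 1) * tt / n))
    p[k] <- (re^2 + im^2) / (fs * sum(w^2))
  }
  if (n %% 2 == 0) p[2:(nb - 1)] <- 2 * p[2:(nb - 1)] else p[2:nb] <- 2 * p[2:nb]
  list(frequencies = (seq_len(nb) - 1) * fs / n, power = p)
}

# Analytic power of the one-sample paired t-test via the noncentral t.
power_t_closed_form <- function(d, n, alpha = 0.05,
                                tail = c("two.sided", "greater")) {
  tail <- match.arg(tail)
  ncp <- d * sqrt(n); df <- n - 1
  if (tail == "two.sided") {
    crit <- qt(1 - alpha / 2, df)
    pt(crit, df, ncp, lower.tail = FALSE) + pt(-crit, df, ncp)
  } else {
    pt(qt(1 - alpha, df), df, ncp, lower.tail = FALSE)
  }
}
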