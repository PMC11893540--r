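#' Construct a multichannel recording object
#'
#' @param samples Channels x time numeric matrix, physical units uV.
#' @param sampling_rate Sampling rate in Hz.
#' @param channel_labels Character vector, one label per row of `samples`.
#' @param start_time Recording start in seconds (default 0).
#' @return Object of class `recording`.
#' @export
recording <- function(samples, sampling_rate, channel_labels, start_time = 0) {
  samples <- as.matrix(samples)
  if (nrow(samples) != length(channel_labels))
    stop("need one channel label per row of `samples`")
  if (anyDuplicated(channel_labels))
    stop("duplicate channel label: ",
         channel_labels[duplicated(channel_labels)][1])
  if (sampling_rate <= 0) stop("sampling_rate must be positive")
  rownames(samples) <- channel_labels
  structure(list(samples = samples, sampling_rate = sampling_rate,
                 channel_labels = channel_labels, start_time = start_time),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat("<recording> ", length(x$channel_labels), " channels x ",
      ncol(x$samples), " samples (", ncol(x$samples) / x$sampling_rate,
      " s @ ", x$sampling_rate, " Hz)\n  channels: ",
      paste(x$channel_labels, collapse = " "), "\n", sep = "")
  invisible(x)
}

# Occipito-parietal region of interest and reference channels.
ROI_CHANNELS <- c("O1", "Oz", "O2", "PO3", "POz", "PO4")
MASTOID_CHANNELS <- c("A1", "A2")
EOG_CHANNELS <- c("LEOG", "REOG")
EMG_CHANNELS <- c("LEMG", "REMG")
ALL_CHANNELS <- c(ROI_CHANNELS, MASTOID_CHANNELS, EOG_CHANNELS, EMG_CHANNELS)

# Gaussian noise with a 1/f^a amplitude spectrum above 1 Hz (flat below),
# scaled to an exact target RMS. Deterministic given the RNG state.
powerlaw_noise <- function(n, fs, exponent, rms) {
  if (rms <= 0) return(numeric(n))
  w <- rnorm(n)
  if (exponent == 0) return(w * rms / stats::sd(w))
  X <- fft(w)
  f <- c(0, seq_len(n - 1)) * fs / n
  f <- pmin(f, fs - f)              # fold to physical frequency
  g <- pmax(f, 1) ^ (-exponent / 2) # flat below 1 Hz
  g[1] <- 0                         # no DC
  x <- Re(fft(X * g, inverse = TRUE)) / n
  x * rms / stats::sd(x)
}

# Raised-cosine taper of `k` samples applied to both ends of x (in place).
taper_ends <- function(x, k) {
  n <- length(x)
  k <- min(k, floor(n / 2))
  if (k < 1) return(x)
  w <- 0.5 * (1 - cos(pi * (seq_len(k) - 0.5) / k))
  x[seq_len(k)] <- x[seq_len(k)] * w
  x[(n - k + 1):n] <- x[(n - k + 1):n] * rev(w)
  x
}

#' Render a full synthetic polysomnography night
#'
#' Produces a 12-channel recording (occipito-parietal ROI O1/Oz/O2/PO3/POz/
#' PO4, mastoids A1/A2, two EOG and two EMG leads), the hypnogram that drove
#' it, the stimulation log, and the ground truth needed for parameter
#' recovery. The signal model per ROI channel is: shared 1/f background +
#' stage-specific oscillations (alpha in W, spindles in N2, a slow
#' oscillation in N3, theta in REM) + the 40 Hz evoked response (scaled by the
#' configured stage amplitude and the instantaneous illuminance, present only
#' while visible stimulation is on) + artifact bleed + white sensor noise.
#' An optional biphasic electrical LED artifact is added to all channels at
#' every LED edge whenever the circuit is active - including in the control
#' condition, where the LEDs are driven but masked.
#'
#' @param config A [sim_config()].
#' @param hyp Optional [hypnogram()] overriding the generated one (the
#'   stimulation schedule still reacts to it).
#' @return A list of class `sim_night` with elements `recording`,
#'   `hypnogram`, `stim_log`, `ground_truth`.
#' @export
render_night <- function(config, hyp = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(hyp)) {
    hyp <- generate_hypnogram(config)  # seeds the RNG from the config
  } else {
    stopifnot(inherits(hyp, "hypnogram"))
    if (length(hyp) * 30L != config$night_duration)
      stop("hypnogram length does not match night_duration")
    set.seed(config$rng_seed)
  }
  fs <- config$sampling_rate
  n <- length(hyp) * 30L * fs
  es <- 30L * fs
  sl <- build_stim_schedule(hyp, config)

  stage_per_epoch <- hyp$stages
  bouts <- rle(stage_per_epoch)
  bout_end <- cumsum(bouts$lengths)
  bout_start <- bout_end - bouts$lengths + 1L

  ch <- matrix(0, nrow = length(ALL_CHANNELS), ncol = n,
               dimnames = list(ALL_CHANNELS, NULL))

  ## shared occipito-parietal background + broadband floor + oscillations
  B <- powerlaw_noise(n, fs, config$background_1f_exponent,
                      config$background_rms)
  if ((config$floor_psd %||% 0) > 0)
    B <- B + rnorm(n) * sqrt(config$floor_psd * fs / 2)
  # tonic waking muscle-tone floor during W epochs
  if ((config$wake_floor_psd %||% 0) > 0) {
    w_idx <- which(rep(stage_per_epoch, each = es) == "W")
    if (length(w_idx))
      B[w_idx] <- B[w_idx] +
        rnorm(length(w_idx)) * sqrt(config$wake_floor_psd * fs / 2)
  }
  sbp <- config$stage_band_powers
  spindle_times <- numeric(0)
  for (b in seq_along(bouts$values)) {
    st <- bouts$values[b]
    if (is.null(sbp[[st]])) next
    s0 <- (bout_start[b] - 1L) * es + 1L
    s1 <- bout_end[b] * es
    idx <- s0:s1
    len <- length(idx)
    p <- sbp[[st]]
    if (st == "N2") {
      n_ev <- rpois(1, p$rate_per_min * len / fs / 60)
      if (n_ev > 0) {
        t_ev <- sort(runif(n_ev, 0, len / fs - p$duration))
        spindle_times <- c(spindle_times, (s0 - 1L) / fs + t_ev)
        for (te in t_ev) {
          k <- round(p$duration * fs)
          tt <- seq_len(k) / fs
          env <- 0.5 * (1 - cos(2 * pi * (seq_len(k) - 0.5) / k))
          seg <- p$amp * env * sin(2 * pi * p$freq * tt + runif(1, 0, 2 * pi))
          j <- s0 + round(te * fs) + seq_len(k) - 1L
          B[j] <- B[j] + seg
        }
      }
    } else {
      tt <- (idx - 1) / fs
      osc <- sqrt(2) * p$rms * sin(2 * pi * p$freq * tt + runif(1, 0, 2 * pi))
      B[idx] <- B[idx] + taper_ends(osc, fs)
    }
  }

  ## artifacts (waveforms shared between source lead and scalp bleed)
  ar <- config$artifact_rates
  emg_bleed <- numeric(n); emg_lead <- numeric(n)
  ocu_bleed <- numeric(n); ocu_lead <- numeric(n)
  emg_times <- numeric(0); ocu_times <- numeric(0)
  for (b in seq_along(bouts$values)) {
    st <- bouts$values[b]
    s0 <- (bout_start[b] - 1L) * es + 1L
    len <- bouts$lengths[b] * es
    mins <- len / fs / 60
    rate <- ar$emg * if (st == "W") ar$emg_wake_factor else 1
    n_ev <- rpois(1, rate * mins)
    if (n_ev > 0) {
      k <- round(0.5 * fs)
      env <- 0.5 * (1 - cos(2 * pi * (seq_len(k) - 0.5) / k))
      for (te in runif(n_ev, 0, (len - k - 1) / fs)) {
        j <- s0 + round(te * fs) + seq_len(k) - 1L
        burst <- rnorm(k) * env
        emg_lead[j] <- emg_lead[j] + ar$emg_amp * burst
        emg_bleed[j] <- emg_bleed[j] + ar$emg_roi_amp * burst
        emg_times <- c(emg_times, (s0 - 1L) / fs + te)
      }
    }
    if (st %in% c("W", "REM")) {
      n_ev <- rpois(1, ar$ocular * mins)
      if (n_ev > 0) {
        k <- round(1 * fs)
        env <- 0.5 * (1 - cos(2 * pi * (seq_len(k) - 0.5) / k))
        for (te in runif(n_ev, 0, (len - k - 1) / fs)) {
          j <- s0 + round(te * fs) + seq_len(k) - 1L
          sgn <- sample(c(-1, 1), 1)
          ocu_lead[j] <- ocu_lead[j] + sgn * ar$ocular_amp * env
          ocu_bleed[j] <- ocu_bleed[j] + sgn * ar$ocular_roi_amp * env
          ocu_times <- c(ocu_times, (s0 - 1L) / fs + te)
        }
      }
    }
  }

  ## evoked 40 Hz response on ROI channels during visible stimulation
  vis <- sl$intervals[sl$intervals$visible == 1, , drop = FALSE]
  evoked <- NULL; vis_idx <- NULL; stim_on <- logical(n)
  if (nrow(vis) > 0) {
    vis_idx <- unlist(lapply(seq_len(nrow(vis)),
                             function(k) vis$start[k]:(vis$end[k] - 1L)))
    ill <- stim_illuminance(sl)[vis_idx]
    amp_map <- c(config$stage_ssvep_amplitude, N1 = 0)
    amp_epoch <- amp_map[stage_per_epoch]
    amp_s <- amp_epoch[(vis_idx - 1L) %/% es + 1L]
    tt <- (vis_idx - 1) / fs - config$evoked_delay
    w <- sin(2 * pi * config$stim_frequency * tt)
    if (config$evoked_harmonic > 0)
      w <- w + config$evoked_harmonic *
        sin(2 * pi * 2 * config$stim_frequency * tt)
    # normalise so the sampled per-cycle peak-to-trough equals the configured
    # amplitude exactly (the sample grid does not hit the analytic extrema)
    t0 <- seq_len(sl$period) / fs - 1 / fs - config$evoked_delay
    w0 <- sin(2 * pi * config$stim_frequency * t0)
    if (config$evoked_harmonic > 0)
      w0 <- w0 + config$evoked_harmonic *
        sin(2 * pi * 2 * config$stim_frequency * t0)
    evoked <- amp_s * ill * w / (max(w0) - min(w0))
    stim_on[vis_idx] <- ill > 0
  }

  ## assemble channels
  for (cc in ROI_CHANNELS) {
    x <- B + emg_bleed + ocu_bleed +
      rnorm(n) * config$sensor_noise_rms
    if (!is.null(evoked)) x[vis_idx] <- x[vis_idx] + evoked
    ch[cc, ] <- x
  }
  for (cc in MASTOID_CHANNELS)
    ch[cc, ] <- powerlaw_noise(n, fs, config$background_1f_exponent,
                               config$mastoid_rms) +
      rnorm(n) * config$sensor_noise_rms
  eog_sign <- c(LEOG = 1, REOG = -1)
  for (cc in EOG_CHANNELS)
    ch[cc, ] <- powerlaw_noise(n, fs, config$background_1f_exponent, 5) +
      eog_sign[cc] * ocu_lead + rnorm(n) * config$sensor_noise_rms
  for (cc in EMG_CHANNELS)
    ch[cc, ] <- rnorm(n) * 5 + emg_lead

  ## electrical LED artifact at every edge while the circuit is active.
  ## Coupling is channel-specific (electrical pickup is not spatially
  ## uniform), so mastoid re-referencing attenuates but does not cancel it;
  ## the Oz gain is exactly 1 so the configured amplitude is the Oz value.
  led_edge_samples <- integer(0)
  if (config$led_artifact_amplitude > 0 && nrow(sl$intervals) > 0) {
    led_edge_samples <- led_edges(sl, "both", "active")
    w <- max(2L, as.integer(round(config$led_artifact_width * fs)))
    half <- w %/% 2L
    tpl <- config$led_artifact_amplitude * rep(c(1, -1), c(half, w - half))
    art <- numeric(n)
    for (o in seq_len(w)) {
      j <- led_edge_samples + o - 1L
      ok <- j <= n
      art[j[ok]] <- art[j[ok]] + tpl[o]
    }
    gains <- c(O1 = 1.1, Oz = 1.0, O2 = 0.9, PO3 = 1.05, POz = 0.95,
               PO4 = 1.0, A1 = 0.5, A2 = 0.5, LEOG = 1.2, REOG = 1.2,
               LEMG = 0.8, REMG = 0.8)
    for (cc in ALL_CHANNELS) ch[cc, ] <- ch[cc, ] + gains[[cc]] * art
  }

  rec <- recording(ch, fs, ALL_CHANNELS)
  gt <- list(stage_amplitudes = config$stage_ssvep_amplitude,
             hypnogram = hyp$stages,
             stim_on_mask = stim_on,
             artifact_times = list(emg = sort(emg_times),
                                   ocular = sort(ocu_times),
                                   spindles = sort(spindle_times),
                                   led_edges = led_edge_samples),
             condition = config$condition,
             rng_seed = config$rng_seed)
  structure(list(recording = rec, hypnogram = hyp, stim_log = sl,
                 ground_truth = gt),
            class = "sim_night")
}

#' @export
print.sim_night <- function(x, ...) {
  cat("<sim_night> condition=", x$ground_truth$condition, "\n", sep = "")
  print(x$recording); print(x$hypnogram); print(x$stim_log)
  invisible(x)
}

#' Write a ground-truth sidecar JSON
#'
#' Stores the injected stage amplitudes, hypnogram, artifact event times and
#' the run-length-encoded visible-stimulation mask.
#'
#' @param night A `sim_night` from [render_night()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth_json <- function(night, path) {
  stopifnot(inherits(night, "sim_night"))
  gt <- night$ground_truth
  r <- rle(gt$stim_on_mask)
  out <- list(stage_amplitudes = as.list(gt$stage_amplitudes),
              hypnogram = gt$hypnogram,
              stim_on_rle = list(lengths = r$lengths, values = r$values),
              artifact_times = gt$artifact_times,
              condition = gt$condition,
              rng_seed = gt$rng_seed)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
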