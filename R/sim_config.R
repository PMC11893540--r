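#' Simulation configuration for a synthetic stimulation night
#'
#' Bundles every knob of the synthetic polysomnography generator: the
#' stimulation protocol constants (40 Hz square-wave flicker, 50% duty cycle,
#' 5-minute raised-cosine fade-in, 5-second fade-out on arousal, resumption
#' after six consecutive non-W/N1 epochs), the per-stage evoked-response
#' amplitudes, the background-EEG model and the artifact model.
#'
#' Stage evoked amplitudes default to the peak-to-trough values typical of
#' red-light 40 Hz flicker through closed eyelids: large while awake
#' (0.96 uV) and an order of magnitude smaller in sleep (N2 0.08, N3 0.07,
#' REM 0.09 uV).
#'
#' @param sampling_rate Sampling rate in Hz; must be a multiple of 40 so each
#'   25 ms flicker cycle is an integer number of samples. Default 1000.
#' @param night_duration Recording duration in seconds; must be a multiple of
#'   30 (one PSG epoch) and at least 120. Default 28800 (8 h sleep
#'   opportunity).
#' @param stim_frequency Flicker frequency in Hz, fixed at 40.
#' @param duty_cycle Fraction of each flicker period with the LED on, in
#'   (0, 1). Default 0.5.
#' @param fade_in_duration Illuminance ramp duration in seconds for the sleep
#'   protocol (raised cosine). Default 300.
#' @param fade_out_duration Fade-out duration in seconds on arousal. Default 5.
#' @param resume_rule_epochs Number of consecutive epochs scored neither W nor
#'   N1 required before stimulation restarts. Default 6.
#' @param stage_ssvep_amplitude Named numeric map stage -> injected evoked
#'   peak-to-trough amplitude in uV for stages W, N2, N3, REM (N1 receives no
#'   evoked response and is never analysed).
#' @param evoked_delay Latency in seconds between an LED-ON edge and the
#'   evoked sinusoid's zero phase. Default 0.004.
#' @param evoked_harmonic Relative amplitude of an optional 2nd harmonic of
#'   the evoked response (0 = pure fundamental, the default).
#' @param background_1f_exponent Spectral exponent of the 1/f^a background.
#'   Default 2 (typical of sleep EEG above ~1 Hz).
#' @param background_rms RMS amplitude (uV) of the shared occipito-parietal
#'   1/f background. Default 4.
#' @param floor_psd Spectral density (uV^2/Hz) of the flat broadband floor
#'   shared by the ROI channels, emulating the scalp-EMG/amplifier noise
#'   floor that dominates real EEG spectra above ~30 Hz. Default 0.005.
#' @param wake_floor_psd Additional broadband floor (uV^2/Hz) during W
#'   epochs, emulating tonic waking muscle activity: waking EEG carries far
#'   more 40 Hz-range power than atonic sleep. Default 0.15.
#' @param mastoid_rms RMS amplitude (uV) of the mastoid 1/f background.
#'   Default 2.
#' @param sensor_noise_rms Per-channel white sensor noise RMS in uV. Default 1.
#' @param stage_band_powers Named list of per-stage oscillation settings; see
#'   Details. Pass `list()` to disable all stage oscillations.
#' @param artifact_rates List with events-per-minute rates `emg` and `ocular`
#'   (the W/REM-dominant slow deflections); amplitudes `emg_amp` (uV RMS on
#'   the EMG leads), `emg_roi_amp` (bleed into the scalp ROI), `ocular_amp`
#'   (EOG deflection size) and `ocular_roi_amp`.
#' @param led_artifact_amplitude Amplitude (uV) of the biphasic electrical
#'   transient injected at every LED on/off edge on all channels whenever the
#'   LED circuit is active (also in the control night, where the LEDs are
#'   masked but still driven). Default 0 (none).
#' @param led_artifact_width Width of the biphasic transient in seconds.
#'   Default 0.002.
#' @param condition `"experimental"` or `"control"`. In the control condition
#'   the LED circuit runs for the whole recording but no light is visible.
#' @param protocol `"sleep"` (closed-loop, triggered by the first N3 epoch)
#'   or `"wake"` (stimulation on from the start of the recording, as in a
#'   wakefulness stimulation block).
#' @param stage_transitions Optional 5x5 row-stochastic matrix (rows/columns
#'   W, N1, N2, N3, REM) replacing the default hypnogram transition matrix.
#' @param start_stage Stage the hypnogram starts in. Default "W".
#' @param require_n3 Logical; resample the hypnogram (deterministically under
#'   the seed) until it contains at least one N3 epoch so the stimulation
#'   trigger can fire. Default TRUE for sleep-protocol nights.
#' @param rng_seed Integer seed driving every random draw of the generator.
#'
#' @details
#' `stage_band_powers` entries are lists with fields depending on the stage:
#' `W = list(freq, rms)` continuous alpha; `N2 = list(freq, rate_per_min,
#' duration, amp)` spindle events; `N3 = list(freq, rms)` slow oscillation;
#' `REM = list(freq, rms)` low-amplitude theta.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(sampling_rate = 1000,
                       night_duration = 28800,
                       stim_frequency = 40,
                       duty_cycle = 0.5,
                       fade_in_duration = 300,
                       fade_out_duration = 5,
                       resume_rule_epochs = 6,
                       stage_ssvep_amplitude = c(W = 0.96, N2 = 0.08,
                                                 N3 = 0.07, REM = 0.09),
                       evoked_delay = 0.004,
                       evoked_harmonic = 0,
                       background_1f_exponent = 2,
                       background_rms = 4,
                       floor_psd = 0.005,
                       wake_floor_psd = 0.15,
                       mastoid_rms = 2,
                       sensor_noise_rms = 1,
                       stage_band_powers = default_stage_band_powers(),
                       artifact_rates = default_artifact_rates(),
                       led_artifact_amplitude = 0,
                       led_artifact_width = 0.002,
                       condition = c("experimental", "control"),
                       protocol = c("sleep", "wake"),
                       stage_transitions = NULL,
                       start_stage = "W",
                       require_n3 = NULL,
                       rng_seed = 1L) {
  condition <- match.arg(condition)
  protocol <- match.arg(protocol)
  if (sampling_rate <= 0 || sampling_rate %% stim_frequency != 0)
    stop("sampling_rate must be a positive multiple of ", stim_frequency, " Hz")
  if (night_duration < 120)
    stop("night_duration must be at least 120 s")
  if (night_duration %% 30 != 0)
    stop("night_duration must be a multiple of 30 s (one PSG epoch)")
  if (duty_cycle <= 0 || duty_cycle >= 1)
    stop("duty_cycle must lie in (0, 1)")
  amp <- stage_ssvep_amplitude
  if (!all(ANALYSIS_STAGES %in% names(amp)))
    stop("stage_ssvep_amplitude needs entries for W, N2, N3, REM")
  if (any(amp < 0) || background_rms < 0 || mastoid_rms < 0 ||
      sensor_noise_rms < 0 || led_artifact_amplitude < 0 || floor_psd < 0 ||
      wake_floor_psd < 0)
    stop("amplitudes must be non-negative")
  if (fade_in_duration < 0 || fade_out_duration < 0)
    stop("fade durations must be non-negative")
  if (!is.null(stage_transitions)) {
    stage_transitions <- as.matrix(stage_transitions)
    if (!identical(dim(stage_transitions), c(5L, 5L)))
      stop("stage_transitions must be a 5x5 matrix")
    dimnames(stage_transitions) <- list(STAGES, STAGES)
    if (any(stage_transitions < 0) ||
        any(abs(rowSums(stage_transitions) - 1) > 1e-8))
      stop("stage_transitions rows must be non-negative and sum to 1")
  }
  if (!start_stage %in% STAGES) stop("unknown start_stage: ", start_stage)
  if (is.null(require_n3)) require_n3 <- protocol == "sleep"

  structure(list(
    sampling_rate = as.integer(sampling_rate),
    night_duration = as.integer(night_duration),
    stim_frequency = stim_frequency,
    duty_cycle = duty_cycle,
    fade_in_duration = fade_in_duration,
    fade_out_duration = fade_out_duration,
    resume_rule_epochs = as.integer(resume_rule_epochs),
    stage_ssvep_amplitude = amp[ANALYSIS_STAGES],
    evoked_delay = evoked_delay,
    evoked_harmonic = evoked_harmonic,
    background_1f_exponent = background_1f_exponent,
    background_rms = background_rms,
    floor_psd = floor_psd,
    wake_floor_psd = wake_floor_psd,
    mastoid_rms = mastoid_rms,
    sensor_noise_rms = sensor_noise_rms,
    stage_band_powers = stage_band_powers,
    artifact_rates = artifact_rates,
    led_artifact_amplitude = led_artifact_amplitude,
    led_artifact_width = led_artifact_width,
    condition = condition,
    protocol = protocol,
    stage_transitions = stage_transitions,
    start_stage = start_stage,
    require_n3 = isTRUE(require_n3),
    rng_seed = as.integer(rng_seed)
  ), class = "sim_config")
}

#' Default per-stage oscillatory signatures of the synthetic EEG
#'
#' Alpha while awake, sleep spindles in N2, a slow oscillation in N3 and
#' low-amplitude theta in REM. Amplitudes are in uV (RMS for continuous
#' rhythms, peak for spindle events).
#'
#' @return Named list keyed by stage.
#' @export
default_stage_band_powers <- function() {
  list(
    W   = list(freq = 10,   rms = 5),
    N2  = list(freq = 13,   rate_per_min = 2.5, duration = 1, amp = 7),
    N3  = list(freq = 0.75, rms = 20),
    REM = list(freq = 5,    rms = 2)
  )
}

#' Default artifact model rates and amplitudes
#'
#' EMG bursts occur in every stage (four times as often in W, reflecting
#' waking muscle tone); slow ocular deflections occur in W and REM only.
#'
#' @return List of rates (events/min) and amplitudes (uV).
#' @export
default_artifact_rates <- function() {
  list(emg = 0.5, emg_wake_factor = 4, emg_amp = 30, emg_roi_amp = 5,
       ocular = 1, ocular_amp = 100, ocular_roi_amp = 8)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$condition, "/", x$protocol,
      " night, ", x$night_duration, " s @ ", x$sampling_rate, " Hz\n", sep = "")
  cat("  flicker: ", x$stim_frequency, " Hz, duty ", x$duty_cycle,
      ", fade-in ", x$fade_in_duration, " s, fade-out ",
      x$fade_out_duration, " s, resume after ", x$resume_rule_epochs,
      " calm epochs\n", sep = "")
  cat("  evoked p2p (uV):",
      paste(names(x$stage_ssvep_amplitude), x$stage_ssvep_amplitude,
            sep = "=", collapse = " "), "\n")
  cat("  background 1/f^", x$background_1f_exponent, " rms ",
      x$background_rms, " uV; LED artifact ", x$led_artifact_amplitude,
      " uV; seed ", x$rng_seed, "\n", sep = "")
  invisible(x)
}
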