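#' Zero-phase band-pass filter a recording
#'
#' Cascade of 4th-order Butterworth high-pass and low-pass sections applied
#' forward-backward (zero phase) to every channel. The default band is
#' 0.16-300 Hz; when the upper edge reaches the Nyquist frequency it is
#' clipped to 0.45 * sampling rate with a warning (or an error when
#' `allow_clip = FALSE`).
#'
#' @param rec A [recording()].
#' @param low,high Band edges in Hz.
#' @param allow_clip Permit clipping `high` below Nyquist. Default TRUE.
#' @return A filtered [recording()].
#' @export
bandpass_filter <- function(rec, low = 0.16, high = 300, allow_clip = TRUE) {
  stopifnot(inherits(rec, "recording"))
  fs <- rec$sampling_rate
  nyq <- fs / 2
  if (low <= 0 || low >= high) stop("need 0 < low < high")
  if (high >= nyq) {
    if (!allow_clip)
      stop("upper band edge ", high, " Hz is at or above Nyquist (", nyq,
           " Hz)")
    high <- 0.45 * fs
    warning("upper band edge clipped to ", high, " Hz (Nyquist ", nyq, " Hz)")
    if (low >= high) stop("band collapsed after clipping")
  }
  hp <- signal::butter(4, low / nyq, type = "high")
  lp <- signal::butter(4, high / nyq, type = "low")
  out <- rec
  for (i in seq_len(nrow(rec$samples))) {
    x <- signal::filtfilt(hp, rec$samples[i, ])
    out$samples[i, ] <- signal::filtfilt(lp, x)
  }
  out
}

#' Flag flat or outlying channels
#'
#' A channel is flagged when it is flat (variance below `flat_var` uV^2) or
#' when the robust z-score of its log-variance exceeds `z_thresh` in
#' absolute value (median/MAD based). The outlier rule compares like with
#' like: when region-of-interest EEG channels are present it is evaluated
#' among them only, leaving reference and peripheral leads (mastoids, EOG,
#' EMG) to the flat check; otherwise all channels are pooled. The MAD is
#' floored at 0.2 log-units so that channels sharing near-identical
#' variance cannot make trivial fluctuations look like outliers. Flagged
#' channels are removed from the returned recording.
#'
#' @param rec A [recording()].
#' @param flat_var Flat-channel variance threshold in uV^2. Default 0.01.
#' @param z_thresh Robust z threshold on log-variance. Default 5.
#' @return List with elements `recording` (surviving channels) and
#'   `rejected` (labels of flagged channels).
#' @export
reject_bad_channels <- function(rec, flat_var = 0.01, z_thresh = 5) {
  stopifnot(inherits(rec, "recording"))
  v <- apply(rec$samples, 1, stats::var)
  flat <- v < flat_var
  roi <- rec$channel_labels %in% ROI_CHANNELS
  pool <- if (any(roi)) which(roi) else seq_along(v)
  lv <- log(pmax(v, .Machine$double.xmin))
  med <- median(lv[pool])
  madv <- max(median(abs(lv[pool] - med)) * 1.4826, 0.2)
  z <- rep(0, length(lv))
  z[pool] <- (lv[pool] - med) / madv
  bad <- flat | abs(z) > z_thresh
  if (any(roi) && all(bad[roi]))
    stop("all region-of-interest channels flagged as bad; manual review ",
         "required")
  keep <- which(!bad)
  out <- recording(rec$samples[keep, , drop = FALSE], rec$sampling_rate,
                   rec$channel_labels[keep], rec$start_time)
  list(recording = out, rejected = rec$channel_labels[bad])
}

#' Average the occipito-parietal ROI and re-reference to the mastoids
#'
#' Output sample t = mean over surviving ROI channels of sample t minus the
#' mean of A1 and A2 at sample t.
#'
#' @param rec A [recording()] containing at least one ROI channel
#'   (O1, Oz, O2, PO3, POz, PO4) and both mastoids (A1, A2).
#' @return A single-channel [recording()] labelled `"ROI"`.
#' @export
roi_average_and_rereference <- function(rec) {
  stopifnot(inherits(rec, "recording"))
  roi <- intersect(ROI_CHANNELS, rec$channel_labels)
  if (length(roi) < 1) stop("no region-of-interest channels present")
  missing_mast <- setdiff(MASTOID_CHANNELS, rec$channel_labels)
  if (length(missing_mast) > 0)
    stop("missing mastoid channel(s): ", paste(missing_mast, collapse = ", "))
  roi_mean <- colMeans(rec$samples[roi, , drop = FALSE])
  mast_mean <- colMeans(rec$samples[MASTOID_CHANNELS, , drop = FALSE])
  recording(matrix(roi_mean - mast_mean, nrow = 1), rec$sampling_rate,
            "ROI", rec$start_time)
}

#' Cut a recording into labelled 30-second epochs
#'
#' Consecutive non-overlapping half-open epochs `[k*30 s, (k+1)*30 s)`
#' carrying the hypnogram stage and certainty, the condition and session
#' identifiers, and the seconds of visible stimulation overlapping the epoch.
#'
#' @param rec A single-channel [recording()] (typically the output of
#'   [roi_average_and_rereference()]).
#' @param hyp A [hypnogram()].
#' @param stim A `stim_log` (or NULL for a recording without stimulation
#'   hardware; stimulation seconds are then 0).
#' @param condition `"experimental"` or `"control"`.
#' @param session Session identifier (1, 2 or 3).
#' @return An object of class `epoch_set`: `signal` (epochs x samples
#'   matrix), `meta` (one row per epoch: `epoch_index` 0-based, `stage`,
#'   `certainty`, `condition`, `session`, `stim_seconds`, `rejected`,
#'   `reason`), `fs`.
#' @export
epoch_and_label <- function(rec, hyp, stim, condition, session) {
  stopifnot(inherits(rec, "recording"), inherits(hyp, "hypnogram"))
  if (nrow(rec$samples) != 1)
    stop("epoch_and_label expects a single-channel recording")
  condition <- match.arg(condition, c("experimental", "control"))
  fs <- rec$sampling_rate
  es <- 30L * fs
  n <- ncol(rec$samples)
  n_epochs <- min(n %/% es, length(hyp))
  if (n_epochs == 0) {
    warning("recording shorter than one 30 s epoch; empty epoch set")
    return(empty_epoch_set(fs))
  }
  sigmat <- matrix(rec$samples[1, seq_len(n_epochs * es)],
                   nrow = n_epochs, byrow = TRUE)
  stim_sec <- numeric(n_epochs)
  if (!is.null(stim)) {
    stopifnot(inherits(stim, "stim_log"))
    vis <- stim$intervals$visible == 1
    if (any(vis)) {
      ill <- stim_illuminance(stim, 1L, n_epochs * es)
      on <- logical(n_epochs * es)
      for (k in which(vis)) {
        a <- max(stim$intervals$start[k], 1L)
        b <- min(stim$intervals$end[k] - 1L, n_epochs * es)
        if (a <= b) on[a:b] <- TRUE
      }
      on <- on & ill > 0
      stim_sec <- as.numeric(tapply(on, (seq_len(n_epochs * es) - 1L) %/% es,
                                    sum)) / fs
    }
  }
  meta <- data.frame(
    epoch_index = seq_len(n_epochs) - 1L,
    stage = hyp$stages[seq_len(n_epochs)],
    certainty = hyp$certainty[seq_len(n_epochs)],
    condition = condition,
    session = session,
    stim_seconds = stim_sec,
    rejected = FALSE,
    reason = NA_character_,
    stringsAsFactors = FALSE)
  structure(list(signal = sigmat, meta = meta, fs = fs), class = "epoch_set")
}

empty_epoch_set <- function(fs) {
  structure(list(signal = matrix(numeric(), 0, 0),
                 meta = data.frame(epoch_index = integer(),
                                   stage = character(),
                                   certainty = numeric(),
                                   condition = character(),
                                   session = integer(),
                                   stim_seconds = numeric(),
                                   rejected = logical(),
                                   reason = character(),
                                   stringsAsFactors = FALSE),
                 fs = fs), class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat("<epoch_set> ", nrow(x$meta), " epochs @ ", x$fs, " Hz; rejected: ",
      sum(x$meta$rejected), "\n", sep = "")
  invisible(x)
}

#' Subset an epoch set by row index
#'
#' @param es An `epoch_set`.
#' @param idx Integer row indices into the epoch table.
#' @return An `epoch_set` with the selected epochs.
#' @export
epoch_subset <- function(es, idx) {
  stopifnot(inherits(es, "epoch_set"))
  out <- es
  out$signal <- es$signal[idx, , drop = FALSE]
  out$meta <- es$meta[idx, , drop = FALSE]
  rownames(out$meta) <- NULL
  out
}

#' Apply the bad-trial rejection rules
#'
#' An epoch is rejected when its peak-to-peak amplitude exceeds 1 mV, when
#' the scoring certainty is below 50%, or - in the spectral context and only
#' for experimental-condition epochs - when fewer than 25 s of visible
#' stimulation overlap it (the control night's LEDs are masked, so the
#' stimulation-duration rule is vacuous there). In the `ssvep` context
#' segments exist only during stimulation, so only the amplitude and
#' certainty rules apply. Reason codes (`"amplitude"`, `"certainty"`,
#' `"stim_duration"`, comma-joined when several apply) are recorded; each
#' epoch is judged on its own data, so the operation is idempotent.
#'
#' @param es An `epoch_set`.
#' @param context `"spectral"` or `"ssvep"`.
#' @param p2p_limit Peak-to-peak limit in uV. Default 1000 (1 mV).
#' @param min_certainty Scoring-certainty floor. Default 0.5.
#' @param min_stim_seconds Minimum visible stimulation per experimental
#'   epoch in the spectral context. Default 25.
#' @return The `epoch_set` with `rejected`/`reason` filled in.
#' @export
reject_epochs <- function(es, context = c("spectral", "ssvep"),
                          p2p_limit = 1000, min_certainty = 0.5,
                          min_stim_seconds = 25) {
  stopifnot(inherits(es, "epoch_set"))
  context <- match.arg(context)
  if (nrow(es$meta) == 0) return(es)
  p2p <- apply(es$signal, 1, function(x) max(x) - min(x))
  amp <- p2p > p2p_limit
  cert <- es$meta$certainty < min_certainty
  stim <- rep(FALSE, nrow(es$meta))
  if (context == "spectral")
    stim <- es$meta$condition == "experimental" &
      es$meta$stim_seconds < min_stim_seconds
  reason <- mapply(function(a, c, s) {
    r <- c(if (a) "amplitude", if (c) "certainty", if (s) "stim_duration")
    if (length(r)) paste(r, collapse = ",") else NA_character_
  }, amp, cert, stim)
  es$meta$rejected <- amp | cert | stim
  es$meta$reason <- as.character(reason)
  es
}

#' Assign epochs to condition x stage analysis bins
#'
#' Control bins (W, N2, N3, REM) come from session 2; the experimental W bin
#' only from session 1 (the wakefulness stimulation block); experimental N2,
#' N3 and REM bins from session 3. N1 epochs enter no bin.
#'
#' @param session_epochs Named list of `epoch_set`s keyed `"1"`, `"2"`, `"3"`
#'   (any may be an empty epoch set).
#' @return Nested list `bins[[condition]][[stage]]`, each an `epoch_set`.
#' @export
assign_condition_bins <- function(session_epochs) {
  get_session <- function(s) {
    es <- session_epochs[[as.character(s)]]
    if (is.null(es)) empty_epoch_set(NA_real_) else es
  }
  pick <- function(es, stage) epoch_subset(es, which(es$meta$stage == stage))
  s1 <- get_session(1); s2 <- get_session(2); s3 <- get_session(3)
  bins <- list(control = list(), experimental = list())
  for (st in ANALYSIS_STAGES) bins$control[[st]] <- pick(s2, st)
  bins$experimental$W <- pick(s1, "W")
  for (st in c("N2", "N3", "REM")) bins$experimental[[st]] <- pick(s3, st)
  bins
}
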