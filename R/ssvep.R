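#' Cut a signal into 25 ms stimulus-locked segments
#'
#' One segment per LED-ON edge: in the experimental condition, edges during
#' visible stimulation at full illuminance (fade-in and fade-out intervals
#' are excluded); in the control condition, the electrical 40 Hz clock of the
#' masked LEDs provides "virtual" edges over the whole mask-on interval.
#' Segments are contiguous and non-overlapping (one per flicker cycle), of
#' length `sampling_rate / 40` samples (25 ms).
#'
#' @param x Numeric vector: the ROI-averaged, re-referenced signal in uV.
#' @param stim A `stim_log` aligned to `x` (same sampling rate and start).
#' @param keep_epochs Optional integer vector of 0-based 30 s epoch indices;
#'   segments outside these epochs are dropped (used to propagate bad-trial
#'   rejection into the segment domain).
#' @return Object of class `segment_set`: `segments` (n x L matrix),
#'   `epoch_index` (0-based source epoch per segment), `fs`, `n_rejected`
#'   (filled by [reject_segments()]).
#' @export
segment_at_led_on <- function(x, stim, keep_epochs = NULL) {
  stopifnot(inherits(stim, "stim_log"))
  if (stim$n_samples != length(x))
    stop("stimulation log covers ", stim$n_samples,
         " samples but the signal has ", length(x),
         "; logs must be aligned to the recording")
  L <- stim$period
  within <- if (any(stim$intervals$visible == 1)) "visible_full" else "active"
  edges <- led_edges(stim, "on", within)
  edges <- edges[edges + L - 1L <= length(x)]
  if (!is.null(keep_epochs) && length(edges)) {
    es <- 30L * stim$fs
    edges <- edges[((edges - 1L) %/% es) %in% keep_epochs]
  }
  if (length(edges) == 0) {
    warning("no stimulus-locked segments (no visible stimulation and no ",
            "mask-on interval)")
    return(structure(list(segments = matrix(numeric(), 0, L),
                          epoch_index = integer(), fs = stim$fs,
                          n_rejected = 0L), class = "segment_set"))
  }
  idx <- rep(edges, each = L) + rep.int(seq_len(L) - 1L, length(edges))
  segs <- matrix(x[idx], nrow = length(edges), ncol = L, byrow = TRUE)
  structure(list(segments = segs,
                 epoch_index = as.integer((edges - 1L) %/% (30L * stim$fs)),
                 fs = stim$fs, n_rejected = 0L),
            class = "segment_set")
}

#' @export
print.segment_set <- function(x, ...) {
  cat("<segment_set> ", nrow(x$segments), " segments x ", ncol(x$segments),
      " samples (", 1000 * ncol(x$segments) / x$fs, " ms); rejected earlier: ",
      x$n_rejected, "\n", sep = "")
  invisible(x)
}

#' Reject high-amplitude segments
#'
#' A segment is kept if and only if its signal range (max - min) does not
#' exceed `limit` uV; the boundary is read strictly, so a segment spanning
#' exactly `limit` survives.
#'
#' @param ss A `segment_set`.
#' @param limit Peak-to-trough limit in uV. Default 100.
#' @return The filtered `segment_set` (`n_rejected` incremented).
#' @export
reject_segments <- function(ss, limit = 100) {
  stopifnot(inherits(ss, "segment_set"))
  if (nrow(ss$segments) == 0) stop("empty segment set")
  rng <- matrixStats_range(ss$segments)
  keep <- rng <= limit
  ss$n_rejected <- ss$n_rejected + sum(!keep)
  ss$segments <- ss$segments[keep, , drop = FALSE]
  ss$epoch_index <- ss$epoch_index[keep]
  ss
}

# Row-wise max - min without apply() overhead.
matrixStats_range <- function(m) {
  mx <- m[, 1]; mn <- m[, 1]
  for (j in seq_len(ncol(m))[-1]) {
    mx <- pmax(mx, m[, j]); mn <- pmin(mn, m[, j])
  }
  mx - mn
}

#' Average stimulus-locked segments into an SSVEP
#'
#' The grand-average waveform is the per-sample mean across segments; the
#' SSVEP amplitude is its peak-to-trough range (no fitting, no smoothing).
#'
#' @param ss A `segment_set` with at least one segment.
#' @param condition,stage Optional labels stored in the result.
#' @return Object of class `ssvep_result`: `waveform` (uV), `ssvep_amp`
#'   (uV peak-to-trough), `snr` (NA until [shuffle_snr()] fills it),
#'   `n_segments`, `fs`.
#' @export
average_ssvep <- function(ss, condition = NULL, stage = NULL) {
  stopifnot(inherits(ss, "segment_set"))
  if (nrow(ss$segments) == 0)
    stop("no segments left after rejection; cannot average")
  w <- colMeans(ss$segments)
  structure(list(waveform = w, ssvep_amp = max(w) - min(w), snr = NA_real_,
                 n_segments = nrow(ss$segments), fs = ss$fs,
                 condition = condition, stage = stage),
            class = "ssvep_result")
}

#' @export
print.ssvep_result <- function(x, ...) {
  lab <- if (!is.null(x$condition)) paste0(x$condition, "/", x$stage, ": ")
         else ""
  cat("<ssvep_result> ", lab, "amplitude ", signif(x$ssvep_amp, 3),
      " uV over ", x$n_segments, " segments; shuffle SNR ",
      if (is.na(x$snr)) "not computed" else signif(x$snr, 3), "\n", sep = "")
  invisible(x)
}

#' @export
plot.ssvep_result <- function(x, ...) {
  t_ms <- (seq_along(x$waveform) - 1) / x$fs * 1000
  graphics::plot(t_ms, x$waveform, type = "l", xlab = "Time (ms)",
                 ylab = "Amplitude (uV)", ...)
  invisible(x)
}

#' Shuffled-segment permutation SNR
#'
#' Null construction for the SSVEP amplitude: for each repeat, the sample
#' order is permuted independently within every segment (fresh permutations
#' per repeat), segments are averaged into a "random" SSVEP and its
#' peak-to-trough amplitude recorded; the SNR is the true amplitude divided
#' by the mean of the `n_repeats` (default 100) random amplitudes. Values
#' near 1 indicate no temporal structure locked to the stimulus.
#'
#' @param ss A `segment_set` with at least 2 segments.
#' @param n_repeats Number of shuffle repeats. Default 100.
#' @param seed Optional integer seed for reproducibility.
#' @return The SNR (numeric scalar) with attributes `true_amp` and
#'   `null_amps`.
#' @export
shuffle_snr <- function(ss, n_repeats = 100, seed = NULL) {
  stopifnot(inherits(ss, "segment_set"))
  if (nrow(ss$segments) < 2) stop("need at least 2 segments")
  if (n_repeats < 1) stop("n_repeats must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  true_amp <- average_ssvep(ss)$ssvep_amp
  null_amps <- shuffle_null_amps_cpp(ss$segments, as.integer(n_repeats))
  m <- mean(null_amps)
  if (m == 0)
    stop("degenerate null: all segments constant, random amplitudes are 0")
  structure(true_amp / m, true_amp = true_amp, null_amps = null_amps)
}

# Reference implementation of the shuffle null in plain R (used as an
# independent check of the compiled kernel on small inputs).
shuffle_null_amps_r <- function(segs, n_repeats) {
  n <- nrow(segs); L <- ncol(segs)
  vapply(seq_len(n_repeats), function(r) {
    perm <- t(vapply(seq_len(n),
                     function(i) segs[i, sample.int(L)], numeric(L)))
    w <- colMeans(perm)
    max(w) - min(w)
  }, numeric(1))
}

#' Linearly interpolate over LED edges
#'
#' Replaces the samples within +/- `window`/2 of every LED on/off edge by a
#' linear ramp between the samples bounding the window, removing any
#' electrical LED transient. The supplementary control for the analysis:
#' applied to the experimental condition it should leave the SSVEP amplitude
#' essentially unchanged, while in an artifact-carrying control recording it
#' flattens the stimulus-locked average.
#'
#' @param x Numeric signal vector.
#' @param stim A `stim_log` aligned to `x`.
#' @param window Total interpolation window per edge in seconds; must be
#'   shorter than half a flicker cycle (12.5 ms). Default 0.002.
#' @return The interpolated signal.
#' @export
interpolate_led_artifact <- function(x, stim, window = 0.002) {
  stopifnot(inherits(stim, "stim_log"))
  fs <- stim$fs
  if (window >= (stim$period / 2) / fs)
    stop("interpolation window (", window * 1000,
         " ms) must be below half a flicker cycle (",
         500 * stim$period / fs, " ms); windows would overlap")
  edges <- led_edges(stim, "both", "active")
  hw <- max(1L, as.integer(round(window / 2 * fs)))
  edges <- edges[edges - hw - 1L >= 1L & edges + hw + 1L <= length(x)]
  if (length(edges) == 0) return(x)
  b0 <- x[edges - hw - 1L]
  b1 <- x[edges + hw + 1L]
  k <- 2L * hw + 1L
  for (o in seq_len(k)) {
    frac <- o / (k + 1)
    x[edges - hw - 1L + o] <- b0 + (b1 - b0) * frac
  }
  x
}

#' SSVEP amplitude and shuffle SNR for one condition x stage bin
#'
#' Convenience wrapper: segment, reject (> 100 uV), average, permutation SNR.
#'
#' @param x ROI signal vector.
#' @param stim `stim_log` aligned to `x`.
#' @param keep_epochs 0-based epoch indices surviving bad-trial rejection.
#' @param condition,stage Labels for the result.
#' @param n_repeats,seed Passed to [shuffle_snr()].
#' @return An `ssvep_result` with `snr` filled in, or NULL when the bin has
#'   no segments.
#' @export
bin_ssvep <- function(x, stim, keep_epochs, condition, stage,
                      n_repeats = 100, seed = NULL) {
  ss <- suppressWarnings(segment_at_led_on(x, stim, keep_epochs))
  if (nrow(ss$segments) == 0) return(NULL)
  ss <- reject_segments(ss)
  if (nrow(ss$segments) == 0) return(NULL)
  res <- average_ssvep(ss, condition, stage)
  res$snr <- as.numeric(shuffle_snr(ss, n_repeats, seed))
  res
}
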