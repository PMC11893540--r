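#' Hamming-window periodogram of one epoch
#'
#' Single-taper Hamming periodogram with density scaling. Power is expressed
#' in dB relative to 1 V^2/Hz, the signal being converted from uV to V
#' before the logarithm, so typical sleep-EEG values near 40 Hz land around
#' -130 dB. A 30 s epoch yields a frequency grid of 1/30 Hz spacing, which
#' contains a bin at exactly 40 Hz. Bins with zero linear power are floored
#' at `db_floor`.
#'
#' @param x Numeric vector, one epoch of a single channel in uV.
#' @param fs Sampling rate in Hz.
#' @param expected_seconds Optional required epoch duration; an error is
#'   thrown when `length(x) != expected_seconds * fs`. The condition x stage
#'   pipeline passes 30.
#' @param db_floor Value substituted for -Inf dB (default -400).
#' @return Object of class `spectrum40`: `frequencies` (Hz), `power_db`,
#'   `n_epochs_averaged`, `df` (grid spacing).
#' @export
epoch_psd <- function(x, fs, expected_seconds = NULL, db_floor = -400) {
  if (!is.null(expected_seconds) &&
      length(x) != as.integer(round(expected_seconds * fs)))
    stop("epoch has ", length(x), " samples; expected ",
         expected_seconds * fs)
  n <- length(x)
  if (n < 2) stop("epoch too short")
  w <- signal::hamming(n)
  X <- fft(x * w)
  nb <- n %/% 2 + 1L                  # one-sided bins 0 .. floor(n/2)
  p <- (Mod(X[seq_len(nb)])^2) / (fs * sum(w^2))
  if (n %% 2 == 0) {
    p[2:(nb - 1L)] <- 2 * p[2:(nb - 1L)]
  } else {
    p[2:nb] <- 2 * p[2:nb]
  }
  freqs <- (seq_len(nb) - 1L) * fs / n
  zero <- p <= 0
  db <- rep(db_floor, nb)
  db[!zero] <- 10 * log10(p[!zero] * 1e-12)  # uV^2/Hz -> V^2/Hz
  db <- pmax(db, db_floor)
  if (any(zero))
    message("epoch_psd: ", sum(zero), " zero-power bin(s) floored at ",
            db_floor, " dB")
  structure(list(frequencies = freqs, power_db = db,
                 n_epochs_averaged = 1L, df = fs / n),
            class = "spectrum40")
}

#' @export
print.spectrum40 <- function(x, ...) {
  cat("<spectrum40> ", length(x$frequencies), " bins, df = ",
      signif(x$df, 4), " Hz, average of ", x$n_epochs_averaged,
      " epoch(s)\n", sep = "")
  invisible(x)
}

#' @export
plot.spectrum40 <- function(x, xlim = c(0, 60), ...) {
  sel <- x$frequencies >= xlim[1] & x$frequencies <= xlim[2]
  graphics::plot(x$frequencies[sel], x$power_db[sel], type = "l",
                 xlab = "Frequency (Hz)", ylab = "Power (dB re 1 V²/Hz)",
                 ...)
  graphics::abline(v = 40, col = "red", lty = 2)
  invisible(x)
}

#' Average spectra across epochs
#'
#' The mean is taken on the linear power scale (averaging dB values would
#' bias the estimate low) and converted back to dB.
#'
#' @param spectra List of `spectrum40` objects on identical frequency grids.
#' @param db_floor Floor for zero-power bins.
#' @return A `spectrum40` with `n_epochs_averaged` summed.
#' @export
average_psd <- function(spectra, db_floor = -400) {
  if (length(spectra) < 1) stop("need at least one spectrum")
  f0 <- spectra[[1]]$frequencies
  for (s in spectra)
    if (length(s$frequencies) != length(f0) ||
        any(abs(s$frequencies - f0) > 1e-9))
      stop("spectra are on different frequency grids")
  lin <- vapply(spectra, function(s) 10^(s$power_db / 10), numeric(length(f0)))
  m <- rowMeans(matrix(lin, nrow = length(f0)))
  db <- ifelse(m > 0, 10 * log10(m), db_floor)
  structure(list(frequencies = f0, power_db = pmax(db, db_floor),
                 n_epochs_averaged = sum(vapply(spectra, function(s)
                   s$n_epochs_averaged, 0L)),
                 df = spectra[[1]]$df),
            class = "spectrum40")
}

#' Extract the 40 Hz power (PSD40)
#'
#' Returns the dB value of the bin whose frequency equals `freq` exactly;
#' never interpolates.
#'
#' @param spec A `spectrum40`.
#' @param freq Target frequency, default 40 Hz.
#' @return Power in dB at the target bin.
#' @export
extract_psd40 <- function(spec, freq = 40) {
  stopifnot(inherits(spec, "spectrum40"))
  i <- which(abs(spec$frequencies - freq) < 1e-6)
  if (length(i) != 1)
    stop("frequency grid has no bin at exactly ", freq,
         " Hz (spacing ", signif(spec$df, 6), " Hz); refusing to interpolate")
  spec$power_db[i]
}

#' Neighbour-band signal-to-noise ratio of the 40 Hz bin
#'
#' Ratio of the linear power at 40 Hz to the mean linear power over the
#' flanking bands \[38, 39.5\] and \[40.5, 42\] Hz (bounds inclusive). This
#' corrects for the individual 1/f shape of the spectrum; a value near 1
#' means 40 Hz activity is indistinguishable from its neighbours. The ratio
#' is formed on the linear power scale: a quotient of (negative) dB values
#' would invert that interpretation.
#'
#' @param spec A `spectrum40` covering 38-42 Hz.
#' @param freq Centre frequency (default 40 Hz).
#' @param bands Two-sided flanking bands as a 2x2 matrix of bounds; default
#'   `rbind(c(38, 39.5), c(40.5, 42))`.
#' @return SNR as a unitless ratio.
#' @export
psd_snr <- function(spec, freq = 40, bands = rbind(c(38, 39.5), c(40.5, 42))) {
  stopifnot(inherits(spec, "spectrum40"))
  p40 <- 10^(extract_psd40(spec, freq) / 10)
  f <- spec$frequencies
  tol <- 1e-9
  sel <- rep(FALSE, length(f))
  for (b in seq_len(nrow(bands)))
    sel <- sel | (f >= bands[b, 1] - tol & f <= bands[b, 2] + tol)
  if (!any(sel)) stop("no frequency bins inside the neighbour bands")
  p_neigh <- mean(10^(spec$power_db[sel] / 10))
  p40 / p_neigh
}

#' PSD40 and neighbour-band SNR for one condition x stage bin
#'
#' Computes the Hamming periodogram of every surviving epoch, averages on the
#' linear scale, and extracts the 40 Hz power and its neighbour-band SNR.
#'
#' @param es An `epoch_set` (rejected epochs are skipped).
#' @param condition,stage Labels stored in the result (defaults taken from
#'   the epoch metadata).
#' @return Object of class `psd40_result` with fields `psd40` (dB), `snr`,
#'   `condition`, `stage`, `n_epochs`, `spectrum`.
#' @export
bin_psd40 <- function(es, condition = NULL, stage = NULL) {
  stopifnot(inherits(es, "epoch_set"))
  keep <- which(!es$meta$rejected)
  if (length(keep) == 0) stop("no surviving epochs in bin")
  spectra <- lapply(keep, function(i)
    epoch_psd(es$signal[i, ], es$fs, expected_seconds = 30))
  avg <- average_psd(spectra)
  structure(list(psd40 = extract_psd40(avg), snr = psd_snr(avg),
                 condition = condition %||% es$meta$condition[keep[1]],
                 stage = stage %||% es$meta$stage[keep[1]],
                 n_epochs = length(keep), spectrum = avg),
            class = "psd40_result")
}

#' @export
print.psd40_result <- function(x, ...) {
  cat("<psd40_result> ", x$condition, "/", x$stage, ": PSD40 = ",
      round(x$psd40, 2), " dB, SNR = ", round(x$snr, 2), " (",
      x$n_epochs, " epochs)\n", sep = "")
  invisible(x)
}
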