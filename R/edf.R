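#' Write a recording to an EDF file
#'
#' Plain EDF (16-bit), one-second data records, physical units uV. The
#' physical min/max encoded in the 8-character EDF header fields are used for
#' the digitization itself, so a write/read round trip is exact up to one
#' 16-bit quantization step.
#'
#' @param rec A [recording()]. Its duration must be an integer number of
#'   seconds.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  fs <- rec$sampling_rate
  n <- ncol(rec$samples)
  if (fs != round(fs)) stop("EDF writer requires an integer sampling rate")
  if (n %% fs != 0)
    stop("recording duration must be an integer number of seconds")
  ndr <- n %/% fs
  ns <- nrow(rec$samples)

  pad <- function(x, w) formatC(substr(as.character(x), 1, w), width = -w)
  num8 <- function(x) pad(formatC(x, digits = 7, width = 8, format = "g"), 8)

  pmin_raw <- apply(rec$samples, 1, min)
  pmax_raw <- apply(rec$samples, 1, max)
  flat <- pmax_raw - pmin_raw < 1e-9
  pmin_raw[flat] <- pmin_raw[flat] - 1
  pmax_raw[flat] <- pmax_raw[flat] + 1
  # round-trip through the 8-char ASCII fields so scaling matches the header
  pmin <- as.numeric(num8(pmin_raw)); pmax <- as.numeric(num8(pmax_raw))
  pmin <- pmin(pmin, pmin_raw); pmax <- pmax(pmax, pmax_raw)
  pmin <- as.numeric(num8(pmin)); pmax <- as.numeric(num8(pmax))
  dmin <- -32768L; dmax <- 32767L

  con <- file(path, "wb"); on.exit(close(con))
  wr <- function(s) writeChar(s, con, nchars = nchar(s), eos = NULL)
  wr(pad("0", 8)); wr(pad("synthetic", 80)); wr(pad("gammaflick", 80))
  wr(pad("01.01.00", 8)); wr(pad("00.00.00", 8))
  wr(pad(256L * (ns + 1L), 8)); wr(pad("", 44))
  wr(pad(ndr, 8)); wr(pad(1L, 8)); wr(pad(ns, 4))
  for (lab in rec$channel_labels) wr(pad(lab, 16))
  for (i in seq_len(ns)) wr(pad("", 80))
  for (i in seq_len(ns)) wr(pad("uV", 8))
  for (i in seq_len(ns)) wr(num8(pmin[i]))
  for (i in seq_len(ns)) wr(num8(pmax[i]))
  for (i in seq_len(ns)) wr(pad(dmin, 8))
  for (i in seq_len(ns)) wr(pad(dmax, 8))
  for (i in seq_len(ns)) wr(pad("", 80))
  for (i in seq_len(ns)) wr(pad(fs, 8))
  for (i in seq_len(ns)) wr(pad("", 32))

  scale <- (dmax - dmin) / (pmax - pmin)
  for (r in seq_len(ndr)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    block <- matrix(0L, nrow = fs, ncol = ns)
    for (i in seq_len(ns)) {
      d <- as.integer(round((rec$samples[i, idx] - pmin[i]) * scale[i]) + dmin)
      block[, i] <- pmin(pmax(d, dmin), dmax)
    }
    writeBin(as.integer(block), con, size = 2L, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file into a recording
#'
#' @param path Path to an EDF file.
#' @return A [recording()].
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 256)
    stop("EDF parse error: file too short for a header (", sz, " bytes)")
  con <- file(path, "rb"); on.exit(close(con))
  rd <- function(nch) readChar(con, nch, useBytes = TRUE)
  num <- function(s, field) {
    v <- suppressWarnings(as.numeric(trimws(s)))
    if (is.na(v)) stop("EDF parse error in field '", field, "': '",
                       trimws(s), "'")
    v
  }
  rd(8)                       # version
  rd(80); rd(80); rd(8); rd(8)
  header_bytes <- num(rd(8), "header bytes")
  rd(44)
  ndr <- num(rd(8), "number of data records")
  rec_dur <- num(rd(8), "record duration")
  ns <- as.integer(num(rd(4), "number of signals"))
  if (ns < 1) stop("EDF parse error in field 'number of signals': ", ns)
  if (header_bytes != 256 * (ns + 1))
    stop("EDF parse error in field 'header bytes': expected ",
         256 * (ns + 1), ", got ", header_bytes)
  labels <- trimws(vapply(seq_len(ns), function(i) rd(16), ""))
  if (anyDuplicated(labels))
    stop("EDF parse error: duplicate channel label '",
         labels[duplicated(labels)][1], "'")
  for (i in seq_len(ns)) rd(80)   # transducer
  for (i in seq_len(ns)) rd(8)    # physical dimension
  pmin <- vapply(seq_len(ns), function(i) num(rd(8), "physical minimum"), 0)
  pmax <- vapply(seq_len(ns), function(i) num(rd(8), "physical maximum"), 0)
  dmin <- vapply(seq_len(ns), function(i) num(rd(8), "digital minimum"), 0)
  dmax <- vapply(seq_len(ns), function(i) num(rd(8), "digital maximum"), 0)
  for (i in seq_len(ns)) rd(80)   # prefiltering
  spr <- vapply(seq_len(ns), function(i)
    as.integer(num(rd(8), "samples per record")), 0L)
  for (i in seq_len(ns)) rd(32)
  if (any(pmax <= pmin)) stop("EDF parse error in field 'physical maximum': ",
                              "must exceed physical minimum")
  if (length(unique(spr)) != 1)
    stop("EDF reader supports a single common sampling rate only")
  fs <- spr[1] / rec_dur

  total <- ndr * sum(spr)
  raw <- readBin(con, integer(), n = total, size = 2L, signed = TRUE,
                 endian = "little")
  if (length(raw) < total)
    stop("EDF parse error: truncated data section (expected ", total,
         " samples, found ", length(raw), ")")
  samples <- matrix(0, nrow = ns, ncol = ndr * spr[1])
  scale <- (pmax - pmin) / (dmax - dmin)
  pos <- 0L
  for (r in seq_len(as.integer(ndr))) {
    for (i in seq_len(ns)) {
      d <- raw[(pos + 1L):(pos + spr[i])]
      samples[i, ((r - 1L) * spr[i] + 1L):(r * spr[i])] <-
        (d - dmin[i]) * scale[i] + pmin[i]
      pos <- pos + spr[i]
    }
  }
  recording(samples, fs, labels)
}
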