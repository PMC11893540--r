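#' Build the LED stimulation schedule for a night
#'
#' Implements the closed-loop protocol: stimulation starts at the first N3
#' epoch with a raised-cosine illuminance ramp (default 300 s) toward the
#' target level; any epoch scored W or N1 triggers a 5 s fade-out; the light
#' stays off until the configured number of consecutive epochs (default 6)
#' scored neither W nor N1 have elapsed, and then restarts with a fresh
#' fade-in at the start of the following epoch. The LED itself always toggles
#' at 40 Hz with the configured duty cycle while the circuit is active; fades
#' modulate only the illuminance.
#'
#' Protocol variants: `protocol = "wake"` drives the LEDs from the start of
#' the recording at full illuminance irrespective of the hypnogram (a
#' wakefulness stimulation block); `condition = "control"` keeps the LED
#' circuit running for the whole recording with the LEDs masked, so the
#' electrical 40 Hz clock exists but no light is visible
#' (`visible = 0`, illuminance 0 everywhere).
#'
#' @param hyp A [hypnogram()].
#' @param config A [sim_config()].
#' @return An object of class `stim_log` with fields `fs`, `n_samples`,
#'   `period` (samples per flicker cycle), `duty`, `intervals` (circuit-active
#'   intervals with a `visible` flag; `start` 1-based, `end` exclusive),
#'   `pieces` (piecewise illuminance definition) and `no_n3` (TRUE when a
#'   sleep-protocol night contained no N3, leaving the schedule off).
#' @export
build_stim_schedule <- function(hyp, config) {
  stopifnot(inherits(hyp, "hypnogram"), inherits(config, "sim_config"))
  if (length(hyp) == 0) stop("hypnogram is empty")
  fs <- config$sampling_rate
  n <- length(hyp) * 30L * fs
  period <- as.integer(fs / config$stim_frequency)
  es <- 30L * fs  # samples per epoch

  empty <- data.frame(start = integer(), end = integer(), visible = integer())
  no_pieces <- data.frame(start = integer(), end = integer(),
                          kind = character(), origin = integer(),
                          param = numeric(), level = numeric())
  sl <- structure(list(fs = fs, n_samples = n, period = period,
                       duty = config$duty_cycle, intervals = empty,
                       pieces = no_pieces, no_n3 = FALSE,
                       condition = config$condition), class = "stim_log")

  if (config$condition == "control") {
    sl$intervals <- data.frame(start = 1L, end = n + 1L, visible = 0L)
    return(sl)
  }

  if (config$protocol == "wake") {
    sl$intervals <- data.frame(start = 1L, end = n + 1L, visible = 1L)
    sl$pieces <- data.frame(start = 1L, end = n + 1L, kind = "full",
                            origin = 1L, param = 0, level = 1)
    return(sl)
  }

  ramp <- config$fade_in_duration * fs
  fade <- config$fade_out_duration * fs
  awake <- hyp$stages %in% c("W", "N1")
  first_n3 <- match("N3", hyp$stages)
  if (is.na(first_n3)) {
    sl$no_n3 <- TRUE
    return(sl)
  }

  intervals <- list(); pieces <- list()
  state <- "idle"; ramp_t0 <- NA_integer_; calm <- 0L
  open_run <- function(t0) {  # t0: 1-based start sample of the run
    ramp_t0 <<- t0; state <<- "on"
  }
  close_run <- function(t_a) {
    # arousal at sample t_a (start of the W/N1 epoch): 5 s fade-out
    lvl <- ramp_level(t_a - ramp_t0, ramp)
    f_end <- min(t_a + fade, n + 1L)
    intervals[[length(intervals) + 1L]] <<-
      data.frame(start = ramp_t0, end = f_end, visible = 1L)
    if (t_a > ramp_t0) {
      r_end <- min(ramp_t0 + ramp, t_a)
      if (r_end > ramp_t0)
        pieces[[length(pieces) + 1L]] <<-
          data.frame(start = ramp_t0, end = r_end, kind = "ramp",
                     origin = ramp_t0, param = ramp, level = 1)
      if (t_a > r_end)
        pieces[[length(pieces) + 1L]] <<-
          data.frame(start = r_end, end = t_a, kind = "full",
                     origin = ramp_t0, param = 0, level = 1)
    }
    if (f_end > t_a && fade > 0)
      pieces[[length(pieces) + 1L]] <<-
        data.frame(start = t_a, end = f_end, kind = "fade",
                   origin = t_a, param = fade, level = lvl)
    state <<- "paused"; calm <<- 0L
  }

  for (i in seq_along(hyp$stages)) {
    t0 <- (i - 1L) * es + 1L
    if (state == "idle") {
      if (hyp$stages[i] == "N3") open_run(t0)
    } else if (state == "on") {
      if (awake[i]) close_run(t0)
    } else {  # paused
      if (awake[i]) calm <- 0L
      else {
        calm <- calm + 1L
        if (calm >= config$resume_rule_epochs && i < length(hyp$stages))
          open_run(i * es + 1L)  # start of the following epoch
      }
    }
  }
  if (state == "on") {  # run extends to the end of the recording
    t_end <- n + 1L
    intervals[[length(intervals) + 1L]] <-
      data.frame(start = ramp_t0, end = t_end, visible = 1L)
    r_end <- min(ramp_t0 + ramp, t_end)
    if (r_end > ramp_t0)
      pieces[[length(pieces) + 1L]] <-
        data.frame(start = ramp_t0, end = r_end, kind = "ramp",
                   origin = ramp_t0, param = ramp, level = 1)
    if (t_end > r_end)
      pieces[[length(pieces) + 1L]] <-
        data.frame(start = r_end, end = t_end, kind = "full",
                   origin = ramp_t0, param = 0, level = 1)
  }
  sl$intervals <- do.call(rbind, intervals) %||% empty
  sl$pieces <- do.call(rbind, pieces) %||% no_pieces
  sl
}

# Raised-cosine ramp level after `dt` samples of a ramp lasting `ramp`
# samples (level 1 once the ramp is complete; full level for ramp == 0).
ramp_level <- function(dt, ramp) {
  if (ramp <= 0) return(1)
  dt <- pmin(pmax(dt, 0), ramp)
  0.5 * (1 - cos(pi * dt / ramp))
}

#' Per-sample illuminance fraction of a stimulation schedule
#'
#' @param sl A `stim_log`.
#' @param from,to 1-based sample range (defaults: whole recording).
#' @return Numeric vector of illuminance fractions in \[0, 1\], relative to
#'   the target level.
#' @export
stim_illuminance <- function(sl, from = 1L, to = sl$n_samples) {
  stopifnot(inherits(sl, "stim_log"))
  out <- numeric(to - from + 1L)
  p <- sl$pieces
  if (nrow(p) == 0) return(out)
  for (k in seq_len(nrow(p))) {
    s <- max(p$start[k], from); e <- min(p$end[k] - 1L, to)
    if (s > e) next
    idx <- (s:e) - from + 1L
    dt <- (s:e) - p$origin[k]
    out[idx] <- switch(p$kind[k],
      full = p$level[k],
      ramp = ramp_level(dt, p$param[k]),
      fade = p$level[k] * 0.5 * (1 + cos(pi * pmin(dt, p$param[k]) / p$param[k]))
    )
  }
  out
}

#' LED edge sample indices
#'
#' The LED clock is phase-locked to the recording start: cycle k occupies
#' samples `[k*period, (k+1)*period)` (0-based), the LED switching on at the
#' first sample and off after `duty` of the period. Only cycles lying fully
#' inside a circuit-active interval are returned.
#'
#' @param sl A `stim_log`.
#' @param phase `"on"` for LED-ON edges (cycle starts), `"off"` for LED-OFF
#'   edges, `"both"` for the union.
#' @param within `"active"`: any circuit-active interval (this includes the
#'   control condition's masked LEDs and the fade intervals);
#'   `"visible_full"`: only intervals with visible light at full illuminance
#'   (fade-in and fade-out excluded).
#' @return Sorted integer vector of 1-based sample indices.
#' @export
led_edges <- function(sl, phase = c("on", "off", "both"),
                      within = c("active", "visible_full")) {
  stopifnot(inherits(sl, "stim_log"))
  phase <- match.arg(phase); within <- match.arg(within)
  P <- sl$period
  iv <- if (within == "active") {
    sl$intervals
  } else {
    p <- sl$pieces
    if (nrow(p) == 0 || all(sl$intervals$visible == 0))
      p[0, ] else p[p$kind == "full", ]
  }
  if (is.null(iv) || nrow(iv) == 0) return(integer())
  res <- integer()
  off_shift <- as.integer(round(P * sl$duty))
  for (k in seq_len(nrow(iv))) {
    # first full cycle starting at or after the interval start
    k0 <- ceiling((iv$start[k] - 1L) / P)
    k1 <- floor((iv$end[k] - 1L) / P) - 1L  # last cycle fully inside
    if (k1 < k0) next
    on <- as.integer(k0:k1) * P + 1L
    res <- c(res, switch(phase, on = on, off = on + off_shift,
                         both = c(on, on + off_shift)))
  }
  sort(unique(res))
}

#' @export
print.stim_log <- function(x, ...) {
  vis <- x$intervals[x$intervals$visible == 1, , drop = FALSE]
  cat("<stim_log> ", x$n_samples / x$fs, " s @ ", x$fs, " Hz, ",
      1 / (x$period / x$fs), " Hz flicker\n", sep = "")
  if (x$no_n3) cat("  no N3 epoch: schedule entirely off\n")
  cat("  circuit-active intervals: ", nrow(x$intervals),
      "; visible stimulation: ",
      round(sum((vis$end - vis$start)) / x$fs, 1), " s\n", sep = "")
  invisible(x)
}

#' Write / read a stimulation log CSV
#'
#' One row per LED edge while the circuit is active, with columns
#' `sample_index` (0-based), `led_state` (1 at an ON edge, 0 at an OFF edge),
#' `illuminance_fraction`, `visible`.
#'
#' @param sl A `stim_log`.
#' @param path File path.
#' @return `read_stimlog_csv()` returns a `stim_log` whose illuminance is
#'   piecewise linear between the logged edges; `write_stimlog_csv()` returns
#'   `path` invisibly.
#' @export
write_stimlog_csv <- function(sl, path) {
  stopifnot(inherits(sl, "stim_log"))
  on <- led_edges(sl, "on"); off <- led_edges(sl, "off")
  s <- c(on, off)
  st <- rep(c(1L, 0L), c(length(on), length(off)))
  o <- order(s); s <- s[o]; st <- st[o]
  vis <- integer(length(s))
  for (k in seq_len(nrow(sl$intervals)))
    vis[s >= sl$intervals$start[k] & s < sl$intervals$end[k]] <-
      sl$intervals$visible[k]
  ill <- if (length(s)) stim_illuminance(sl)[s] else numeric()
  df <- data.frame(sample_index = s - 1L, led_state = st,
                   illuminance_fraction = ill, visible = vis)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_stimlog_csv
#' @param fs,n_samples Sampling rate and recording length of the recording
#'   the log belongs to (the CSV itself stores only edge rows).
#' @export
read_stimlog_csv <- function(path, fs, n_samples) {
  df <- read.csv(path)
  need <- c("sample_index", "led_state", "illuminance_fraction", "visible")
  if (!all(need %in% names(df)))
    stop("stim log CSV must have columns ", paste(need, collapse = ", "))
  on <- df$sample_index[df$led_state == 1] + 1L
  if (is.unsorted(df$sample_index, strictly = FALSE))
    df <- df[order(df$sample_index), ]
  period <- if (length(on) > 1) min(diff(sort(unique(on)))) else fs %/% 40L
  # reconstruct active intervals from gaps in the edge sequence
  s <- df$sample_index + 1L
  brk <- which(diff(s) > period)
  starts <- s[c(1L, brk + 1L)]; ends <- s[c(brk, length(s))] + period
  vis <- df$visible[match(starts, s)]
  sl <- structure(list(fs = fs, n_samples = n_samples, period = period,
                       duty = 0.5,
                       intervals = data.frame(start = starts, end = ends,
                                              visible = vis),
                       pieces = data.frame(start = integer(), end = integer(),
                                           kind = character(),
                                           origin = integer(),
                                           param = numeric(),
                                           level = numeric()),
                       no_n3 = length(s) == 0, condition = NA_character_,
                       edge_illuminance = data.frame(
                         sample = s, value = df$illuminance_fraction)),
                  class = "stim_log")
  sl
}
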