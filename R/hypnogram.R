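#' Construct a hypnogram object
#'
#' A hypnogram is the per-30-second-epoch sequence of sleep-stage labels
#' (W, N1, N2, N3, REM) together with the scoring algorithm's certainty for
#' each epoch.
#'
#' @param stages Character vector of stage labels, one per 30 s epoch.
#' @param certainty Numeric vector in \[0, 1\], one value per epoch. Defaults
#'   to 1 for every epoch.
#' @return Object of class `hypnogram`.
#' @export
hypnogram <- function(stages, certainty = rep(1, length(stages))) {
  stages <- as.character(stages)
  if (!all(stages %in% STAGES))
    stop("unknown stage labels: ",
         paste(unique(setdiff(stages, STAGES)), collapse = ", "))
  if (length(certainty) != length(stages))
    stop("certainty must have one value per epoch")
  if (any(certainty < 0 | certainty > 1))
    stop("certainty must lie in [0, 1]")
  structure(list(stages = stages, certainty = as.numeric(certainty),
                 epoch_seconds = 30), class = "hypnogram")
}

#' @export
length.hypnogram <- function(x) length(x$stages)

#' @export
print.hypnogram <- function(x, ...) {
  tab <- table(factor(x$stages, levels = STAGES))
  cat("<hypnogram> ", length(x), " epochs (",
      length(x) / 2, " min): ",
      paste(names(tab), tab, sep = "=", collapse = " "), "\n", sep = "")
  invisible(x)
}

# Default epoch-to-epoch stage transition matrix. First-order Markov dynamics
# whose stationary stage mix approximates a healthy young sleeper
# (roughly N1 8%, N2 53%, N3 17%, REM 22% of total sleep time, TST ~420 of
# 480 min). Rows index the current stage, columns the next.
default_stage_transitions <- function() {
  m <- rbind(
    W   = c(W = 0.820, N1 = 0.165, N2 = 0.015, N3 = 0.000, REM = 0.000),
    N1  = c(W = 0.090, N1 = 0.610, N2 = 0.270, N3 = 0.000, REM = 0.030),
    N2  = c(W = 0.016, N1 = 0.013, N2 = 0.918, N3 = 0.024, REM = 0.029),
    N3  = c(W = 0.017, N1 = 0.000, N2 = 0.056, N3 = 0.927, REM = 0.000),
    REM = c(W = 0.028, N1 = 0.018, N2 = 0.038, N3 = 0.000, REM = 0.916)
  )
  m
}

#' Generate a synthetic hypnogram
#'
#' Draws a first-order Markov stage sequence (one state per 30 s epoch) with
#' per-epoch scoring certainty sampled from a Beta distribution with mode 0.9.
#' By default the chain's stationary mix approximates a healthy young
#' sleeper's night and the draw is repeated (deterministically under the
#' seed) until at least one N3 epoch is present, so that the closed-loop
#' stimulation trigger can fire.
#'
#' @param config A [sim_config()].
#' @return A [hypnogram()].
#' @export
generate_hypnogram <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n_epochs <- config$night_duration %/% 30L
  trans <- config$stage_transitions %||% default_stage_transitions()
  withr_seed <- config$rng_seed
  set.seed(withr_seed)
  for (try in seq_len(1000L)) {
    stages <- character(n_epochs)
    state <- config$start_stage
    for (i in seq_len(n_epochs)) {
      stages[i] <- state
      state <- sample(STAGES, 1L, prob = trans[state, ])
    }
    if (!config$require_n3 || any(stages == "N3")) break
    if (try == 1000L)
      stop("could not generate a hypnogram containing N3 in 1000 attempts; ",
           "check stage_transitions")
  }
  certainty <- rbeta(n_epochs, 10, 2)  # mode (10-1)/(10+2-2) = 0.9
  hypnogram(stages, certainty)
}

#' Write / read a hypnogram CSV
#'
#' Columns: `epoch_index` (0-based), `stage` (W/N1/N2/N3/REM), `certainty`.
#'
#' @param hyp A [hypnogram()].
#' @param path File path.
#' @return `read_hypnogram_csv()` returns a [hypnogram()];
#'   `write_hypnogram_csv()` returns `path` invisibly.
#' @export
write_hypnogram_csv <- function(hyp, path) {
  stopifnot(inherits(hyp, "hypnogram"))
  df <- data.frame(epoch_index = seq_along(hyp$stages) - 1L,
                   stage = hyp$stages, certainty = hyp$certainty)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hypnogram_csv
#' @export
read_hypnogram_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("epoch_index", "stage", "certainty")
  if (!all(need %in% names(df)))
    stop("hypnogram CSV must have columns ", paste(need, collapse = ", "))
  df <- df[order(df$epoch_index), ]
  hypnogram(df$stage, df$certainty)
}
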