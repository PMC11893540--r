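#' Objective sleep-quality summary of a hypnogram
#'
#' All quantities use the 30 s epoch grid (0.5 min per epoch):
#' * TST (total sleep time): minutes scored N1 + N2 + N3 + REM.
#' * WASO (wake after sleep onset): minutes scored W strictly between the
#'   first and the last sleep epoch (wake before sleep onset and after the
#'   final sleep epoch are not counted).
#' * Stage percentages: stage minutes as a percentage of TST.
#' * Sleep-onset latency (SOL): minutes from lights-off to the first
#'   non-W epoch.
#' * REM latency: minutes from sleep onset to the first REM epoch.
#'
#' @param hyp A [hypnogram()].
#' @return Object of class `sleep_summary` with fields `tst`, `waso`,
#'   `stage_pct` (named N1/N2/N3/REM), `rem_latency`, `sol`, `flags`.
#'   For an all-wake night TST and WASO are 0 and latencies are NA with a
#'   flag recorded.
#' @export
summarize_hypnogram <- function(hyp) {
  stopifnot(inherits(hyp, "hypnogram"))
  if (length(hyp) == 0) stop("empty hypnogram")
  st <- hyp$stages
  sleep <- st != "W"
  epoch_min <- 0.5
  flags <- character()
  if (!any(sleep)) {
    return(structure(list(
      tst = 0, waso = 0,
      stage_pct = c(N1 = NA_real_, N2 = NA_real_, N3 = NA_real_,
                    REM = NA_real_),
      rem_latency = NA_real_, sol = NA_real_,
      flags = "no_sleep"), class = "sleep_summary"))
  }
  first_sleep <- which(sleep)[1]
  last_sleep <- tail(which(sleep), 1)
  tst <- sum(sleep) * epoch_min
  within_span <- seq(first_sleep, last_sleep)
  waso <- sum(st[within_span] == "W") * epoch_min
  stage_min <- vapply(c("N1", "N2", "N3", "REM"),
                      function(s) sum(st == s) * epoch_min, 0)
  stage_pct <- 100 * stage_min / tst
  sol <- (first_sleep - 1) * epoch_min
  first_rem <- match("REM", st)
  rem_latency <- if (is.na(first_rem)) {
    flags <- c(flags, "no_rem")
    NA_real_
  } else (first_rem - first_sleep) * epoch_min
  structure(list(tst = tst, waso = waso, stage_pct = stage_pct,
                 rem_latency = rem_latency, sol = sol,
                 flags = if (length(flags)) flags else character()),
            class = "sleep_summary")
}

#' @export
print.sleep_summary <- function(x, ...) {
  cat("<sleep_summary> TST ", x$tst, " min, WASO ", x$waso,
      " min, SOL ", x$sol, " min, REM latency ",
      ifelse(is.na(x$rem_latency), "NA", x$rem_latency), " min\n", sep = "")
  cat("  % of TST:",
      paste(names(x$stage_pct), round(x$stage_pct, 1), sep = "=",
            collapse = " "), "\n")
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Sum score of the Groningen Sleep Quality Scale
#'
#' Takes the 14 item responses already keyed in the poor-sleep direction
#' (1 = response indicating poor sleep, 0 = good sleep) and returns their
#' sum, from 0 (perfect sleep quality) to 14 (poor sleep quality). Items are
#' stored pre-keyed so the instrument's item text is not embedded.
#'
#' @param items Integer/logical vector of exactly 14 keyed binary responses.
#' @return Object of class `gsqs_score` (integer sum with an `n_items`
#'   attribute).
#' @export
gsqs_sum <- function(items) {
  if (length(items) != 14)
    stop("GSQS has exactly 14 items; got ", length(items))
  miss <- which(is.na(items))
  if (length(miss))
    stop("missing GSQS item(s): ", paste(miss, collapse = ", "))
  items <- as.integer(items)
  if (!all(items %in% c(0L, 1L)))
    stop("GSQS items must be keyed binary (0/1)")
  structure(sum(items), n_items = 14L, class = "gsqs_score")
}

#' @export
print.gsqs_score <- function(x, ...) {
  cat("<gsqs_score> ", unclass(x), " / 14 (0 = perfect sleep quality)\n",
      sep = "")
  invisible(x)
}

#' Write one-night sleep summaries to CSV
#'
#' @param summaries Named list of `sleep_summary` objects (names become the
#'   `night` column).
#' @param gsqs Optional named numeric vector of GSQS sums for the same
#'   nights.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sleep_summary_csv <- function(summaries, path, gsqs = NULL) {
  rows <- lapply(names(summaries), function(nm) {
    s <- summaries[[nm]]
    data.frame(night = nm, tst_min = s$tst, waso_min = s$waso,
               pct_n1 = s$stage_pct[["N1"]], pct_n2 = s$stage_pct[["N2"]],
               pct_n3 = s$stage_pct[["N3"]], pct_rem = s$stage_pct[["REM"]],
               rem_latency_min = s$rem_latency, sol_min = s$sol,
               gsqs = if (!is.null(gsqs) && nm %in% names(gsqs))
                 as.numeric(gsqs[[nm]]) else NA_real_)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
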