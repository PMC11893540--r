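#' Default run configuration (frozen analysis profile)
#'
#' Returns the full configuration for [run_pipeline()]. Every analysis
#' threshold defaults to the protocol value: 1 mV epoch peak-to-peak limit,
#' 50% scoring-certainty floor, 25 s minimum stimulation per experimental
#' epoch, 100 uV segment rejection, 100 shuffle repeats, neighbour bands
#' [38, 39.5] and [40.5, 42] Hz. Simulation sizes default to a desk-scale
#' study (6 subjects, 2 h nights at 400 Hz) so a full run completes in
#' minutes; the generator's signal parameters are the [sim_config()]
#' defaults.
#'
#' @param seed Master seed; every random draw of the run derives from it.
#' @return A list of class `run_config`.
#' @export
default_run_config <- function(seed = 1) {
  structure(list(
    seed = as.integer(seed),
    n_subjects = 6L,
    sampling_rate = 400L,
    session_durations = list(s1 = 1200L, s2 = 7200L, s3 = 7200L),
    conditions = c("control", "experimental"),
    sim = list(),   # overrides forwarded to sim_config()
    analysis = list(
      bandpass = c(0.16, 300),
      p2p_limit_uv = 1000,
      min_certainty = 0.5,
      min_stim_seconds = 25,
      segment_p2p_limit_uv = 100,
      shuffle_repeats = 100L,
      snr_bands = rbind(c(38, 39.5), c(40.5, 42))
    ),
    gsqs_item_prob = c(control = 4.57 / 14, experimental = 2.73 / 14),
    out_dir = NULL,
    cache_dir = NULL
  ), class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file path.
#' @param config A `run_config`.
#' @return `read_run_config()` returns a `run_config` (unspecified fields
#'   fall back to [default_run_config()] values).
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- default_run_config(y$seed %||% 1)
  for (nm in intersect(names(y), names(cfg))) {
    if (nm == "analysis") {
      for (an in intersect(names(y$analysis), names(cfg$analysis)))
        cfg$analysis[[an]] <- y$analysis[[an]]
    } else cfg[[nm]] <- y[[nm]]
  }
  if (is.matrix(cfg$analysis$snr_bands) ||
      is.list(cfg$analysis$snr_bands))
    cfg$analysis$snr_bands <- matrix(unlist(cfg$analysis$snr_bands),
                                     ncol = 2, byrow = TRUE)
  cfg$session_durations <- lapply(cfg$session_durations, as.integer)
  cfg
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  y <- unclass(config)
  y$analysis$snr_bands <- lapply(seq_len(nrow(y$analysis$snr_bands)),
                                 function(i) y$analysis$snr_bands[i, ])
  yaml::write_yaml(y, path)
  invisible(path)
}

# Stable content hash (md5 of the serialized object).
config_hash <- function(obj) {
  tf <- tempfile(); on.exit(unlink(tf))
  writeBin(serialize(obj, NULL, version = 3), tf)
  unname(tools::md5sum(tf))
}

#' Preprocess one night to labelled epochs and the ROI signal
#'
#' Chains band-pass filtering, bad-channel rejection, ROI averaging with
#' mastoid re-referencing, epoching and spectral-context bad-trial
#' rejection.
#'
#' @param rec A [recording()].
#' @param hyp The matching [hypnogram()].
#' @param stim The matching `stim_log` (or NULL).
#' @param condition,session Labels for the epoch metadata.
#' @param analysis Analysis parameter list (see [default_run_config()]).
#' @return List with `epochs` (spectral-rejected `epoch_set`), `roi`
#'   (numeric ROI signal), `ssvep_keep` (0-based epoch indices passing the
#'   ssvep-context rejection), `rejected_channels`.
#' @export
preprocess_night <- function(rec, hyp, stim, condition, session,
                             analysis = default_run_config()$analysis) {
  filt <- suppressWarnings(
    bandpass_filter(rec, analysis$bandpass[1], analysis$bandpass[2]))
  chk <- reject_bad_channels(filt)
  roi <- roi_average_and_rereference(chk$recording)
  es <- epoch_and_label(roi, hyp, stim, condition, session)
  es_spec <- reject_epochs(es, "spectral",
                           p2p_limit = analysis$p2p_limit_uv,
                           min_certainty = analysis$min_certainty,
                           min_stim_seconds = analysis$min_stim_seconds)
  es_ssvep <- reject_epochs(es, "ssvep",
                            p2p_limit = analysis$p2p_limit_uv,
                            min_certainty = analysis$min_certainty)
  list(epochs = es_spec, roi = as.numeric(roi$samples[1, ]),
       ssvep_keep = es_ssvep$meta$epoch_index[!es_ssvep$meta$rejected],
       rejected_channels = chk$rejected)
}

simulate_subject_sessions <- function(cfg, subject) {
  fs <- cfg$sampling_rate
  base <- cfg$seed * 1000L + subject * 10L
  sim_args <- cfg$sim
  make_cfg <- function(duration, condition, protocol, seed) {
    do.call(sim_config, c(list(sampling_rate = fs, night_duration = duration,
                               condition = condition, protocol = protocol,
                               rng_seed = seed), sim_args))
  }
  sessions <- list()
  if ("experimental" %in% cfg$conditions) {
    c1 <- make_cfg(cfg$session_durations$s1, "experimental", "wake",
                   base + 1L)
    n_ep <- cfg$session_durations$s1 %/% 30L
    sessions[["1"]] <- render_night(c1, hyp = hypnogram(rep("W", n_ep)))
  }
  if ("control" %in% cfg$conditions)
    sessions[["2"]] <- render_night(
      make_cfg(cfg$session_durations$s2, "control", "sleep", base + 2L))
  if ("experimental" %in% cfg$conditions)
    sessions[["3"]] <- render_night(
      make_cfg(cfg$session_durations$s3, "experimental", "sleep", base + 3L))
  sessions
}

analyze_subject <- function(cfg, subject, sessions) {
  an <- cfg$analysis
  pre <- lapply(names(sessions), function(sid) {
    s <- sessions[[sid]]
    preprocess_night(s$recording, s$hypnogram, s$stim_log,
                     s$ground_truth$condition, as.integer(sid), an)
  })
  names(pre) <- names(sessions)
  bins <- assign_condition_bins(lapply(pre, `[[`, "epochs"))

  session_for_bin <- function(condition, stage) {
    if (condition == "control") "2" else if (stage == "W") "1" else "3"
  }
  rows <- list(); waves <- list()
  bin_i <- 0L
  for (condition in names(bins)) {
    for (stage in names(bins[[condition]])) {
      bin_i <- bin_i + 1L
      es <- bins[[condition]][[stage]]
      sid <- session_for_bin(condition, stage)
      if (is.null(pre[[sid]]) || nrow(es$meta) == 0) next
      spec <- tryCatch(bin_psd40(es, condition, stage),
                       error = function(e) NULL)
      keep_spec <- es$meta$epoch_index[!es$meta$rejected]
      keep_ssvep <- intersect(pre[[sid]]$ssvep_keep,
                              es$meta$epoch_index)
      sv <- bin_ssvep(pre[[sid]]$roi, sessions[[sid]]$stim_log, keep_ssvep,
                      condition, stage, n_repeats = an$shuffle_repeats,
                      seed = cfg$seed * 100L + subject * 10L + bin_i)
      rows[[length(rows) + 1L]] <- data.frame(
        subject = subject, condition = condition, stage = stage,
        n_epochs = if (is.null(spec)) 0L else spec$n_epochs,
        psd40_db = if (is.null(spec)) NA_real_ else spec$psd40,
        psd_snr = if (is.null(spec)) NA_real_ else spec$snr,
        n_segments = if (is.null(sv)) 0L else sv$n_segments,
        ssvep_amp_uv = if (is.null(sv)) NA_real_ else sv$ssvep_amp,
        ssvep_snr = if (is.null(sv)) NA_real_ else sv$snr)
      if (!is.null(sv))
        waves[[length(waves) + 1L]] <- data.frame(
          subject = subject, condition = condition, stage = stage,
          sample_index = seq_along(sv$waveform) - 1L,
          time_ms = (seq_along(sv$waveform) - 1) / sv$fs * 1000,
          mean_uv = sv$waveform)
    }
  }

  sleep_rows <- list()
  for (sid in intersect(c("2", "3"), names(sessions))) {
    cond <- sessions[[sid]]$ground_truth$condition
    ss <- summarize_hypnogram(sessions[[sid]]$hypnogram)
    set.seed(cfg$seed * 1000L + subject * 10L + as.integer(sid) + 100L)
    g <- gsqs_sum(rbinom(14, 1, cfg$gsqs_item_prob[[cond]]))
    sleep_rows[[sid]] <- data.frame(
      subject = subject, condition = cond, tst_min = ss$tst,
      waso_min = ss$waso, sol_min = ss$sol,
      rem_latency_min = ss$rem_latency,
      pct_n1 = ss$stage_pct[["N1"]], pct_n2 = ss$stage_pct[["N2"]],
      pct_n3 = ss$stage_pct[["N3"]], pct_rem = ss$stage_pct[["REM"]],
      gsqs = as.integer(g))
  }
  list(results = do.call(rbind, rows),
       waveforms = do.call(rbind, waves),
       sleep = do.call(rbind, unname(sleep_rows)))
}

#' Run the complete simulate -> analyse -> test pipeline
#'
#' For each synthetic subject, renders the study's sessions (wakefulness
#' stimulation block, control night with masked LEDs, experimental night
#' with the closed-loop schedule), preprocesses them, computes the
#' condition x stage PSD40 / neighbour-band SNR and SSVEP amplitude /
#' shuffle SNR, summarizes sleep, and finally runs the hypothesis battery:
#' one-tailed paired comparisons of experimental vs control per stage for
#' 40 Hz power (H1-H4) and SSVEP amplitude (H1b-H4b, Bonferroni-Holm within
#' each family), stage multilevel comparisons in the experimental condition
#' (H5, H5b), and two-tailed paired comparisons of GSQS, TST and WASO
#' (H6-H8). Entirely deterministic under `config$seed`. With a control-only
#' configuration the statistics stage is skipped with a logged reason.
#'
#' @param config A `run_config` from [default_run_config()] or
#'   [read_run_config()].
#' @return A `results_bundle`: `spectral_ssvep` (per subject x condition x
#'   stage table), `waveforms`, `sleep`, `stats` (per-hypothesis table or
#'   NULL), `stats_objects`, `manifest`, `config`.
#' @export
run_pipeline <- function(config = default_run_config()) {
  stopifnot(inherits(config, "run_config"))
  per_subject <- vector("list", config$n_subjects)
  for (subj in seq_len(config$n_subjects)) {
    runner <- function() {
      sessions <- simulate_subject_sessions(config, subj)
      analyze_subject(config, subj, sessions)
    }
    per_subject[[subj]] <- if (!is.null(config$cache_dir)) {
      dir.create(config$cache_dir, showWarnings = FALSE, recursive = TRUE)
      key <- config_hash(list(config[setdiff(names(config),
                                             c("out_dir", "cache_dir"))],
                              subj))
      cache_file <- file.path(config$cache_dir,
                              paste0("subject-", subj, "-", key, ".rds"))
      if (file.exists(cache_file)) readRDS(cache_file)
      else { r <- runner(); saveRDS(r, cache_file); r }
    } else runner()
    message("subject ", subj, ": ",
            sum(per_subject[[subj]]$results$n_epochs), " epochs, ",
            sum(per_subject[[subj]]$results$n_segments), " segments")
  }
  results <- do.call(rbind, lapply(per_subject, `[[`, "results"))
  waveforms <- do.call(rbind, lapply(per_subject, `[[`, "waveforms"))
  sleep <- do.call(rbind, lapply(per_subject, `[[`, "sleep"))

  stats_out <- NULL; stats_objects <- NULL; skip_reason <- NULL
  if (!all(c("control", "experimental") %in% config$conditions)) {
    skip_reason <- paste("statistics stage skipped: both conditions are",
                         "required for the paired hypotheses, got",
                         paste(config$conditions, collapse = "/"))
    message(skip_reason)
  } else {
    st <- hypothesis_battery(results, sleep)
    stats_out <- st$table; stats_objects <- st$objects
  }

  manifest <- list(
    config_hash = config_hash(config[setdiff(names(config),
                                             c("out_dir", "cache_dir"))]),
    seed = config$seed,
    n_subjects = config$n_subjects,
    package_version = as.character(utils::packageVersion("gammaflick")),
    r_version = R.version.string)

  bundle <- structure(list(spectral_ssvep = results, waveforms = waveforms,
                           sleep = sleep, stats = stats_out,
                           stats_objects = stats_objects,
                           stats_skipped_reason = skip_reason,
                           manifest = manifest, config = config),
                      class = "results_bundle")
  if (!is.null(config$out_dir)) write_results(bundle, config$out_dir)
  bundle
}

# Paired value extraction helper: subjects having both conditions.
paired_by_stage <- function(results, var, stage) {
  sub <- results[results$stage == stage, ]
  wide <- merge(sub[sub$condition == "experimental", c("subject", var)],
                sub[sub$condition == "control", c("subject", var)],
                by = "subject", suffixes = c("_exp", "_con"))
  wide <- wide[complete.cases(wide), ]
  wide
}

hypothesis_battery <- function(results, sleep) {
  objects <- list(); rows <- list()
  add_row <- function(id, variable, stage, tr) {
    objects[[id]] <<- tr
    rows[[id]] <<- data.frame(
      hypothesis = id, variable = variable, stage = stage,
      test = if (is.null(tr)) NA_character_ else tr$test,
      statistic = if (is.null(tr)) NA_real_ else tr$statistic,
      p_raw = if (is.null(tr)) NA_real_ else tr$p_raw,
      p_adjusted = NA_real_,
      effect_kind = if (is.null(tr)) NA_character_ else tr$effect$kind,
      effect = if (is.null(tr)) NA_real_ else tr$effect$value,
      ci_lo = if (is.null(tr)) NA_real_ else tr$effect$ci95[1],
      ci_hi = if (is.null(tr)) NA_real_ else tr$effect$ci95[2],
      n = if (is.null(tr)) NA_integer_ else tr$n)
  }
  pair_test <- function(var, stage, tail) {
    wide <- paired_by_stage(results, var, stage)
    if (nrow(wide) < 3) return(NULL)
    paired_compare(wide[[paste0(var, "_exp")]], wide[[paste0(var, "_con")]],
                   tail = tail)
  }
  for (i in seq_along(ANALYSIS_STAGES)) {
    st <- ANALYSIS_STAGES[i]
    add_row(paste0("H", i, "a"), "psd40_db", st,
            pair_test("psd40_db", st, "greater"))
    add_row(paste0("H", i, "b"), "ssvep_amp_uv", st,
            pair_test("ssvep_amp_uv", st, "greater"))
  }
  multilevel <- function(var) {
    exp <- results[results$condition == "experimental",
                   c("subject", "stage", var)]
    wide <- stats::reshape(exp, idvar = "subject", timevar = "stage",
                           direction = "wide")
    m <- as.matrix(wide[, -1, drop = FALSE])
    colnames(m) <- sub(paste0(var, "."), "", colnames(m), fixed = TRUE)
    m <- m[complete.cases(m), intersect(ANALYSIS_STAGES, colnames(m)),
           drop = FALSE]
    if (nrow(m) < 3 || ncol(m) < 3) return(NULL)
    multilevel_compare(m)
  }
  add_row("H5a", "psd40_db", "all", multilevel("psd40_db"))
  add_row("H5b", "ssvep_amp_uv", "all", multilevel("ssvep_amp_uv"))

  sleep_test <- function(var) {
    wide <- merge(sleep[sleep$condition == "experimental",
                        c("subject", var)],
                  sleep[sleep$condition == "control", c("subject", var)],
                  by = "subject", suffixes = c("_exp", "_con"))
    wide <- wide[complete.cases(wide), ]
    if (nrow(wide) < 3) return(NULL)
    paired_compare(wide[[paste0(var, "_exp")]], wide[[paste0(var, "_con")]],
                   tail = "two.sided")
  }
  add_row("H6", "gsqs", "night", sleep_test("gsqs"))
  add_row("H7", "tst_min", "night", sleep_test("tst_min"))
  add_row("H8", "waso_min", "night", sleep_test("waso_min"))

  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  # Bonferroni-Holm within the two confirmatory one-tailed families
  for (fam in list(paste0("H", 1:4, "a"), paste0("H", 1:4, "b"))) {
    sel <- tab$hypothesis %in% fam & !is.na(tab$p_raw)
    if (any(sel)) tab$p_adjusted[sel] <- holm_adjust(tab$p_raw[sel])
  }
  list(table = tab, objects = objects)
}

#' Run the hypothesis battery from a tidy long-format table
#'
#' Entry point for externally computed results: a data frame (or CSV) with
#' columns `subject`, `condition` (`control`/`experimental`), `stage`
#' (W/N2/N3/REM for stage-level variables, anything for night-level ones),
#' `variable` and `value`. Variables `psd40_db` and `ssvep_amp_uv` feed the
#' stage-wise one-tailed contrasts (H1-H4, H1b-H4b, Holm-corrected within
#' family) and the stage multilevel comparisons (H5, H5b); `gsqs`,
#' `tst_min` and `waso_min` feed the two-tailed night contrasts (H6-H8).
#'
#' @param x A data frame in the long format above, or a path to a CSV.
#' @param out_csv Optional path; the per-hypothesis table is written there.
#' @return List with `table` (one row per hypothesis) and `objects`
#'   (the underlying `test_result`s).
#' @export
run_hypotheses <- function(x, out_csv = NULL) {
  df <- if (is.character(x)) read.csv(x, stringsAsFactors = FALSE) else x
  need <- c("subject", "condition", "stage", "variable", "value")
  if (!all(need %in% names(df)))
    stop("need columns ", paste(need, collapse = ", "))
  wide_stage <- function(var) {
    sub <- df[df$variable == var, c("subject", "condition", "stage", "value")]
    names(sub)[names(sub) == "value"] <- var
    sub
  }
  stage_vars <- intersect(c("psd40_db", "ssvep_amp_uv"), unique(df$variable))
  results <- NULL
  for (v in stage_vars) {
    w <- wide_stage(v)
    results <- if (is.null(results)) w else
      merge(results, w, by = c("subject", "condition", "stage"), all = TRUE)
  }
  if (is.null(results))
    results <- data.frame(subject = integer(), condition = character(),
                          stage = character())
  for (v in setdiff(c("psd40_db", "ssvep_amp_uv"), names(results)))
    results[[v]] <- NA_real_
  sleep_vars <- intersect(c("gsqs", "tst_min", "waso_min"),
                          unique(df$variable))
  sleep <- NULL
  for (v in sleep_vars) {
    sub <- df[df$variable == v, c("subject", "condition", "value")]
    names(sub)[names(sub) == "value"] <- v
    sleep <- if (is.null(sleep)) sub else
      merge(sleep, sub, by = c("subject", "condition"), all = TRUE)
  }
  if (is.null(sleep))
    sleep <- data.frame(subject = integer(), condition = character())
  for (v in setdiff(c("gsqs", "tst_min", "waso_min"), names(sleep)))
    sleep[[v]] <- NA_real_
  st <- hypothesis_battery(results, sleep)
  if (!is.null(out_csv)) write.csv(st$table, out_csv, row.names = FALSE)
  st
}

#' @export
print.results_bundle <- function(x, ...) {
  cat("<results_bundle> ", x$manifest$n_subjects, " subjects, seed ",
      x$manifest$seed, ", config ", substr(x$manifest$config_hash, 1, 8),
      "\n", sep = "")
  agg <- stats::aggregate(cbind(psd40_db, ssvep_amp_uv) ~ condition + stage,
                          x$spectral_ssvep, mean)
  print(agg, digits = 4)
  if (!is.null(x$stats)) {
    cat("hypotheses:\n")
    print(x$stats[, c("hypothesis", "test", "p_raw", "p_adjusted",
                      "effect_kind", "effect")], digits = 3)
  } else if (!is.null(x$stats_skipped_reason)) {
    cat(x$stats_skipped_reason, "\n")
  }
  invisible(x)
}

#' Write all result tables of a pipeline run
#'
#' Emits `psd40.csv` (condition, stage, n_epochs, psd40_db, snr per
#' subject), `ssvep.csv`, `ssvep_waveforms.csv`, `sleep.csv`, `stats.csv`
#' and `manifest.json` into `dir`.
#'
#' @param bundle A `results_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_results <- function(bundle, dir) {
  stopifnot(inherits(bundle, "results_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  r <- bundle$spectral_ssvep
  write.csv(r[, c("subject", "condition", "stage", "n_epochs", "psd40_db",
                  "psd_snr")],
            file.path(dir, "psd40.csv"), row.names = FALSE)
  write.csv(r[, c("subject", "condition", "stage", "n_segments",
                  "ssvep_amp_uv", "ssvep_snr")],
            file.path(dir, "ssvep.csv"), row.names = FALSE)
  write.csv(bundle$waveforms, file.path(dir, "ssvep_waveforms.csv"),
            row.names = FALSE)
  write.csv(bundle$sleep, file.path(dir, "sleep.csv"), row.names = FALSE)
  if (!is.null(bundle$stats))
    write.csv(bundle$stats, file.path(dir, "stats.csv"), row.names = FALSE)
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
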