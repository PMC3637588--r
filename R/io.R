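#' Write a recording bundle to disk
#'
#' One CSV per signal group and session (first column `time_s`, then one
#' column per channel) plus a JSON sidecar holding the timeline, probe
#' geometry, simulation configuration and seed.
#'
#' @param recording a `nirs_recording`.
#' @param path output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "nirs_recording"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (s in seq_along(recording$sessions)) {
    ses <- recording$sessions[[s]]
    fn <- data.table::data.table(
      time_s = (seq_len(nrow(ses$fnirs)) - 1) / recording$fs_fnirs,
      ses$fnirs)
    data.table::fwrite(fn, file.path(path, sprintf("session%d_fnirs.csv", s)))
    if (!is.null(ses$bio)) {
      bio <- data.table::data.table(
        time_s = (seq_len(nrow(ses$bio)) - 1) / recording$fs_bio, ses$bio)
      data.table::fwrite(bio,
                         file.path(path, sprintf("session%d_biosignals.csv", s)))
    }
    if (!is.null(ses$force)) {
      data.table::fwrite(data.table::data.table(force_N = ses$force),
                         file.path(path, sprintf("session%d_force.csv", s)))
    }
  }
  tl <- recording$timeline
  meta <- list(
    n_sessions = length(recording$sessions),
    fs_fnirs = recording$fs_fnirs, fs_bio = recording$fs_bio,
    timeline = list(
      seed = tl$seed,
      config = unclass(tl$config),
      sessions = lapply(tl$sessions, function(ses)
        list(duration_s = ses$duration_s,
             baseline_start_s = ses$baseline_start_s,
             baseline_end_s = ses$baseline_end_s,
             trials = ses$trials))),
    geometry = unclass(recording$geometry),
    sim_config = unclass(recording$config),
    artifacts = recording$artifacts)
  jsonlite::write_json(meta, file.path(path, "metadata.json"),
                       digits = NA, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' Read a recording bundle from disk
#'
#' Inverse of [write_recording()]; numeric values round-trip losslessly.
#' Ground-truth and force traces are not part of the interchange format
#' (`truth` is absent after a round trip; `force` is restored when
#' present).
#'
#' @param path directory written by [write_recording()].
#' @return a `nirs_recording`.
#' @export
read_recording <- function(path) {
  meta_file <- file.path(path, "metadata.json")
  if (!file.exists(meta_file)) stop("no metadata.json under ", path)
  meta <- jsonlite::read_json(meta_file, simplifyVector = TRUE)
  cfg <- meta$timeline$config
  tl_config <- timeline_config(
    n_sessions = cfg$n_sessions, trials_per_condition = cfg$trials_per_condition,
    baseline_start_s = cfg$baseline_start_s, baseline_end_s = cfg$baseline_end_s,
    rest_range_s = cfg$rest_range_s, pinch_duration_s = cfg$pinch_duration_s,
    cue_durations_s = cfg$cue_durations_s)
  sess_meta <- meta$timeline$sessions
  sessions_tl <- lapply(seq_len(meta$n_sessions), function(s) {
    sm <- if (is.data.frame(sess_meta)) sess_meta[s, ] else sess_meta[[s]]
    tr <- sm$trials
    if (is.list(tr) && !is.data.frame(tr)) tr <- tr[[1]]
    list(duration_s = sm$duration_s, baseline_start_s = sm$baseline_start_s,
         baseline_end_s = sm$baseline_end_s, trials = as.data.frame(tr))
  })
  timeline <- structure(list(sessions = sessions_tl, config = tl_config,
                             seed = meta$timeline$seed),
                        class = "nirs_timeline")
  g <- meta$geometry
  geometry <- optical_geometry(g$wavelengths_nm, g$path_lengths_cm, g$dpf,
                               g$eps_o2hb, g$eps_hhb)
  ch_names <- fnirs_channels(geometry)$name
  sessions <- lapply(seq_len(meta$n_sessions), function(s) {
    f <- file.path(path, sprintf("session%d_fnirs.csv", s))
    fn <- read_signal_csv(f, expected = c("time_s", ch_names))
    ses <- list(fnirs = as.matrix(fn[, ch_names, drop = FALSE]))
    bf <- file.path(path, sprintf("session%d_biosignals.csv", s))
    if (file.exists(bf)) {
      bio <- read_signal_csv(bf, expected = c("time_s", "ECG", "RESP", "BP", "SC"))
      ses$bio <- as.matrix(bio[, c("ECG", "RESP", "BP", "SC"), drop = FALSE])
    }
    ff <- file.path(path, sprintf("session%d_force.csv", s))
    if (file.exists(ff)) ses$force <- read_signal_csv(ff, "force_N")$force_N
    ses
  })
  sc <- meta$sim_config
  sim_cfg <- structure(sc, class = "sim_config")
  structure(list(sessions = sessions, timeline = timeline,
                 geometry = geometry, config = sim_cfg,
                 fs_fnirs = meta$fs_fnirs, fs_bio = meta$fs_bio,
                 artifacts = if (length(meta$artifacts))
                   as.data.frame(meta$artifacts) else NULL),
            class = "nirs_recording")
}

## CSV reader with header/shape validation and row-level diagnostics
read_signal_csv <- function(file, expected) {
  if (!file.exists(file)) stop("missing file: ", file)
  dt <- withCallingHandlers(
    tryCatch(
      data.table::fread(file, fill = FALSE),
      error = function(e) stop("parse error in ", basename(file), ": ",
                               conditionMessage(e))),
    warning = function(w) {
      # fread housekeeping notices are benign; data warnings are not
      if (grepl("cleaned up", conditionMessage(w), fixed = TRUE)) {
        invokeRestart("muffleWarning")
      } else {
        stop("parse error in ", basename(file), ": ", conditionMessage(w))
      }
    })
  miss <- setdiff(expected, names(dt))
  if (length(miss)) {
    stop("malformed header in ", basename(file), ": missing column(s) ",
         paste(miss, collapse = ", "))
  }
  for (cn in expected) {
    bad <- which(!is.finite(dt[[cn]]) & !is.na(dt[[cn]]))
    nas <- which(is.na(dt[[cn]]))
    if (length(nas)) {
      stop("parse error in ", basename(file), " at row ", nas[1],
           " (column ", cn, "): missing or non-numeric value")
    }
  }
  as.data.frame(dt)
}

#' Run configuration
#'
#' A single JSON-serialisable document that governs a full simulate +
#' decode run: segment geometry, topology grid, repeats, folds, restarts,
#' preprocessing constants, modes and the master seed. Unknown keys are
#' rejected.
#'
#' @param ... overrides of the defaults.
#' @return a list of class `run_config`.
#' @export
run_config <- function(...) {
  defaults <- list(
    modes = c("fnirs_only", "combined"),
    n_window = 75L, n_shift = 25L,
    grid_states = 1:5, grid_mix = 1:2,
    n_repeats = 7L, k_folds = 4L, n_restarts = 10L,
    ma_threshold = 3, em_max_iter = 100L, em_tol = 1e-6,
    seed = 1L)
  over <- list(...)
  if (length(over) == 1L && is.list(over[[1]]) && is.null(names(over))) {
    over <- over[[1]]
  }
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  defaults[names(over)] <- over
  structure(defaults, class = "run_config")
}

#' @rdname run_config
#' @param path JSON file to read/write.
#' @param config a `run_config`.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  run_config(obj)
}

#' Execute a configured decoding run
#'
#' Thin composition used by the command-line interface: preprocessing,
#' feature extraction, dual-HMM training and cross-validated assessment
#' per [run_experiment()], driven by a [run_config()].
#'
#' @param recording a `nirs_recording` (e.g. from [read_recording()]).
#' @param config a [run_config()].
#' @return a `decoding_report`.
#' @export
run_from_config <- function(recording, config) {
  stopifnot(inherits(config, "run_config"))
  grid <- topology_grid(config$grid_states, config$grid_mix)
  run_experiment(recording,
                 modes = config$modes, grid = grid,
                 n_repeats = config$n_repeats, k = config$k_folds,
                 n_restarts = config$n_restarts,
                 spec = segment_spec(config$n_window, config$n_shift),
                 seed = config$seed, ma_threshold = config$ma_threshold,
                 max_iter = config$em_max_iter, tol = config$em_tol)
}

#' Write a decoding report to JSON and a readable table
#'
#' @param report a `decoding_report`.
#' @param path output file stem; writes `<path>.json` and `<path>.txt`.
#' @return invisible vector of the files written.
#' @export
write_report <- function(report, path) {
  obj <- list(selected = report$selected, summaries = report$summaries,
              runs = report$runs, n_trials = report$n_trials,
              n_pairs_used = report$n_pairs_used,
              n_pairs_excluded = report$n_pairs_excluded, seed = report$seed)
  jsonlite::write_json(obj, paste0(path, ".json"), digits = NA,
                       auto_unbox = TRUE, dataframe = "columns")
  txt <- utils::capture.output(print(report))
  writeLines(txt, paste0(path, ".txt"))
  invisible(c(paste0(path, ".json"), paste0(path, ".txt")))
}
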