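#' Mean blood pressure preprocessing
#'
#' Per-session linear detrend followed by a zero-phase first-order
#' Butterworth low-pass at 0.1 Hz, isolating the low and very-low
#' frequency content ("mean blood pressure").
#'
#' @param bp raw continuous blood pressure, one session.
#' @param fs sampling rate (default 600).
#' @param cutoff_hz low-pass cutoff (default 0.1).
#' @return filtered series at the input rate.
#' @export
preprocess_bp <- function(bp, fs = 600, cutoff_hz = 0.1) {
  n <- length(bp)
  if (n < 10 * fs) stop("session shorter than 10 s")
  t <- seq_len(n)
  fit <- stats::lm.fit(cbind(1, t), bp)
  detr <- fit$residuals
  f <- signal::butter(1, cutoff_hz / (fs / 2), type = "low")
  zero_phase(f, detr)
}

## decaying running maximum: env[t] = max_{k<=t} s[k] * decay^(t-k),
## evaluated block-wise to stay in floating-point range
decaying_max <- function(s, decay) {
  n <- length(s)
  out <- numeric(n)
  block <- 4096L
  w_full <- decay^(0:(block - 1L))
  carry <- 0
  i <- 1L
  while (i <= n) {
    j <- min(n, i + block - 1L)
    ww <- w_full[1:(j - i + 1L)]
    v <- ww * cummax(s[i:j] / ww)
    out[i:j] <- pmax(v, carry * decay * ww)
    carry <- out[j]
    i <- j + 1L
  }
  out
}

#' Adaptive-threshold event detection on a squared derivative
#'
#' Concretisation of slope-based QRS/breath detection: the (optionally
#' rectified) squared first difference of the band-limited signal is
#' compared against an adaptive threshold equal to `frac` times an
#' exponentially decaying running maximum of itself (time constant
#' `tau_s`); threshold-exceeding local maxima separated by at least the
#' refractory period are returned as event times.
#'
#' @param x pre-filtered signal (one session).
#' @param fs sampling rate.
#' @param frac threshold fraction of the running peak envelope.
#' @param tau_s envelope decay time constant (s).
#' @param refractory_s minimum event separation (s).
#' @param rectify use only positive slopes (one event per oscillation
#'   cycle; used for respiration).
#' @return numeric vector of event times (s), strictly increasing.
#' @export
adaptive_threshold_events <- function(x, fs, frac = 0.4, tau_s = 5,
                                      refractory_s = 0.25, rectify = FALSE) {
  d <- diff(x)
  if (rectify) d <- pmax(d, 0)
  s <- d^2
  if (max(s) == 0) stop("flat signal: no events detectable; review parameters")
  env <- decaying_max(s, exp(-1 / (tau_s * fs)))
  above <- s > frac * env & s > 1e-3 * max(s)
  loc <- which(above)
  loc <- loc[s[loc] >= s[pmax(1L, loc - 1L)] & s[loc] >= s[pmin(length(s), loc + 1L)]]
  if (length(loc) == 0) stop("no events found; review detector parameters")
  keep <- numeric(0)
  last <- -Inf
  for (k in loc) {
    if ((k - last) / fs >= refractory_s) {
      keep <- c(keep, k)
      last <- k
    }
  }
  (keep - 1) / fs
}

#' Detect heartbeats or breaths
#'
#' Applies the modality-specific band-limiting filter and the adaptive
#' slope-based threshold detector. For ECG, a 4th-order Butterworth
#' band-pass 0.01-40 Hz (realised as a high-pass/low-pass cascade);
#' for blood pressure, the raw pulsatile signal is used directly;
#' for respiration, an 8th-order band-pass 0.1-2.1 Hz (cascade applied
#' after decimation to 50 Hz, where the low band edge is well
#' conditioned).
#'
#' @param x raw signal, one session.
#' @param type one of `"ecg"`, `"bp"`, `"resp"`.
#' @param fs input sampling rate (default 600).
#' @return numeric vector of event times (s); class attribute `source`
#'   records the modality.
#' @export
detect_beats <- function(x, type = c("ecg", "bp", "resp"), fs = 600) {
  type <- match.arg(type)
  if (sd(x) == 0) stop("flat signal: no events detectable; review parameters")
  if (type == "ecg") {
    hp <- signal::butter(2, 0.01 / (fs / 2), type = "high")
    lp <- signal::butter(4, 40 / (fs / 2), type = "low")
    xf <- zero_phase(lp, zero_phase(hp, x))
    times <- adaptive_threshold_events(xf, fs, frac = 0.4, tau_s = 5,
                                       refractory_s = 0.25)
  } else if (type == "bp") {
    hp <- signal::butter(2, 0.5 / (fs / 2), type = "high")
    lp <- signal::butter(4, 8 / (fs / 2), type = "low")
    xf <- zero_phase(lp, zero_phase(hp, x))
    times <- adaptive_threshold_events(xf, fs, frac = 0.5, tau_s = 5,
                                       refractory_s = 0.4)
  } else {
    fs2 <- 50
    xr <- if (fs > fs2) downsample_signal(x, fs, fs2) else x
    if (fs <= fs2) fs2 <- fs
    hp <- signal::butter(4, 0.1 / (fs2 / 2), type = "high")
    lp <- signal::butter(4, 2.1 / (fs2 / 2), type = "low")
    xf <- zero_phase(lp, zero_phase(hp, xr))
    times <- adaptive_threshold_events(xf, fs2, frac = 0.3, tau_s = 10,
                                       refractory_s = 1.5, rectify = TRUE)
  }
  structure(times, source = type)
}

## previous-interval instantaneous rate (events/min) sampled on a 5 Hz grid
rate_step_series <- function(times, n_out, fs_out = 5) {
  grid <- (seq_len(n_out) - 1) / fs_out
  if (length(times) < 2) return(rep(NA_real_, n_out))
  iv <- diff(times)
  rate <- 60 / iv
  idx <- findInterval(grid, times[-1]) + 1L  # interval index whose rate applies
  idx[idx > length(rate)] <- length(rate)
  rate[idx]
}

#' Fuse ECG- and blood-pressure-derived heart rate
#'
#' Instantaneous heart rate from ECG beat-to-beat intervals as a
#' previous-interval step function on a 5 Hz grid; wherever the
#' ECG-derived interval is physiologically implausible (outside
#' `rr_bounds`) or missing, the blood-pressure-derived estimate
#' substitutes. Optionally smoothed with a zero-phase 0.25 Hz low-pass.
#'
#' @param ecg_beats,bp_beats beat-time vectors (s) from [detect_beats()];
#'   either may be `NULL`.
#' @param n_out output length (samples at `fs_out`).
#' @param fs_out output rate (default 5 Hz).
#' @param rr_bounds plausible beat-to-beat interval range (s).
#' @param smooth apply the 0.25 Hz low-pass (default TRUE).
#' @return heart-rate series (beats/min) of length `n_out`.
#' @export
fuse_heart_rate <- function(ecg_beats, bp_beats, n_out, fs_out = 5,
                            rr_bounds = c(0.3, 2.0), smooth = TRUE) {
  if ((is.null(ecg_beats) || length(ecg_beats) < 2) &&
      (is.null(bp_beats) || length(bp_beats) < 2)) {
    stop("both beat sources empty")
  }
  plaus <- function(times) {
    r <- rate_step_series(times, n_out, fs_out)
    ## intervals at or beyond the physiological bounds are implausible
    ## (a missed beat in a 60 bpm train doubles the interval to exactly 2 s)
    r[!is.na(r) & (r <= 60 / rr_bounds[2] | r >= 60 / rr_bounds[1])] <- NA_real_
    r
  }
  hr <- plaus(ecg_beats)
  hr_bp <- plaus(bp_beats)
  miss <- is.na(hr)
  hr[miss] <- hr_bp[miss]
  if (anyNA(hr)) {  # fill remaining gaps by nearest valid value
    ok <- which(!is.na(hr))
    if (length(ok) == 0) stop("no plausible beat intervals in either source")
    hr <- approx(ok, hr[ok], xout = seq_along(hr), method = "constant",
                 rule = 2, f = 0)$y
  }
  if (smooth) {
    f <- signal::butter(2, 0.25 / (fs_out / 2), type = "low")
    hr <- zero_phase(f, hr)
  }
  hr
}

#' Breathing rate from respiratory flow
#'
#' Band-passes the flow signal, detects breath onsets with the adaptive
#' slope detector, and converts breath-to-breath intervals to an
#' instantaneous rate series on a 5 Hz grid (previous-interval step
#' function, smoothed at 0.25 Hz).
#'
#' @param resp raw respiration flow, one session.
#' @param n_out output length at `fs_out`.
#' @param fs input rate (default 600).
#' @param fs_out output rate (default 5).
#' @param smooth apply the 0.25 Hz low-pass.
#' @return breathing-rate series (breaths/min).
#' @export
compute_br <- function(resp, n_out, fs = 600, fs_out = 5, smooth = TRUE) {
  breaths <- detect_beats(resp, type = "resp", fs = fs)
  br <- rate_step_series(breaths, n_out, fs_out)
  if (anyNA(br)) {
    ok <- which(!is.na(br))
    if (length(ok) == 0) stop("no breaths detected")
    br <- approx(ok, br[ok], xout = seq_along(br), method = "constant",
                 rule = 2)$y
  }
  if (smooth) {
    f <- signal::butter(2, 0.25 / (fs_out / 2), type = "low")
    br <- zero_phase(f, br)
  }
  br
}

#' Skin conductance response extraction
#'
#' Low-passes the skin conductance signal (8th-order Butterworth, 30 Hz),
#' then removes the tonic level with a continuous piecewise-linear fit
#' whose breakpoints are the trial start times; with fewer than two
#' breakpoints a global linear detrend is used with a warning.
#'
#' @param sc raw skin conductance, one session.
#' @param trial_starts_s trial start times (s) used as detrend
#'   breakpoints.
#' @param fs sampling rate (default 600).
#' @return the phasic (detrended) series at the input rate.
#' @export
preprocess_scr <- function(sc, trial_starts_s, fs = 600) {
  n <- length(sc)
  f <- signal::butter(8, 30 / (fs / 2), type = "low")
  x <- zero_phase(f, sc)
  t <- (seq_len(n) - 1) / fs
  bp <- trial_starts_s[trial_starts_s > t[1] & trial_starts_s < t[n]]
  if (length(bp) < 2) {
    warning("fewer than 2 breakpoints: falling back to global linear detrend")
    fit <- stats::lm.fit(cbind(1, t), x)
    return(x - cbind(1, t) %*% fit$coefficients)
  }
  basis <- cbind(1, t, vapply(bp, function(b) pmax(t - b, 0), numeric(n)))
  thin <- seq(1L, n, by = max(1L, fs %/% 5L))
  fit <- stats::lm.fit(basis[thin, , drop = FALSE], x[thin])
  drop(x - basis %*% fit$coefficients)
}

#' Assemble the four 5 Hz autonomic feature signals
#'
#' From the raw biosignal block of each session, derives mean blood
#' pressure (BP), fused heart rate (HR), breathing rate (BR) and the
#' phasic skin conductance response (SCR), downsampled to 5 Hz, aligned
#' to a common length, and session-wise z-normalised.
#'
#' @param recording a `nirs_recording` with biosignal channels `ECG`,
#'   `RESP`, `BP`, `SC`.
#' @return object of class `ans_features`: list of per-session
#'   samples x 4 matrices with columns `BP`, `HR`, `BR`, `SCR`.
#' @export
assemble_biosignals <- function(recording) {
  stopifnot(inherits(recording, "nirs_recording"))
  fs <- recording$fs_bio
  out <- vector("list", length(recording$sessions))
  for (s in seq_along(recording$sessions)) {
    bio <- recording$sessions[[s]]$bio
    needed <- c("ECG", "RESP", "BP", "SC")
    if (is.null(bio) || !all(needed %in% colnames(bio))) {
      missing_ch <- if (is.null(bio)) needed else setdiff(needed, colnames(bio))
      stop("missing biosignal channel(s) in session ", s, ": ",
           paste(missing_ch, collapse = ", "))
    }
    n600 <- nrow(bio)
    n5 <- n600 %/% 120L
    bp5 <- downsample_signal(preprocess_bp(bio[, "BP"], fs), fs, 5)[seq_len(n5)]
    ecg_b <- detect_beats(bio[, "ECG"], "ecg", fs)
    bp_b <- tryCatch(detect_beats(bio[, "BP"], "bp", fs), error = function(e) NULL)
    hr5 <- fuse_heart_rate(ecg_b, bp_b, n_out = n5)
    br5 <- compute_br(bio[, "RESP"], n_out = n5, fs = fs)
    starts <- recording$timeline$sessions[[s]]$trials$start_s
    scr5 <- downsample_signal(preprocess_scr(bio[, "SC"], starts, fs),
                              fs, 5)[seq_len(n5)]
    m <- cbind(BP = bp5, HR = hr5[seq_len(n5)], BR = br5[seq_len(n5)], SCR = scr5)
    out[[s]] <- normalize_session(m)
  }
  structure(list(sessions = out, fs = 5), class = "ans_features")
}
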