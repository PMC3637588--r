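#' Optical probe geometry and absorption constants
#'
#' Describes the two-wavelength, four-path probe used at each cortical
#' location: source-detector separations, wavelength-specific differential
#' pathlength factors (DPF), and the extinction coefficients of oxy- and
#' deoxyhemoglobin at the two wavelengths, in (cm mM)^-1.
#'
#' @param wavelengths_nm the two laser wavelengths (nm).
#' @param path_lengths_cm source-detector separations of the four light
#'   paths (cm).
#' @param dpf differential pathlength factor per wavelength.
#' @param eps_o2hb,eps_hhb extinction coefficients of O2Hb and HHb at the
#'   two wavelengths, (cm mM)^-1.
#' @return an object of class `nirs_geometry`.
#' @export
optical_geometry <- function(wavelengths_nm = c(692, 834),
                             path_lengths_cm = c(2, 2.5, 3.5, 4),
                             dpf = c(6.51, 5.86),
                             eps_o2hb = c(0.9556, 2.3671),
                             eps_hhb = c(4.8538, 1.7891)) {
  g <- list(wavelengths_nm = wavelengths_nm, path_lengths_cm = path_lengths_cm,
            dpf = dpf, eps_o2hb = eps_o2hb, eps_hhb = eps_hhb)
  if (any(unlist(g) <= 0)) stop("all geometry entries must be strictly positive")
  if (length(wavelengths_nm) != 2L || length(dpf) != 2L ||
      length(eps_o2hb) != 2L || length(eps_hhb) != 2L) {
    stop("geometry is defined for exactly two wavelengths")
  }
  E <- extinction_matrix(g)
  if (abs(det(E)) < 1e-12) stop("extinction matrix is singular")
  class(g) <- "nirs_geometry"
  g
}

## rows = wavelengths, cols = (O2Hb, HHb)
extinction_matrix <- function(geometry) {
  matrix(c(geometry$eps_o2hb[1], geometry$eps_hhb[1],
           geometry$eps_o2hb[2], geometry$eps_hhb[2]),
         nrow = 2, byrow = TRUE)
}

#' fNIRS channel metadata
#'
#' The 16 raw intensity channels in canonical column order: location
#' (M1 then PMv), light path (1..4), wavelength (first then second).
#'
#' @param geometry an [optical_geometry()] object.
#' @return a data.frame with columns `name`, `location`, `path`,
#'   `wavelength_nm`, `l_cm`, `dpf`.
#' @export
fnirs_channels <- function(geometry = optical_geometry()) {
  loc <- rep(c("M1", "PMv"), each = 8)
  path <- rep(rep(1:4, each = 2), times = 2)
  wl_i <- rep(1:2, times = 8)
  data.frame(
    name = sprintf("I_%s_p%d_w%d", loc, path, geometry$wavelengths_nm[wl_i]),
    location = loc, path = path,
    wavelength_nm = geometry$wavelengths_nm[wl_i],
    l_cm = geometry$path_lengths_cm[path],
    dpf = geometry$dpf[wl_i],
    stringsAsFactors = FALSE
  )
}

#' Configuration for the experimental timeline generator
#'
#' The default protocol: two sessions, each opening with 180 s and closing
#' with 120 s of baseline, containing a randomised sequence of four trial
#' conditions (cued pinching with 10 s or 5 s cue, a sham cue with no
#' pinching, and uncued pinching). Pinching periods last exactly 20 s;
#' every trial is preceded by a rest period of randomised duration.
#'
#' @param n_sessions number of recording sessions.
#' @param trials_per_condition trials of each of the four conditions per
#'   session (default 5, i.e. 30 pinching trials over two sessions).
#' @param baseline_start_s,baseline_end_s opening/closing baseline (s).
#' @param rest_range_s range of the randomised rest durations (s).
#' @param pinch_duration_s fixed pinching duration (s).
#' @param cue_durations_s cue duration per condition (s); condition 3 is
#'   the sham (cue, no pinching), condition 4 is uncued.
#' @return a list of class `timeline_config`.
#' @export
timeline_config <- function(n_sessions = 2L, trials_per_condition = 5L,
                            baseline_start_s = 180, baseline_end_s = 120,
                            rest_range_s = c(15, 24), pinch_duration_s = 20,
                            cue_durations_s = c(10, 5, 10, 0)) {
  if (trials_per_condition < 0) stop("trials_per_condition must be >= 0")
  if (n_sessions < 1) stop("need at least one session")
  if (baseline_start_s <= 0 || baseline_end_s <= 0) {
    stop("non-positive session duration budget")
  }
  structure(list(n_sessions = as.integer(n_sessions),
                 trials_per_condition = as.integer(trials_per_condition),
                 baseline_start_s = baseline_start_s,
                 baseline_end_s = baseline_end_s,
                 rest_range_s = rest_range_s,
                 pinch_duration_s = pinch_duration_s,
                 cue_durations_s = cue_durations_s),
            class = "timeline_config")
}

#' Generate a randomised experimental timeline
#'
#' Conditions are presented in uniformly random order within each session
#' (each condition appearing `trials_per_condition` times) and rest
#' durations are drawn uniformly from `rest_range_s`. Deterministic for a
#' fixed seed.
#'
#' @param config a [timeline_config()].
#' @param seed integer seed.
#' @return an object of class `nirs_timeline`: a list with one element per
#'   session, each holding `duration_s` and a `trials` data.frame with
#'   columns `condition`, `start_s` (start of the preceding rest),
#'   `rest_duration_s`, `cue_duration_s`, `cue_onset_s`, `pinch_onset_s`
#'   (NA for the sham condition), `pinch_duration_s`, `end_s`.
#' @export
generate_timeline <- function(config = timeline_config(), seed = 1L) {
  set.seed(derive_seed(seed, 11L))
  sessions <- vector("list", config$n_sessions)
  for (s in seq_len(config$n_sessions)) {
    n_trials <- 4L * config$trials_per_condition
    if (n_trials == 0L) {
      sessions[[s]] <- list(
        duration_s = config$baseline_start_s + config$baseline_end_s,
        baseline_start_s = config$baseline_start_s,
        baseline_end_s = config$baseline_end_s,
        trials = data.frame(condition = integer(0), start_s = numeric(0),
                            rest_duration_s = numeric(0),
                            cue_duration_s = numeric(0), cue_onset_s = numeric(0),
                            pinch_onset_s = numeric(0),
                            pinch_duration_s = numeric(0), end_s = numeric(0)))
      next
    }
    cond <- sample(rep(1:4, config$trials_per_condition))
    rest <- runif(n_trials, config$rest_range_s[1], config$rest_range_s[2])
    cue <- config$cue_durations_s[cond]
    start <- numeric(n_trials); pinch_on <- rep(NA_real_, n_trials)
    pinch_dur <- rep(NA_real_, n_trials); end <- numeric(n_trials)
    t <- config$baseline_start_s
    for (i in seq_len(n_trials)) {
      start[i] <- t
      cue_on <- t + rest[i]
      if (cond[i] == 3L) {
        end[i] <- cue_on + cue[i]
      } else {
        pinch_on[i] <- cue_on + cue[i]
        pinch_dur[i] <- config$pinch_duration_s
        end[i] <- pinch_on[i] + config$pinch_duration_s
      }
      t <- end[i]
    }
    sessions[[s]] <- list(
      duration_s = t + config$baseline_end_s,
      baseline_start_s = config$baseline_start_s,
      baseline_end_s = config$baseline_end_s,
      trials = data.frame(condition = cond, start_s = start,
                          rest_duration_s = rest, cue_duration_s = cue,
                          cue_onset_s = start + rest, pinch_onset_s = pinch_on,
                          pinch_duration_s = pinch_dur, end_s = end))
  }
  structure(list(sessions = sessions, config = config, seed = seed),
            class = "nirs_timeline")
}

#' Configuration of the synthetic recording simulator
#'
#' Amplitudes, oscillation and noise levels of the forward model that turns
#' a timeline into raw optical intensities and biosignals. Task-locked
#' hemoglobin changes are pinch-period boxcars convolved with a double-gamma
#' hemodynamic response; autonomic channels carry smoothed stimulus-locked
#' step responses; optical channels are contaminated by cardiac,
#' respiratory and Mayer-wave oscillations, slow drift and white noise.
#'
#' @param seed simulator seed.
#' @param baseline_intensity mean raw intensity per optical channel (a.u.).
#' @param o2hb_amp_mM plateau amplitude of the task-evoked oxyhemoglobin
#'   increase (mM); typical single-trial motor responses are a few tenths
#'   of a micromolar.
#' @param hhb_ratio deoxyhemoglobin amplitude as a (negative) fraction of
#'   the O2Hb amplitude.
#' @param location_gain named multipliers of the evoked response per
#'   location.
#' @param hrf_peak_s,hrf_undershoot_s,hrf_ratio double-gamma response
#'   shape: time-to-peak, undershoot peak and undershoot ratio.
#' @param hr_base_bpm,hr_amp_bpm baseline heart rate and task increase.
#' @param br_base_bpm,br_amp_bpm baseline breathing rate and task increase.
#' @param bp_base,bp_amp,bp_pulse_amp,bp_mayer_amp mean blood pressure
#'   (mmHg): baseline, task step, pulsatile and Mayer-wave amplitudes.
#' @param scr_amp phasic skin conductance response amplitude (uS).
#' @param scr_delay_range_s onset latency range of the phasic response
#'   after pinch onset (s).
#' @param scr_rise_s,scr_decay_s rise/decay time constants of the
#'   double-exponential (Bateman) response kernel.
#' @param sc_tonic_base,sc_drift tonic skin conductance level and per
#'   session drift span (uS).
#' @param osc_cardiac_mM,osc_resp_mM,osc_mayer_mM amplitudes of systemic
#'   oscillations leaking into the hemoglobin signals (mM).
#' @param cardiac_freq_hz,resp_freq_hz,mayer_freq_hz their frequencies.
#' @param drift_od slow optical drift span (optical density units).
#' @param noise_od white optical noise SD per 50 Hz sample (OD units).
#' @param ecg_noise,resp_noise,bp_noise,sc_noise additive white noise SDs
#'   of the biosignal channels (native units).
#' @param rr_jitter beat-to-beat timing jitter (fraction of an interval).
#' @param env_tau_s time constant of the autonomic step response (s).
#' @param null_mode if TRUE, force every task-locked effect size to zero
#'   (chance-level recordings with the same noise structure).
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       baseline_intensity = 1000,
                       o2hb_amp_mM = 3e-4, hhb_ratio = -1 / 3,
                       location_gain = c(M1 = 1, PMv = 0.6),
                       hrf_peak_s = 6, hrf_undershoot_s = 16, hrf_ratio = 1 / 6,
                       hr_base_bpm = 62, hr_amp_bpm = 5,
                       br_base_bpm = 15, br_amp_bpm = 3,
                       bp_base = 90, bp_amp = 5, bp_pulse_amp = 3,
                       bp_mayer_amp = 1.5,
                       scr_amp = 0.5, scr_delay_range_s = c(1, 3),
                       scr_rise_s = 0.75, scr_decay_s = 4,
                       sc_tonic_base = 5, sc_drift = 0.8,
                       osc_cardiac_mM = 4e-5, osc_resp_mM = 4e-5,
                       osc_mayer_mM = 8e-5,
                       cardiac_freq_hz = 1.1, resp_freq_hz = 0.27,
                       mayer_freq_hz = 0.1,
                       drift_od = 2e-3, noise_od = 1.5e-2,
                       ecg_noise = 0.03, resp_noise = 0.05,
                       bp_noise = 0.5, sc_noise = 0.01,
                       rr_jitter = 0.02, env_tau_s = 3,
                       null_mode = FALSE) {
  cfg <- as.list(environment())
  amps <- c("o2hb_amp_mM", "hr_amp_bpm", "br_amp_bpm", "bp_amp", "scr_amp",
            "osc_cardiac_mM", "osc_resp_mM", "osc_mayer_mM", "drift_od",
            "noise_od", "bp_pulse_amp", "bp_mayer_amp")
  if (any(unlist(cfg[amps]) < 0)) stop("amplitudes must be >= 0")
  if (isTRUE(null_mode)) {
    cfg$o2hb_amp_mM <- 0; cfg$hr_amp_bpm <- 0; cfg$br_amp_bpm <- 0
    cfg$bp_amp <- 0; cfg$scr_amp <- 0
  }
  structure(cfg, class = "sim_config")
}

#' Double-gamma hemodynamic response kernel
#'
#' Canonical double-gamma impulse response sampled at `fs`, normalised to
#' unit net area so that the response to a sustained stimulus plateaus at
#' the stimulus amplitude.
#'
#' @param fs sampling rate (Hz).
#' @param peak_s,undershoot_s,ratio time-to-peak of the positive lobe, of
#'   the undershoot, and undershoot amplitude ratio.
#' @param duration_s kernel support (s).
#' @return numeric vector of kernel weights (summing to `1/fs` scaled to
#'   unit gain).
#' @export
hrf_kernel <- function(fs, peak_s = 6, undershoot_s = 16, ratio = 1 / 6,
                       duration_s = 32) {
  t <- seq(0, duration_s, by = 1 / fs)
  g <- function(tt, peak) stats::dgamma(tt, shape = peak + 1, rate = 1)
  h <- g(t, peak_s) - ratio * g(t, undershoot_s)
  h / sum(h)
}

## convolve x with kernel k, aligned causally, same length as x.
## FFT length padded to a 2-3-5-smooth size: R's mixed-radix FFT is
## pathologically slow on lengths with large prime factors.
conv_causal <- function(x, k) {
  n <- length(x); m <- length(k)
  N <- stats::nextn(n + m - 1L, c(2L, 3L, 5L))
  X <- fft(c(x, numeric(N - n)))
  K <- fft(c(k, numeric(N - m)))
  Re(fft(X * K, inverse = TRUE))[seq_len(n)] / N
}

## smoothed step response of the autonomic channels
ans_envelope <- function(boxcar, fs, tau_s) {
  k <- exp(-(seq(0, 6 * tau_s, by = 1 / fs)) / tau_s)
  conv_causal(boxcar, k / sum(k))
}

## boxcar (0/1) over the pinch periods of one session, on an fs grid
pinch_boxcar <- function(session, fs, n) {
  b <- numeric(n)
  tr <- session$trials
  if (nrow(tr) > 0) {
    for (i in which(!is.na(tr$pinch_onset_s))) {
      i0 <- floor(tr$pinch_onset_s[i] * fs) + 1L
      i1 <- min(n, floor((tr$pinch_onset_s[i] + tr$pinch_duration_s[i]) * fs))
      if (i0 <= i1) b[i0:i1] <- 1
    }
  }
  b
}

#' Simulate a raw recording from a timeline
#'
#' Forward model: true oxy-/deoxyhemoglobin time courses (task response
#' plus systemic oscillations) are mapped to per-channel optical-density
#' changes through the extinction coefficients, path lengths and DPFs, and
#' to raw intensities as `I = I0 * exp(-OD + drift + noise)` at 50 Hz.
#' ECG, respiration flow, continuous blood pressure and skin conductance
#' are generated at 600 Hz with stimulus-locked autonomic responses. The
#' injected ground truth is stored in the result for validation.
#'
#' @param timeline a [generate_timeline()] result.
#' @param config a [sim_config()].
#' @param geometry an [optical_geometry()].
#' @return an object of class `nirs_recording`: sessions (each with
#'   `fnirs` 50 Hz intensity matrix, `bio` 600 Hz biosignal matrix,
#'   `force` reference-force trace and `truth` ground-truth list), plus
#'   the timeline, geometry and config.
#' @export
simulate_recording <- function(timeline, config = sim_config(),
                               geometry = optical_geometry()) {
  stopifnot(inherits(timeline, "nirs_timeline"))
  E <- extinction_matrix(geometry)
  if (abs(det(E)) < 1e-12) stop("extinction matrix is singular")
  set.seed(derive_seed(config$seed, 23L))
  ch <- fnirs_channels(geometry)
  fs_o <- 50; fs_b <- 600
  hrf <- hrf_kernel(fs_o, config$hrf_peak_s, config$hrf_undershoot_s,
                    config$hrf_ratio)
  sessions <- vector("list", length(timeline$sessions))
  for (s in seq_along(timeline$sessions)) {
    ses <- timeline$sessions[[s]]
    n_o <- round(ses$duration_s * fs_o)
    n_b <- n_o * (fs_b / fs_o)   # exact 12:1 ratio with the optical grid
    t_o <- (seq_len(n_o) - 1) / fs_o
    t_b <- (seq_len(n_b) - 1) / fs_b

    box_o <- pinch_boxcar(ses, fs_o, n_o)
    task <- conv_causal(box_o, hrf)
    ph <- runif(3, 0, 2 * pi)
    osc <- config$osc_mayer_mM * sin(2 * pi * config$mayer_freq_hz * t_o + ph[1]) +
      config$osc_cardiac_mM * sin(2 * pi * config$cardiac_freq_hz * t_o + ph[2]) +
      config$osc_resp_mM * sin(2 * pi * config$resp_freq_hz * t_o + ph[3])
    o2hb <- sapply(c("M1", "PMv"), function(L) {
      config$location_gain[[L]] * config$o2hb_amp_mM * task + osc
    })
    hhb <- sapply(c("M1", "PMv"), function(L) {
      config$hhb_ratio * config$location_gain[[L]] * config$o2hb_amp_mM * task -
        0.3 * osc
    })

    fnirs <- matrix(0, n_o, nrow(ch), dimnames = list(NULL, ch$name))
    i0 <- config$baseline_intensity * exp(rnorm(nrow(ch), 0, 0.05))
    u <- t_o / max(t_o[length(t_o)], 1)
    for (j in seq_len(nrow(ch))) {
      wl <- match(ch$wavelength_nm[j], geometry$wavelengths_nm)
      od <- (geometry$eps_o2hb[wl] * o2hb[, ch$location[j]] +
               geometry$eps_hhb[wl] * hhb[, ch$location[j]]) *
        ch$l_cm[j] * ch$dpf[j]
      drift <- config$drift_od * (rnorm(1) * u + rnorm(1) * u^2)
      noise <- if (config$noise_od > 0) rnorm(n_o, 0, config$noise_od) else 0
      fnirs[, j] <- i0[j] * exp(-(od + drift + noise))
    }

    ## ---- autonomic channels ----
    box_b <- pinch_boxcar(ses, fs_b, n_b)
    env <- ans_envelope(box_b, fs_b, config$env_tau_s)
    hr_inst <- config$hr_base_bpm + config$hr_amp_bpm * env
    beat_int <- cumsum(hr_inst / 60) / fs_b
    n_beats <- floor(max(beat_int))
    inc <- pmax(0.4, 1 + rnorm(n_beats, 0, config$rr_jitter))
    thr <- cumsum(inc)
    thr <- thr[thr < max(beat_int)]
    beat_times <- approx(beat_int, t_b, xout = thr, ties = "ordered")$y
    ecg <- add_pulses(numeric(n_b), beat_times, fs_b, width_s = 0.012, amp = 1)
    ecg <- ecg + 0.1 * sin(2 * pi * 0.25 * t_b + ph[3]) +
      rnorm(n_b, 0, config$ecg_noise)

    bp <- config$bp_base + config$bp_amp * env +
      config$bp_mayer_amp * sin(2 * pi * config$mayer_freq_hz * t_b + ph[1]) +
      config$bp_pulse_amp * pulse_shape(beat_int) +
      rnorm(n_b, 0, config$bp_noise)

    br_inst <- config$br_base_bpm + config$br_amp_bpm * env
    resp <- sin(2 * pi * cumsum(br_inst / 60) / fs_b) *
      (1 + 0.1 * sin(2 * pi * 0.01 * t_b)) + rnorm(n_b, 0, config$resp_noise)

    sc <- config$sc_tonic_base +
      config$sc_drift * (rnorm(1) * u_of(t_b) + 0.3 * sin(2 * pi * 0.003 * t_b + ph[2]))
    tr <- ses$trials
    scr_onsets <- numeric(0)
    if (nrow(tr) > 0 && config$scr_amp > 0) {
      for (i in which(!is.na(tr$pinch_onset_s))) {
        on <- tr$pinch_onset_s[i] + runif(1, config$scr_delay_range_s[1],
                                          config$scr_delay_range_s[2])
        scr_onsets <- c(scr_onsets, on)
        sc <- add_bateman(sc, on, fs_b, config$scr_amp,
                          config$scr_rise_s, config$scr_decay_s)
      }
    }
    sc <- sc + rnorm(n_b, 0, config$sc_noise)

    force <- force_stimulus(t_b, box_b)

    sessions[[s]] <- list(
      fnirs = fnirs,
      bio = cbind(ECG = ecg, RESP = resp, BP = bp, SC = sc),
      force = force,
      truth = list(o2hb = o2hb, hhb = hhb, task = task, boxcar_50hz = box_o,
                   envelope = env[seq(1, n_b, by = 120)],
                   beat_times = beat_times, scr_onsets = scr_onsets,
                   i0 = i0))
  }
  structure(list(sessions = sessions, timeline = timeline,
                 geometry = geometry, config = config,
                 fs_fnirs = fs_o, fs_bio = fs_b,
                 artifacts = NULL),
            class = "nirs_recording")
}

u_of <- function(t) t / max(t[length(t)], 1)

## gaussian pulse train (QRS-like spikes)
add_pulses <- function(x, times, fs, width_s, amp) {
  n <- length(x)
  half <- ceiling(4 * width_s * fs)
  for (bt in times) {
    c0 <- round(bt * fs) + 1L
    idx <- max(1L, c0 - half):min(n, c0 + half)
    if (length(idx)) {
      x[idx] <- x[idx] + amp * exp(-((idx - 1) / fs - bt)^2 / (2 * width_s^2))
    }
  }
  x
}

## asymmetric arterial-pulse-like waveform from cumulative beat phase
pulse_shape <- function(phase) {
  f <- phase %% 1
  exp(-((f - 0.15)^2) / (2 * 0.08^2)) + 0.3 * exp(-((f - 0.45)^2) / (2 * 0.1^2))
}

## add a double-exponential (Bateman) phasic response at time `onset`
add_bateman <- function(x, onset, fs, amp, tau_rise, tau_decay) {
  n <- length(x)
  i0 <- round(onset * fs) + 1L
  if (i0 > n) return(x)
  len <- min(n - i0 + 1L, round(10 * tau_decay * fs))
  s <- (0:(len - 1L)) / fs
  k <- exp(-s / tau_decay) - exp(-s / tau_rise)
  k <- k / max(k)
  x[i0:(i0 + len - 1L)] <- x[i0:(i0 + len - 1L)] + amp * k
  x
}

## reference-force trace: truncated Fourier series, 1-4 N during pinching.
## Generated for completeness; never consumed by the decoder.
force_stimulus <- function(t, boxcar) {
  raw <- sin(2 * pi * 0.5 * t) + 0.6 * sin(2 * pi * 1.0 * t + 1) +
    0.4 * sin(2 * pi * 1.1 * t + 2)
  f <- 2.5 + 1.5 * raw / 2
  f * boxcar
}

#' Inject motion artifacts into a recording
#'
#' Step transients of a given optical-density amplitude are inserted at
#' Poisson-distributed times, simultaneously on all 8 channels of one
#' (randomly chosen) location, each lasting `duration_s`. Ground-truth
#' artifact times are recorded in the returned object.
#'
#' @param recording a `nirs_recording`.
#' @param rate artifact rate (events per second, >= 0).
#' @param amplitude step amplitude in log-intensity (OD) units.
#' @param seed integer seed.
#' @param duration_s duration of each step (s).
#' @return the recording with perturbed intensities and an `artifacts`
#'   data.frame (`session`, `time_s`, `location`, `sign`).
#' @export
inject_motion_artifacts <- function(recording, rate, amplitude, seed = 1L,
                                    duration_s = 3) {
  stopifnot(inherits(recording, "nirs_recording"))
  if (rate < 0) stop("rate must be >= 0")
  set.seed(derive_seed(seed, 37L))
  fs <- recording$fs_fnirs
  ch <- fnirs_channels(recording$geometry)
  events <- list()
  if (rate > 0) {
    for (s in seq_along(recording$sessions)) {
      n <- nrow(recording$sessions[[s]]$fnirs)
      span <- n / fs
      tt <- cumsum(rexp(ceiling(rate * span * 3) + 5, rate))
      tt <- tt[tt > 15 & tt < span - 15]
      ## keep events at least a detection-window span apart so each step
      ## has unambiguous ground truth
      if (length(tt) > 1) {
        keep <- c(TRUE, diff(tt) >= duration_s + 7)
        while (!all(keep)) {
          tt <- tt[keep]
          keep <- c(TRUE, diff(tt) >= duration_s + 7)
        }
      }
      for (at in tt) {
        loc <- sample(c("M1", "PMv"), 1)
        sgn <- sample(c(-1, 1), 1)
        cols <- which(ch$location == loc)
        i0 <- round(at * fs) + 1L
        i1 <- min(n, round((at + duration_s) * fs))
        if (amplitude > 0 && i0 <= i1) {
          recording$sessions[[s]]$fnirs[i0:i1, cols] <-
            recording$sessions[[s]]$fnirs[i0:i1, cols] * exp(sgn * amplitude)
        }
        events[[length(events) + 1L]] <-
          data.frame(session = s, time_s = at, location = loc, sign = sgn)
      }
    }
  }
  recording$artifacts <- if (length(events)) do.call(rbind, events) else
    data.frame(session = integer(0), time_s = numeric(0),
               location = character(0), sign = numeric(0))
  recording
}
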