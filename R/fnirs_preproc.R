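#' Downsample raw fNIRS intensities from 50 Hz to 5 Hz
#'
#' Zero-phase 8th-order Butterworth anti-aliasing (2 Hz cutoff) followed
#' by decimation by 10.
#'
#' @param intensity matrix (samples x channels) or vector at 50 Hz.
#' @return the 5 Hz signal.
#' @export
downsample_fnirs <- function(intensity) {
  n <- if (is.null(dim(intensity))) length(intensity) else nrow(intensity)
  if (n < 10L) stop("input shorter than one decimation step: empty output")
  downsample_signal(intensity, 50, 5, cutoff = 2)
}

#' Detect motion artifacts in raw 5 Hz intensity signals
#'
#' For each location-wavelength combination, a 5-point median filter is
#' applied and the signal is scanned with sliding windows of
#' `window_len` samples advancing by `step` samples. In each window the
#' inverse z-score (mean divided by standard deviation) is computed over
#' the full window and over its first half; the window is flagged when the
#' ratio (first half over full window), averaged across the four light
#' paths, exceeds `threshold`. The flag is propagated to every sample of
#' the window, and a location is marked wherever either of its wavelengths
#' is flagged.
#'
#' @param intensity_5hz matrix (samples x 16 channels) of raw intensities
#'   at 5 Hz, in the canonical [fnirs_channels()] order.
#' @param threshold flagging threshold (default 3).
#' @param window_len window length in samples (default 32, i.e. 6.4 s).
#' @param step window advance in samples; the default 8 moves the window
#'   by a quarter of its length so every sample falls in the second half
#'   of some window.
#' @param ratio one of `"half_over_full"` (default) or `"full_over_half"`.
#' @param geometry an [optical_geometry()].
#' @return an object of class `nirs_mask`: a logical matrix
#'   (samples x 2 locations, columns `M1`, `PMv`). Attributes:
#'   `window_len`, `step`, `window_starts`, and `window_flags` — the
#'   per-window decisions (windows x locations) before propagation to
#'   samples.
#' @export
detect_motion_artifacts <- function(intensity_5hz, threshold = 3,
                                    window_len = 32L, step = 8L,
                                    ratio = c("half_over_full", "full_over_half"),
                                    geometry = optical_geometry()) {
  ratio <- match.arg(ratio)
  ch <- fnirs_channels(geometry)
  x <- as.matrix(intensity_5hz)
  if (ncol(x) != nrow(ch)) stop("expected ", nrow(ch), " channels")
  n <- nrow(x)
  mask <- matrix(FALSE, n, 2, dimnames = list(NULL, c("M1", "PMv")))
  if (n < window_len) {
    return(structure(mask, class = "nirs_mask", window_len = window_len,
                     step = step,
                     window_starts = integer(0),
                     window_flags = matrix(FALSE, 0, 2,
                                           dimnames = list(NULL,
                                                           c("M1", "PMv")))))
  }
  xm <- apply(x, 2, function(col) stats::runmed(col, 5))
  starts <- seq(1L, n - window_len + 1L, by = step)
  half <- window_len %/% 2L
  wflags <- matrix(FALSE, length(starts), 2,
                   dimnames = list(NULL, c("M1", "PMv")))
  warned <- FALSE
  for (L in c("M1", "PMv")) {
    for (wl in unique(ch$wavelength_nm)) {
      cols <- which(ch$location == L & ch$wavelength_nm == wl)
      for (wi in seq_along(starts)) {
        w0 <- starts[wi]
        idx <- w0:(w0 + window_len - 1L)
        r <- vapply(cols, function(j) {
          seg <- xm[idx, j]
          s_full <- sd(seg); s_half <- sd(seg[1:half])
          if (s_full == 0 || s_half == 0) {
            if (!warned) {
              warning("constant signal within a window; treated as artifact-free")
              warned <<- TRUE
            }
            return(NA_real_)
          }
          izf <- mean(seg) / s_full
          izh <- mean(seg[1:half]) / s_half
          if (ratio == "half_over_full") izh / izf else izf / izh
        }, numeric(1))
        if (!all(is.na(r)) && mean(r, na.rm = TRUE) > threshold) {
          mask[idx, L] <- TRUE
          wflags[wi, L] <- TRUE
        }
      }
    }
  }
  structure(mask, class = "nirs_mask", window_len = window_len, step = step,
            window_starts = starts, window_flags = wflags)
}

#' Incremental optical-density changes from raw intensities
#'
#' `dOD(t_k) = -ln(I(t_{k+1}) / I(t_k))`; the cumulative sum of the output
#' telescopes to `-ln(I(t_k) / I(t_0))`.
#'
#' @param intensity vector or matrix of strictly positive intensities.
#' @return the incremental optical-density series, one sample shorter than
#'   the input.
#' @export
intensity_to_od <- function(intensity) {
  x <- as.matrix(intensity)
  bad <- which(x <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-positive intensity at sample %d, channel %d",
                 bad[1, 1], bad[1, 2]))
  }
  if (nrow(x) < 2L) stop("need at least two samples")
  out <- -diff(log(x))
  if (is.null(dim(intensity))) drop(out) else out
}

#' Convert optical-density changes to hemoglobin concentration changes
#'
#' Modified Beer-Lambert law for one light path: the two-wavelength
#' optical-density increments are divided by the wavelength-specific DPF,
#' the 2x2 extinction matrix is inverted, and the result is scaled by the
#' inverse source-detector separation, giving incremental `dO2Hb`/`dHHb`
#' in mM.
#'
#' @param od_w1,od_w2 optical-density increment vectors at the first and
#'   second wavelength.
#' @param geometry an [optical_geometry()].
#' @param path light-path index in 1..4 selecting the separation.
#' @return a matrix with columns `O2Hb` and `HHb` (incremental changes).
#' @export
od_to_hemoglobin <- function(od_w1, od_w2, geometry = optical_geometry(),
                             path = 1L) {
  if (!path %in% 1:4) stop("path must be in 1..4")
  E <- extinction_matrix(geometry)
  if (abs(det(E)) < 1e-12) stop("extinction matrix is singular")
  od <- rbind(od_w1 / geometry$dpf[1], od_w2 / geometry$dpf[2])
  conc <- solve(E, od) / geometry$path_lengths_cm[path]
  out <- t(conc)
  colnames(out) <- c("O2Hb", "HHb")
  out
}

#' Session-wise z-normalisation
#'
#' Subtracts the mean and divides by the standard deviation, per session
#' and per channel.
#'
#' @param x vector or matrix (one session), or list of such (sessions).
#' @return the normalised object, same shape.
#' @export
normalize_session <- function(x) {
  norm1 <- function(m) {
    mm <- as.matrix(m)
    s <- apply(mm, 2, sd)
    if (any(s == 0)) {
      stop("zero standard deviation in channel ",
           paste(which(s == 0), collapse = ", "))
    }
    out <- scale(mm, center = TRUE, scale = s)
    attr(out, "scaled:center") <- NULL; attr(out, "scaled:scale") <- NULL
    if (is.null(dim(m))) drop(out) else out
  }
  if (is.list(x)) lapply(x, norm1) else norm1(x)
}

#' Low-pass filter hemoglobin signals (Chebyshev type II)
#'
#' Second-order type-II design with 40 dB stopband attenuation from
#' 0.5 Hz, applied forward-backward (zero phase) at 5 Hz sampling. This
#' suppresses pulsatile and respiratory components.
#'
#' @param x vector or matrix at 5 Hz.
#' @param fs sampling rate (default 5).
#' @param stop_hz stopband edge (default 0.5).
#' @param atten_db stopband attenuation (default 40).
#' @return filtered signal.
#' @export
lowpass_chebyshev <- function(x, fs = 5, stop_hz = 0.5, atten_db = 40) {
  f <- signal::cheby2(2, atten_db, stop_hz / (fs / 2))
  if (is.null(dim(x))) zero_phase(f, x)
  else apply(as.matrix(x), 2, function(col) zero_phase(f, col))
}

#' High-pass filter by cosine-transform truncation
#'
#' Removes drift by zeroing every DCT coefficient whose frequency lies
#' strictly below the cutoff (including the DC term) and transforming
#' back. The default cutoff 1/54 Hz is the reciprocal of the longest
#' within-protocol period.
#'
#' @param x vector or matrix at `fs` Hz.
#' @param fs sampling rate (default 5).
#' @param cutoff_hz cutoff frequency (default 1/54).
#' @return the drift-free signal (mean approximately zero).
#' @export
highpass_dct <- function(x, fs = 5, cutoff_hz = 1 / 54) {
  hp1 <- function(v) {
    n <- length(v)
    X <- dct2(v)
    freq <- (0:(n - 1L)) * fs / (2 * n)
    X[freq < cutoff_hz] <- 0
    idct2(X)
  }
  if (is.null(dim(x))) hp1(x) else apply(as.matrix(x), 2, hp1)
}

#' Full fNIRS preprocessing pipeline
#'
#' Per session: downsample 50 to 5 Hz, screen motion artifacts on the raw
#' 5 Hz intensities, convert to incremental optical density, apply the
#' modified Beer-Lambert law per path, cumulate into hemoglobin time
#' courses anchored at zero, z-normalise session-wise, low-pass
#' (Chebyshev II) and high-pass (DCT truncation).
#'
#' @param recording a `nirs_recording`.
#' @param ma_threshold motion-artifact flagging threshold.
#' @return a list of class `nirs_processed` with elements `sessions` (each
#'   a samples x 16 matrix with columns `O2Hb_M1_p1`, ..., `HHb_PMv_p4`),
#'   `mask` (per-session `nirs_mask`), `fs` (5) and the geometry.
#' @export
preprocess_fnirs <- function(recording, ma_threshold = 3) {
  stopifnot(inherits(recording, "nirs_recording"))
  geometry <- recording$geometry
  ch <- fnirs_channels(geometry)
  out_names <- as.vector(vapply(c("M1", "PMv"), function(L)
    c(sprintf("O2Hb_%s_p%d", L, 1:4), sprintf("HHb_%s_p%d", L, 1:4)),
    character(8)))
  sessions <- list(); masks <- list()
  for (s in seq_along(recording$sessions)) {
    raw5 <- downsample_fnirs(recording$sessions[[s]]$fnirs)
    masks[[s]] <- detect_motion_artifacts(raw5, threshold = ma_threshold,
                                          geometry = geometry)
    n5 <- nrow(raw5)
    hemo <- matrix(0, n5, 16, dimnames = list(NULL, out_names))
    for (L in c("M1", "PMv")) {
      for (p in 1:4) {
        j1 <- which(ch$location == L & ch$path == p &
                      ch$wavelength_nm == geometry$wavelengths_nm[1])
        j2 <- which(ch$location == L & ch$path == p &
                      ch$wavelength_nm == geometry$wavelengths_nm[2])
        od1 <- intensity_to_od(raw5[, j1])
        od2 <- intensity_to_od(raw5[, j2])
        conc <- od_to_hemoglobin(od1, od2, geometry, p)
        hemo[, sprintf("O2Hb_%s_p%d", L, p)] <- c(0, cumsum(conc[, "O2Hb"]))
        hemo[, sprintf("HHb_%s_p%d", L, p)] <- c(0, cumsum(conc[, "HHb"]))
      }
    }
    sessions[[s]] <- hemo
  }
  raw_cumulative <- sessions
  sessions <- normalize_session(sessions)
  sessions <- lapply(sessions, lowpass_chebyshev)
  sessions <- lapply(sessions, highpass_dct)
  structure(list(sessions = sessions, mask = masks, fs = 5,
                 geometry = geometry, unnormalized = raw_cumulative),
            class = "nirs_processed")
}
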