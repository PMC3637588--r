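#' Segment-extraction specification
#'
#' Window length and forward shift of the class-labelled segments.
#' Defaults: 75 samples (15 s at 5 Hz, the shortest rest interval) shifted
#' forward by 25 samples (5 s) to absorb the hemodynamic delay.
#'
#' @param n_window window length in samples.
#' @param n_shift forward shift in samples.
#' @param fs sampling rate of the processed signals.
#' @return a list of class `segment_spec`.
#' @export
segment_spec <- function(n_window = 75L, n_shift = 25L, fs = 5) {
  if (n_window <= 0) stop("n_window must be > 0")
  if (n_shift < 0) stop("n_shift must be >= 0")
  structure(list(n_window = as.integer(n_window),
                 n_shift = as.integer(n_shift), fs = fs),
            class = "segment_spec")
}

#' Extract associated rest-pinching trial pairs
#'
#' One pair per pinching trial (the sham condition contributes none). The
#' active window starts `n_shift` samples after pinch onset; the rest
#' window is anchored at the end of the preceding rest period and shifted
#' forward by the same amount, i.e. `[rest_end - n_window + n_shift,
#' rest_end + n_shift)`. A pair is flagged as motion-affected when either
#' window intersects the artifact mask at either location.
#'
#' @param timeline a `nirs_timeline`.
#' @param mask optional list of per-session `nirs_mask` objects.
#' @param spec a [segment_spec()].
#' @param n_samples optional per-session signal lengths at 5 Hz used for
#'   bounds checking (defaults to the timeline durations).
#' @return data.frame of class `trial_pairs` with columns `pair_id`,
#'   `session`, `condition`, `active_start`, `rest_start` (1-based sample
#'   indices into the session), and `ma_affected`.
#' @export
extract_trial_pairs <- function(timeline, mask = NULL, spec = segment_spec(),
                                n_samples = NULL) {
  stopifnot(inherits(timeline, "nirs_timeline"))
  fs <- spec$fs
  rows <- list()
  pid <- 0L
  for (s in seq_along(timeline$sessions)) {
    ses <- timeline$sessions[[s]]
    n5 <- if (!is.null(n_samples)) n_samples[s] else round(ses$duration_s * fs)
    tr <- ses$trials
    for (i in seq_len(nrow(tr))) {
      if (is.na(tr$pinch_onset_s[i])) next
      onset_i <- round(tr$pinch_onset_s[i] * fs)
      rest_end_i <- round(tr$cue_onset_s[i] * fs)
      a0 <- onset_i + spec$n_shift + 1L
      r0 <- rest_end_i - spec$n_window + spec$n_shift + 1L
      if (a0 < 1L || r0 < 1L || a0 + spec$n_window - 1L > n5 ||
          r0 + spec$n_window - 1L > n5) {
        warning("trial window outside recording bounds; pair dropped")
        next
      }
      pid <- pid + 1L
      ma <- FALSE
      if (!is.null(mask)) {
        m <- mask[[s]]
        idx <- c(a0:(a0 + spec$n_window - 1L), r0:(r0 + spec$n_window - 1L))
        idx <- idx[idx <= nrow(m)]
        ma <- any(m[idx, ])
      }
      rows[[pid]] <- data.frame(pair_id = pid, session = s,
                                condition = tr$condition[i],
                                active_start = a0, rest_start = r0,
                                ma_affected = ma)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(pair_id = integer(0), session = integer(0),
               condition = integer(0), active_start = integer(0),
               rest_start = integer(0), ma_affected = logical(0))
  attr(out, "spec") <- spec
  class(out) <- c("trial_pairs", class(out))
  out
}

## stack the 8 channels of one location for the given pairs:
## rows = samples of active then rest windows per pair
location_columns <- function(location) {
  c(sprintf("O2Hb_%s_p%d", location, 1:4), sprintf("HHb_%s_p%d", location, 1:4))
}

#' Fit least-squares spatial feature weights for one location
#'
#' Stacks the active and rest training segments of the eight preprocessed
#' hemoglobin channels of one location into a design matrix (in seeded
#' random block order), sets the target to one on active rows and zero on
#' rest rows, and solves the least-squares problem for the 8 weights,
#' using the minimum-norm solution on rank deficiency.
#'
#' @param pairs a `trial_pairs` data.frame (training pairs; motion-flagged
#'   pairs are excluded).
#' @param processed a `nirs_processed` object.
#' @param location `"M1"` or `"PMv"`.
#' @param spec a [segment_spec()].
#' @param seed seed for the (irrelevant to the solution) block order.
#' @return numeric vector of 8 weights, named by channel.
#' @export
fit_weights <- function(pairs, processed, location, spec = segment_spec(),
                        seed = 1L) {
  pairs <- pairs[!pairs$ma_affected, , drop = FALSE]
  if (nrow(pairs) == 0) stop("no unflagged training pairs")
  cols <- location_columns(location)
  blocks <- list(); targets <- list()
  k <- 0L
  for (i in seq_len(nrow(pairs))) {
    ses <- processed$sessions[[pairs$session[i]]]
    for (w in c("active", "rest")) {
      st <- if (w == "active") pairs$active_start[i] else pairs$rest_start[i]
      k <- k + 1L
      blocks[[k]] <- ses[st:(st + spec$n_window - 1L), cols, drop = FALSE]
      targets[[k]] <- rep(if (w == "active") 1 else 0, spec$n_window)
    }
  }
  set.seed(derive_seed(seed, 53L))
  ord <- sample(k)
  M <- do.call(rbind, blocks[ord])
  y <- unlist(targets[ord])
  beta <- lstsq_minnorm(M, y)
  names(beta) <- cols
  beta
}

## minimum-norm least squares via SVD
lstsq_minnorm <- function(A, b, tol = 1e-10) {
  sv <- svd(A)
  d <- sv$d
  pos <- d > tol * max(d)
  drop(sv$v[, pos, drop = FALSE] %*%
         ((crossprod(sv$u[, pos, drop = FALSE], b)) / d[pos]))
}

#' Apply spatial feature weights
#'
#' Weighted sum of the eight preprocessed channels of each location,
#' collapsing the 16 hemoglobin signals to one feature signal per
#' location over the full session length.
#'
#' @param processed a `nirs_processed` object.
#' @param weights named list with elements `M1` and `PMv`, each a length-8
#'   weight vector from [fit_weights()].
#' @return list of per-session matrices (samples x 2, columns `M1`,
#'   `PMv`).
#' @export
apply_weights <- function(processed, weights) {
  lapply(processed$sessions, function(ses) {
    out <- sapply(c("M1", "PMv"), function(L) {
      cols <- location_columns(L)
      w <- weights[[L]]
      if (length(w) != length(cols)) stop("channel-count mismatch for ", L)
      drop(ses[, cols, drop = FALSE] %*% w)
    })
    colnames(out) <- c("M1", "PMv")
    out
  })
}

#' Build class-labelled observations
#'
#' Per unflagged trial pair, extracts one rest and one active fixed-length
#' segment. In `fnirs_only` mode the observation is the 2-column feature
#' signal; in `combined` mode the 4 autonomic channels are appended
#' (6 columns).
#'
#' @param pairs a `trial_pairs` data.frame.
#' @param feature_signals per-session feature matrices from
#'   [apply_weights()].
#' @param ans an `ans_features` object (required for `combined`).
#' @param mode `"fnirs_only"` or `"combined"`.
#' @param spec a [segment_spec()].
#' @return list of observations; each is a list with `data`
#'   (`n_window` x d matrix), `label` (`"active"`/`"rest"`) and `pair_id`.
#' @export
build_observations <- function(pairs, feature_signals, ans = NULL,
                               mode = c("fnirs_only", "combined"),
                               spec = segment_spec()) {
  mode <- match.arg(mode)
  if (mode == "combined" && is.null(ans)) {
    stop("combined mode requires biosignal features; ",
         "fall back to fnirs_only if biosignals are unavailable")
  }
  pairs <- pairs[!pairs$ma_affected, , drop = FALSE]
  obs <- list()
  for (i in seq_len(nrow(pairs))) {
    s <- pairs$session[i]
    feat <- feature_signals[[s]]
    for (w in c("rest", "active")) {
      st <- if (w == "active") pairs$active_start[i] else pairs$rest_start[i]
      idx <- st:(st + spec$n_window - 1L)
      m <- feat[idx, , drop = FALSE]
      if (mode == "combined") {
        a <- ans$sessions[[s]]
        if (max(idx) > nrow(a)) stop("biosignal features shorter than window")
        m <- cbind(m, a[idx, , drop = FALSE])
      }
      obs[[length(obs) + 1L]] <- list(data = m, label = w,
                                      pair_id = pairs$pair_id[i])
    }
  }
  obs
}
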