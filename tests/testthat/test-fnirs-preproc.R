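test_that("downsampling preserves the passband and rejects the stopband", {
  x <- rep(3.7, 1000)
  y <- downsample_fnirs(x)
  expect_length(y, 100)
  expect_equal(y, rep(3.7, 100), tolerance = 1e-9)

  t50 <- seq(0, 200, by = 1 / 50)
  slow <- sin(2 * pi * 0.1 * t50)
  ys <- downsample_fnirs(slow)
  mid <- ys[100:(length(ys) - 100)]
  expect_lt(abs(max(mid) - 1), 0.01)          # amplitude within 1 %

  fast <- sin(2 * pi * 10 * t50)
  yf <- downsample_fnirs(fast)
  expect_lt(max(abs(yf[100:(length(yf) - 100)])), 0.1)  # > 90 % attenuated

  expect_error(downsample_fnirs(rnorm(5)), "empty")
})

test_that("optical-density increments follow the incremental definition", {
  expect_equal(intensity_to_od(rep(5, 10)), rep(0, 9))
  expect_equal(intensity_to_od(c(4, 2))[1], log(2), tolerance = 1e-12)
  set.seed(1)
  I <- exp(rnorm(200, 0, 0.1)) * 800
  od <- intensity_to_od(I)
  expect_length(od, 199)
  # telescoping: cumsum equals -ln(I_k / I_0)
  expect_equal(cumsum(od), -log(I[-1] / I[1]), tolerance = 1e-12)
  expect_error(intensity_to_od(c(1, -1, 2)), "non-positive intensity")
  expect_error(intensity_to_od(c(1, 0, 2)), "sample 2")
})

test_that("Beer-Lambert inversion matches an independent linear solve", {
  g <- optical_geometry()
  z <- od_to_hemoglobin(0, 0, g, 1)
  expect_equal(unname(z[1, ]), c(0, 0))

  # independent oracle: dense 2x2 solve of the forward relation
  E <- matrix(c(0.9556, 4.8538, 2.3671, 1.7891), 2, 2, byrow = TRUE)
  dpf <- c(6.51, 5.86)
  oracle <- solve(E, c(0.01 / dpf[1], 0.01 / dpf[2])) / 2
  got <- od_to_hemoglobin(0.01, 0.01, g, 1)
  expect_equal(unname(got[1, ]), oracle, tolerance = 1e-10)

  # round trip: forward-compose then invert is the identity
  set.seed(2)
  conc <- cbind(rnorm(50, 0, 1e-4), rnorm(50, 0, 1e-4))
  for (p in c(2L, 4L)) {
    l <- g$path_lengths_cm[p]
    od1 <- (g$eps_o2hb[1] * conc[, 1] + g$eps_hhb[1] * conc[, 2]) * l * dpf[1]
    od2 <- (g$eps_o2hb[2] * conc[, 1] + g$eps_hhb[2] * conc[, 2]) * l * dpf[2]
    back <- od_to_hemoglobin(od1, od2, g, p)
    expect_equal(unname(back), unname(conc), tolerance = 1e-10)
  }
  expect_error(od_to_hemoglobin(0.1, 0.1, g, 7), "path")
})

test_that("session normalisation is exact, independent and idempotent", {
  z <- normalize_session(c(1, 2, 3))
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)

  s1 <- matrix(rnorm(100, 5, 2), ncol = 2)
  s2 <- matrix(rnorm(100, -3, 0.5), ncol = 2)
  out <- normalize_session(list(s1, s2))
  for (ses in out) {
    expect_equal(colMeans(ses), c(0, 0), tolerance = 1e-9)
    expect_equal(apply(ses, 2, sd), c(1, 1), tolerance = 1e-9)
  }
  twice <- normalize_session(out)
  expect_equal(twice[[1]], out[[1]], tolerance = 1e-12)
  expect_error(normalize_session(rep(2, 10)), "zero standard deviation")
})

test_that("Chebyshev low-pass meets its design response", {
  n <- 3000
  t5 <- (0:(n - 1)) / 5
  dc <- rep(1, n)
  expect_equal(lowpass_chebyshev(dc), dc, tolerance = 1e-9)

  hum <- sin(2 * pi * 1 * t5)
  y <- lowpass_chebyshev(hum)
  expect_lt(max(abs(y[200:(n - 200)])), 10^(-40 / 20))  # >= 40 dB down

  # passband amplitude matches the analytic design response within 1 %
  # (zero-phase application squares the magnitude response)
  f <- signal::cheby2(2, 40, 0.5 / 2.5)
  H <- signal::freqz(f, n = 4096, Fs = 5)
  slow <- sin(2 * pi * 0.05 * t5)
  ys <- lowpass_chebyshev(slow)
  expected <- abs(H$h[which.min(abs(H$f - 0.05))])^2
  expect_lt(abs(max(ys[200:(n - 200)]) - expected), 0.01)
  expect_gt(expected, 0.8)   # the design passes slow hemodynamics
})

test_that("DCT high-pass removes drift below the cutoff only", {
  n <- 3000  # 600 s at 5 Hz
  t5 <- (0:(n - 1)) / 5
  expect_equal(highpass_dct(rep(4, n)), rep(0, n), tolerance = 1e-9)

  below <- sin(2 * pi * 0.005 * t5)
  yb <- highpass_dct(below)
  expect_lt(sum(yb^2) / sum(below^2), 0.01)

  above <- sin(2 * pi * 0.1 * t5)
  ya <- highpass_dct(above)
  expect_lt(abs(sum(ya^2) / sum(above^2) - 1), 0.05)
  expect_lt(abs(mean(ya)), 1e-9)
})

test_that("fft-based cosine transform matches the direct transform matrix", {
  for (n in c(16, 57, 64)) {
    set.seed(n)
    x <- rnorm(n)
    expect_equal(dct2(x), drop(dct_matrix(n) %*% x), tolerance = 1e-9)
    expect_equal(idct2(dct2(x)), x, tolerance = 1e-12)
  }
})

test_that("motion-artifact detector is quiet on stationary noise", {
  set.seed(11)
  x <- matrix(1000 * exp(rnorm(10000 * 16, 0, 5e-4)), 10000, 16)
  m <- detect_motion_artifacts(x)
  # window-level decision false positives under 1 %
  wf <- attr(m, "window_flags")
  expect_equal(nrow(wf), length(attr(m, "window_starts")))
  expect_lt(mean(wf), 0.01)
  # flagged samples are exactly the union of flagged windows
  expect_true(all(m[, "M1"][unlist(lapply(
    which(wf[, "M1"]), function(wi)
      attr(m, "window_starts")[wi] + 0:31))]))
})

test_that("motion-artifact detector flags injected steps", {
  rec <- small_recording(seed = 13, n_sessions = 1, trials_per_condition = 3)
  raw5 <- downsample_fnirs(rec$sessions[[1]]$fnirs)
  noise_sd <- sd(diff(log(raw5[100:1500, 1]))) / sqrt(2)
  recA <- inject_motion_artifacts(rec, rate = 0.02, amplitude = 10 * noise_sd,
                                  seed = 3)
  m <- detect_motion_artifacts(downsample_fnirs(recA$sessions[[1]]$fnirs))
  art <- recA$artifacts
  expect_gt(nrow(art), 2)
  hits <- vapply(seq_len(nrow(art)), function(i) {
    idx <- round(art$time_s[i] * 5) + 1
    any(m[max(1, idx - 3):min(nrow(m), idx + 18), art$location[i]])
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("constant signals yield no artifact windows and a warning", {
  x <- matrix(100, 500, 16)
  expect_warning(m <- detect_motion_artifacts(x), "constant")
  expect_false(any(m))
})

test_that("full preprocessing recovers injected hemodynamics", {
  rec <- clean_recording(seed = 2)
  proc <- preprocess_fnirs(rec)
  un <- proc$unnormalized[[1]]
  truth5 <- rec$sessions[[1]]$truth$o2hb[seq(1, nrow(rec$sessions[[1]]$fnirs),
                                             by = 10), "M1"]
  n <- min(length(truth5), nrow(un))
  rel_rmse <- sqrt(mean((un[1:n, "O2Hb_M1_p1"] -
                           (truth5[1:n] - truth5[1]))^2)) /
    diff(range(truth5))
  expect_lt(rel_rmse, 0.01)   # < 1 % before normalisation

  # task-evoked contrast survives the full (normalised, filtered) pipeline
  pairs <- extract_trial_pairs(rec$timeline, NULL,
                               n_samples = vapply(proc$sessions, nrow,
                                                  integer(1)))
  spec <- segment_spec()
  sesp <- proc$sessions[[1]]
  d <- vapply(seq_len(nrow(pairs)), function(i) {
    mean(sesp[pairs$active_start[i]:(pairs$active_start[i] + 74), "O2Hb_M1_p1"]) -
      mean(sesp[pairs$rest_start[i]:(pairs$rest_start[i] + 74), "O2Hb_M1_p1"])
  }, numeric(1))
  expect_true(all(d > 0))

  # determinism
  proc2 <- preprocess_fnirs(rec)
  expect_identical(proc$sessions, proc2$sessions)
})
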