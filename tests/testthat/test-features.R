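test_that("trial-pair extraction yields one pair per pinching trial", {
  tl <- generate_timeline(timeline_config(), seed = 1)
  pairs <- extract_trial_pairs(tl, NULL)
  expect_equal(nrow(pairs), 30)
  expect_true(all(pairs$condition %in% c(1, 2, 4)))
  expect_false(any(pairs$ma_affected))

  # all-true mask flags every pair
  n5 <- vapply(tl$sessions, function(s) as.integer(round(s$duration_s * 5)),
               integer(1))
  full_mask <- lapply(n5, function(n)
    matrix(TRUE, n, 2, dimnames = list(NULL, c("M1", "PMv"))))
  pf <- extract_trial_pairs(tl, full_mask)
  expect_true(all(pf$ma_affected))
})

test_that("window geometry is adjacent and non-overlapping at zero shift", {
  # rest period of exactly 15 s, shift 0: windows must touch, not overlap
  tl <- small_timeline(seed = 3)
  tr <- tl$sessions[[1]]$trials
  tr$rest_duration_s[] <- 15
  tr$cue_onset_s <- tr$start_s + 15
  tr$pinch_onset_s <- ifelse(is.na(tr$pinch_onset_s), NA,
                             tr$cue_onset_s + tr$cue_duration_s)
  tl$sessions[[1]]$trials <- tr
  shift0 <- segment_spec(n_window = 75, n_shift = 0)
  pairs <- extract_trial_pairs(tl, NULL, spec = shift0)
  gap <- pairs$active_start - (pairs$rest_start + 74)
  # cue period separates rest end from pinch onset; for the uncued
  # condition the two windows are exactly adjacent
  uncued <- pairs$condition == 4
  expect_true(all(gap[uncued] == 1))
  expect_true(all(gap >= 1))
})

test_that("least-squares weights match the normal-equations oracle", {
  set.seed(7)
  # noisy recording: noise-free channels are exactly collinear across
  # paths, which would make the normal-equations oracle itself singular
  rec <- small_recording(seed = 4, trials_per_condition = 2)
  proc <- preprocess_fnirs(rec)
  pairs <- extract_trial_pairs(rec$timeline, NULL,
                               n_samples = vapply(proc$sessions, nrow,
                                                  integer(1)))
  beta <- fit_weights(pairs, proc, "M1", seed = 5)
  expect_length(beta, 8)
  expect_true(all(is.finite(beta)))

  # oracle: (M'M)^-1 M'y on the same stacked design
  spec <- segment_spec()
  cols <- nirsbci:::location_columns("M1")
  Ms <- list(); ys <- list()
  for (i in seq_len(nrow(pairs))) {
    ses <- proc$sessions[[pairs$session[i]]]
    Ms[[2 * i - 1]] <- ses[pairs$active_start[i]:(pairs$active_start[i] + 74),
                           cols]
    ys[[2 * i - 1]] <- rep(1, 75)
    Ms[[2 * i]] <- ses[pairs$rest_start[i]:(pairs$rest_start[i] + 74), cols]
    ys[[2 * i]] <- rep(0, 75)
  }
  M <- do.call(rbind, Ms); y <- unlist(ys)
  oracle <- solve(crossprod(M), crossprod(M, y))
  expect_equal(unname(beta), unname(drop(oracle)), tolerance = 1e-8)

  # block order is irrelevant to the solution
  beta2 <- fit_weights(pairs, proc, "M1", seed = 99)
  expect_equal(beta, beta2, tolerance = 1e-8)

  # optimality: residual beats 100 random weight vectors
  rss <- function(b) sum((M %*% b - y)^2)
  r0 <- rss(beta)
  rand <- replicate(100, rss(beta + rnorm(8, 0, 0.5)))
  expect_true(all(rand >= r0))
})

test_that("weight fitting ignores test-pair data (no leakage)", {
  rec <- small_recording(seed = 14, trials_per_condition = 3)
  proc <- preprocess_fnirs(rec)
  pairs <- extract_trial_pairs(rec$timeline, proc$mask,
                               n_samples = vapply(proc$sessions, nrow,
                                                  integer(1)))
  train <- pairs[1:4, ]
  beta <- fit_weights(train, proc, "M1", seed = 1)
  # corrupt data inside the held-out pairs' windows only
  proc2 <- proc
  for (i in 5:nrow(pairs)) {
    idx <- pairs$active_start[i]:(pairs$active_start[i] + 74)
    proc2$sessions[[pairs$session[i]]][idx, ] <- 1e6
  }
  beta2 <- fit_weights(train, proc2, "M1", seed = 1)
  expect_identical(beta, beta2)
})

test_that("unit and zero weights behave linearly", {
  rec <- small_recording(seed = 15)
  proc <- preprocess_fnirs(rec)
  w_unit <- list(M1 = c(1, rep(0, 7)), PMv = rep(0, 8))
  f <- apply_weights(proc, w_unit)
  expect_equal(f[[1]][, "M1"], unname(proc$sessions[[1]][, "O2Hb_M1_p1"]))
  expect_equal(f[[1]][, "PMv"], rep(0, nrow(proc$sessions[[1]])))

  set.seed(3)
  b <- rnorm(8)
  w1 <- list(M1 = b, PMv = b)
  w3 <- list(M1 = 3 * b, PMv = 3 * b)
  expect_equal(3 * apply_weights(proc, w1)[[1]],
               apply_weights(proc, w3)[[1]], tolerance = 1e-12)
  expect_error(apply_weights(proc, list(M1 = b[1:5], PMv = b)), "mismatch")
})

test_that("observation assembly obeys shape, mode and exclusion contracts", {
  rec <- small_recording(seed = 16, n_sessions = 2, trials_per_condition = 3)
  proc <- preprocess_fnirs(rec)
  ans <- assemble_biosignals(rec)
  pairs <- extract_trial_pairs(rec$timeline, NULL,
                               n_samples = vapply(proc$sessions, nrow,
                                                  integer(1)))
  pairs <- pairs[1:10, ]
  w <- list(M1 = rnorm(8), PMv = rnorm(8))
  feats <- apply_weights(proc, w)

  obs_f <- build_observations(pairs, feats, NULL, "fnirs_only")
  expect_length(obs_f, 20)
  expect_true(all(vapply(obs_f, function(o)
    all(dim(o$data) == c(75, 2)), logical(1))))
  expect_equal(sum(vapply(obs_f, function(o) o$label == "active", logical(1))),
               10)

  obs_c <- build_observations(pairs, feats, ans, "combined")
  expect_length(obs_c, 20)
  expect_true(all(vapply(obs_c, function(o)
    all(dim(o$data) == c(75, 6)), logical(1))))

  pairs$ma_affected[1:3] <- TRUE
  obs_x <- build_observations(pairs, feats, ans, "combined")
  expect_length(obs_x, 14)

  expect_error(build_observations(pairs, feats, NULL, "combined"),
               "fnirs_only")
})

test_that("strong noise-free effects separate every trial at M1", {
  rec <- clean_recording(seed = 18, trials_per_condition = 3)
  proc <- preprocess_fnirs(rec)
  pairs <- extract_trial_pairs(rec$timeline, NULL,
                               n_samples = vapply(proc$sessions, nrow,
                                                  integer(1)))
  beta <- fit_weights(pairs, proc, "M1")
  feats <- apply_weights(proc, list(M1 = beta, PMv = beta * 0))
  obs <- build_observations(pairs, feats, NULL, "fnirs_only")
  mean_m1 <- vapply(obs, function(o) mean(o$data[, "M1"]), numeric(1))
  lab <- vapply(obs, function(o) o$label, character(1))
  by_pair <- split(seq_along(obs), vapply(obs, `[[`, integer(1), "pair_id"))
  for (ix in by_pair) {
    expect_gt(mean_m1[ix[lab[ix] == "active"]], mean_m1[ix[lab[ix] == "rest"]])
  }
})

test_that("rank-deficient designs take the minimum-norm solution", {
  set.seed(6)
  A <- matrix(rnorm(60 * 4), 60, 4)
  A <- cbind(A, A[, 1] + A[, 2])          # exactly collinear column
  b <- rnorm(60)
  beta <- nirsbci:::lstsq_minnorm(A, b)
  # svd pseudo-inverse oracle
  sv <- svd(A)
  keep <- sv$d > 1e-10 * max(sv$d)
  pinv <- sv$v[, keep] %*% diag(1 / sv$d[keep]) %*% t(sv$u[, keep])
  expect_equal(beta, drop(pinv %*% b), tolerance = 1e-10)
  # any other solution of the normal equations has larger norm
  null_vec <- c(1, 1, 0, 0, -1) / sqrt(3)
  alt <- beta + 0.5 * null_vec
  expect_equal(drop(crossprod(A, A %*% alt - b)), rep(0, 5), tolerance = 1e-8)
  expect_lt(sum(beta^2), sum(alt^2))
})
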