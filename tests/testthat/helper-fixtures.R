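# Shared fixtures and independent oracles, built in code at test time.

# small protocol: short baselines, 2 trials per condition per session
small_timeline <- function(n_sessions = 1L, trials_per_condition = 2L,
                           seed = 1L) {
  generate_timeline(
    timeline_config(n_sessions = n_sessions,
                    trials_per_condition = trials_per_condition,
                    baseline_start_s = 60, baseline_end_s = 40),
    seed = seed)
}

small_recording <- function(seed = 2L, n_sessions = 1L,
                            trials_per_condition = 2L, ...) {
  tl <- small_timeline(n_sessions, trials_per_condition, seed = seed)
  simulate_recording(tl, sim_config(seed = seed + 1L, ...))
}

# noise- and contamination-free simulation for round-trip identities
clean_recording <- function(seed = 2L, n_sessions = 1L,
                            trials_per_condition = 2L) {
  small_recording(seed, n_sessions, trials_per_condition,
                  noise_od = 0, drift_od = 0, osc_cardiac_mM = 0,
                  osc_resp_mM = 0, osc_mayer_mM = 0)
}

# independent oracle: forward probability by brute-force enumeration over
# all state paths (exponential in T; only for tiny instances)
brute_force_loglik <- function(hmm, X) {
  Ns <- hmm$topology$n_states
  Nm <- hmm$topology$n_mix
  T_len <- nrow(X)
  # mixture log-density, combined by log-sum-exp (direct-space densities
  # underflow for far-out observations)
  log_dens <- function(x, s) {
    lc <- vapply(seq_len(Nm), function(m) {
      S <- hmm$sigma[[s]][[m]]
      mu <- hmm$mu[[s]][[m]]
      log(hmm$w[s, m]) -
        0.5 * drop(t(x - mu) %*% solve(S) %*% (x - mu)) -
        0.5 * (length(x) * log(2 * pi) + determinant(S)$modulus)
    }, numeric(1))
    mx <- max(lc)
    mx + log(sum(exp(lc - mx)))
  }
  paths <- as.matrix(expand.grid(rep(list(seq_len(Ns)), T_len)))
  # per-path log probabilities, combined by log-sum-exp (tiny densities
  # underflow in direct space)
  logp <- vapply(seq_len(nrow(paths)), function(r) {
    p <- paths[r, ]
    lp <- log(hmm$pi[p[1]]) + log_dens(X[1, ], p[1])
    if (T_len > 1) {
      for (t in 2:T_len) {
        lp <- lp + log(hmm$A[p[t - 1], p[t]]) + log_dens(X[t, ], p[t])
      }
    }
    lp
  }, numeric(1))
  m <- max(logp)
  m + log(sum(exp(logp - m)))
}

# a well-separated pair of single-state HMMs for classification checks
toy_hmm <- function(mu, d = 2, var = 0.5) {
  structure(list(pi = 1, A = matrix(1, 1, 1), w = matrix(1, 1, 1),
                 mu = list(list(rep(mu, d))),
                 sigma = list(list(diag(d) * var)),
                 topology = hmm_topology(1, 1), d = d, trained = TRUE),
            class = "nirs_hmm")
}

# random left-to-right HMM with given topology for structural tests
random_lr_hmm <- function(Ns, Nm = 1, d = 2, seed = 1) {
  set.seed(seed)
  obs <- lapply(1:4, function(i) matrix(rnorm(10 * Ns * d), 10 * Ns, d))
  init_hmm(obs, hmm_topology(Ns, Nm), seed = seed)
}

# direct O(N^2) DCT-II matrix, oracle for the fft-based transform
dct_matrix <- function(n) {
  outer(0:(n - 1), 0:(n - 1), function(k, nn) cos(pi * (2 * nn + 1) * k / (2 * n)))
}

# labelled observation list sampled from two separated HMMs
labelled_obs <- function(n_pairs, mu_active = 1.5, T_len = 20, d = 2,
                         seed = 1) {
  a <- simulate_hmm(toy_hmm(mu_active, d), T_len, n_pairs, seed = seed)
  r <- simulate_hmm(toy_hmm(0, d), T_len, n_pairs, seed = seed + 1)
  out <- list()
  for (i in seq_len(n_pairs)) {
    out[[length(out) + 1L]] <- list(data = a[[i]], label = "active", pair_id = i)
    out[[length(out) + 1L]] <- list(data = r[[i]], label = "rest", pair_id = i)
  }
  out
}
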