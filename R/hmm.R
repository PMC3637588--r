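#' Model topology
#'
#' Number of hidden states and Gaussian mixtures per state of a
#' left-to-right hidden Markov model.
#'
#' @param n_states number of states (>= 1).
#' @param n_mix mixtures per state (>= 1).
#' @return a list of class `hmm_topology`.
#' @export
hmm_topology <- function(n_states = 1L, n_mix = 1L) {
  if (n_states < 1 || n_mix < 1) stop("n_states and n_mix must be >= 1")
  structure(list(n_states = as.integer(n_states), n_mix = as.integer(n_mix)),
            class = "hmm_topology")
}

#' Default topology grid
#'
#' All combinations of 1-5 states and 1-2 mixtures (10 topologies).
#'
#' @param n_states,n_mix vectors of values to cross.
#' @return list of [hmm_topology()] objects.
#' @export
topology_grid <- function(n_states = 1:5, n_mix = 1:2) {
  g <- expand.grid(n_states = n_states, n_mix = n_mix)
  g <- g[order(g$n_states, g$n_mix), ]
  lapply(seq_len(nrow(g)), function(i) hmm_topology(g$n_states[i], g$n_mix[i]))
}

## observations -> 3D checks and pooled matrix (sequences stacked
## contiguously: rows 1..T are sequence 1, etc.)
obs_matrix_list <- function(observations) {
  if (is.matrix(observations)) return(list(observations))
  if (is.list(observations) && !is.null(observations$data)) {
    observations <- list(observations)
  }
  lapply(observations, function(o) {
    m <- if (is.list(o) && !is.null(o$data)) o$data else o
    as.matrix(m)
  })
}

## log N(x; mu, Sigma) for all rows of X, via Cholesky
mvn_logdens <- function(X, mu, chol_sigma) {
  d <- ncol(X)
  z <- backsolve(chol_sigma, t(X) - mu, transpose = TRUE)
  -0.5 * d * log(2 * pi) - sum(log(diag(chol_sigma))) - 0.5 * colSums(z^2)
}

## per-state log emission densities for pooled rows; returns list:
##  $logb  N x Ns (state log densities)
##  $logphi N x Ns x Nm (component log densities)
emission_logdens <- function(hmm, X) {
  Ns <- hmm$topology$n_states; Nm <- hmm$topology$n_mix
  N <- nrow(X)
  logphi <- array(-Inf, c(N, Ns, Nm))
  for (s in seq_len(Ns)) {
    for (m in seq_len(Nm)) {
      logphi[, s, m] <- mvn_logdens(X, hmm$mu[[s]][[m]], hmm$chol[[s]][[m]])
    }
  }
  logb <- matrix(0, N, Ns)
  for (s in seq_len(Ns)) {
    lw <- matrix(log(hmm$w[s, ]), N, Nm, byrow = TRUE)
    logb[, s] <- logsumexp_rows(matrix(lw + logphi[, s, ], N, Nm))
  }
  list(logb = logb, logphi = logphi)
}

## cache Cholesky factors of the covariance matrices
with_chol <- function(hmm) {
  hmm$chol <- lapply(hmm$sigma, function(per_state)
    lapply(per_state, function(S) chol(S)))
  hmm
}

## batched log-domain forward pass for sequences of equal length T.
## logb_state: list over states of T x nseq matrices.
## Returns list(alpha = T x nseq x Ns array, loglik = per-sequence vector).
forward_batch <- function(hmm, logb_state, keep_alpha = FALSE) {
  Ns <- hmm$topology$n_states
  T_len <- nrow(logb_state[[1]])
  nseq <- ncol(logb_state[[1]])
  lA <- log(hmm$A)
  lpi <- log(hmm$pi)
  alpha <- matrix(rep(lpi, each = nseq), nseq, Ns)
  for (j in seq_len(Ns)) alpha[, j] <- alpha[, j] + logb_state[[j]][1, ]
  alphas <- if (keep_alpha) array(NA_real_, c(T_len, nseq, Ns)) else NULL
  if (keep_alpha) alphas[1, , ] <- alpha
  if (T_len > 1) {
    for (t in 2:T_len) {
      newa <- matrix(-Inf, nseq, Ns)
      for (j in seq_len(Ns)) {
        acc <- alpha[, j] + lA[j, j]
        if (j > 1 && is.finite(lA[j - 1, j])) {
          acc <- logaddexp(acc, alpha[, j - 1] + lA[j - 1, j])
        }
        newa[, j] <- acc + logb_state[[j]][t, ]
      }
      alpha <- newa
      if (keep_alpha) alphas[t, , ] <- alpha
    }
  }
  ll <- logsumexp_rows(alpha)
  list(alpha = alphas, last = alpha, loglik = ll)
}

## batched log-domain backward pass; returns T x nseq x Ns array
backward_batch <- function(hmm, logb_state) {
  Ns <- hmm$topology$n_states
  T_len <- nrow(logb_state[[1]])
  nseq <- ncol(logb_state[[1]])
  lA <- log(hmm$A)
  betas <- array(NA_real_, c(T_len, nseq, Ns))
  betas[T_len, , ] <- 0
  if (T_len > 1) {
    for (t in (T_len - 1):1) {
      for (i in seq_len(Ns)) {
        acc <- lA[i, i] + logb_state[[i]][t + 1, ] + betas[t + 1, , i]
        if (i < Ns && is.finite(lA[i, i + 1])) {
          acc <- logaddexp(acc, lA[i, i + 1] + logb_state[[i + 1]][t + 1, ] +
                             betas[t + 1, , i + 1])
        }
        betas[t, , i] <- acc
      }
    }
  }
  betas
}

## split pooled N x Ns log-densities into per-state T x nseq matrices
split_logb <- function(logb, T_len) {
  lapply(seq_len(ncol(logb)), function(s) matrix(logb[, s], nrow = T_len))
}

#' Log-likelihood of observations under an HMM
#'
#' Exact forward-algorithm `log P(O | HMM)` with log-domain scaling.
#'
#' @param hmm a trained or initial HMM (from [init_hmm()]/[train_hmm()]).
#' @param observations a single matrix (T x d), an observation list entry,
#'   or a list of them (equal lengths are processed in one batch).
#' @return numeric vector of per-sequence log-likelihoods.
#' @export
log_likelihood <- function(hmm, observations) {
  seqs <- obs_matrix_list(observations)
  d <- ncol(seqs[[1]])
  if (d != hmm$d) stop("observation dimension ", d, " does not match model (",
                       hmm$d, ")")
  lens <- vapply(seqs, nrow, integer(1))
  out <- numeric(length(seqs))
  hmm <- with_chol(hmm)
  for (L in unique(lens)) {
    idx <- which(lens == L)
    X <- do.call(rbind, seqs[idx])
    em <- emission_logdens(hmm, X)
    lbs <- split_logb(em$logb, L)
    out[idx] <- forward_batch(hmm, lbs)$loglik
  }
  out
}

#' Initialise a left-to-right mixture HMM
#'
#' Pooled observation rows are grouped by k-means into
#' `n_states * n_mix` clusters; clusters are assigned to state/mixture
#' slots in order of their temporal centroid (mean within-sequence time
#' index), initialising means, full covariances and mixture weights. The
#' allowed transition entries (self and right neighbour) are drawn
#' uniformly and row-normalised; the start distribution is fixed on the
#' leftmost state.
#'
#' @param observations list of observations (matrices or `$data` lists).
#' @param topology an [hmm_topology()].
#' @param seed integer seed (k-means and transition draws).
#' @param cov_floor minimum covariance eigenvalue.
#' @return an object of class `nirs_hmm`.
#' @export
init_hmm <- function(observations, topology, seed = 1L, cov_floor = 1e-6) {
  seqs <- obs_matrix_list(observations)
  X <- do.call(rbind, seqs)
  d <- ncol(X)
  Ns <- topology$n_states; Nm <- topology$n_mix
  k <- Ns * Nm
  if (nrow(X) < k) stop("fewer observation rows than clusters")
  tidx <- unlist(lapply(seqs, function(m) seq_len(nrow(m))))
  set.seed(derive_seed(seed, 71L))
  if (k == 1L) {
    cl <- rep(1L, nrow(X))
  } else {
    km <- kmeans(X, centers = k, nstart = 5, iter.max = 100)
    cl <- km$cluster
  }
  cent_t <- vapply(seq_len(k), function(c) mean(tidx[cl == c]), numeric(1))
  ord <- order(cent_t)
  mu <- vector("list", Ns); sigma <- vector("list", Ns)
  w <- matrix(0, Ns, Nm)
  pooled_cov <- floor_cov(cov(X), cov_floor)
  for (s in seq_len(Ns)) {
    mu[[s]] <- vector("list", Nm); sigma[[s]] <- vector("list", Nm)
    for (m in seq_len(Nm)) {
      c_id <- ord[(s - 1L) * Nm + m]
      rows <- which(cl == c_id)
      w[s, m] <- length(rows)
      mu[[s]][[m]] <- colMeans(X[rows, , drop = FALSE])
      sigma[[s]][[m]] <- if (length(rows) > d + 1) {
        floor_cov(cov(X[rows, , drop = FALSE]), cov_floor)
      } else pooled_cov
    }
  }
  w <- w / rowSums(w)
  A <- matrix(0, Ns, Ns)
  for (s in seq_len(Ns)) {
    if (s < Ns) {
      p <- runif(2)
      A[s, s:(s + 1L)] <- p / sum(p)
    } else {
      A[s, s] <- 1
    }
  }
  structure(list(pi = c(1, rep(0, Ns - 1L)), A = A, w = w, mu = mu,
                 sigma = sigma, topology = topology, d = d,
                 trained = FALSE),
            class = "nirs_hmm")
}

## clamp covariance eigenvalues from below and symmetrise
floor_cov <- function(S, floor_val) {
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  vals <- pmax(e$values, floor_val)
  S2 <- e$vectors %*% (vals * t(e$vectors))
  (S2 + t(S2)) / 2
}

#' EM (Baum-Welch) training of a left-to-right mixture HMM
#'
#' Expectation-maximisation for Gaussian-mixture emissions respecting the
#' left-to-right transition mask. The total training log-likelihood is
#' non-decreasing across iterations; covariances are floored at
#' `cov_floor` (eigenvalues) to guard against collapse.
#'
#' @param observations list of observations (all of equal length).
#' @param initial an initialised `nirs_hmm`.
#' @param max_iter maximum EM iterations.
#' @param tol relative log-likelihood improvement for convergence.
#' @param cov_floor minimum covariance eigenvalue.
#' @return the trained `nirs_hmm`, with fields `loglik_trace` and
#'   `converged`.
#' @export
train_hmm <- function(observations, initial, max_iter = 100L, tol = 1e-6,
                      cov_floor = 1e-6) {
  seqs <- obs_matrix_list(observations)
  lens <- vapply(seqs, nrow, integer(1))
  if (length(unique(lens)) != 1L) stop("all observations must share one length")
  d <- ncol(seqs[[1]])
  if (d != initial$d) stop("observation dimension mismatch")
  T_len <- lens[1]
  nseq <- length(seqs)
  X <- do.call(rbind, seqs)     # rows: seq-major, time within sequence
  ## reorder pooled rows to time-major blocks for split_logb:
  ## we instead keep seq-major and build T x nseq via byrow reshaping
  hmm <- initial
  Ns <- hmm$topology$n_states; Nm <- hmm$topology$n_mix
  trace <- numeric(0)
  warned_floor <- FALSE
  for (iter in seq_len(max_iter)) {
    hmm <- with_chol(hmm)
    em <- emission_logdens(hmm, X)
    ## pooled row r of sequence q, time t is r = (q-1)*T + t
    lbs <- lapply(seq_len(Ns), function(s)
      matrix(em$logb[, s], nrow = T_len, ncol = nseq))
    fwd <- forward_batch(hmm, lbs, keep_alpha = TRUE)
    bwd <- backward_batch(hmm, lbs)
    ll_total <- sum(fwd$loglik)
    trace <- c(trace, ll_total)
    ## ---- E step ----
    ## gamma over pooled rows
    gam <- array(NA_real_, c(T_len, nseq, Ns))
    for (s in seq_len(Ns)) {
      gam[, , s] <- fwd$alpha[, , s] + bwd[, , s] -
        matrix(fwd$loglik, T_len, nseq, byrow = TRUE)
    }
    gam <- exp(gam)
    gam_pooled <- matrix(aperm(gam, c(1, 2, 3)), T_len * nseq, Ns)
    ## mixture responsibilities on pooled rows
    resp <- array(0, c(T_len * nseq, Ns, Nm))
    for (s in seq_len(Ns)) {
      lw <- matrix(log(hmm$w[s, ]), T_len * nseq, Nm, byrow = TRUE)
      comp <- lw + matrix(em$logphi[, s, ], T_len * nseq, Nm)
      comp <- exp(comp - em$logb[, s])
      resp[, s, ] <- gam_pooled[, s] * comp
    }
    ## xi sums over allowed transitions
    xi <- matrix(0, Ns, Ns)
    if (T_len > 1 && Ns >= 1) {
      lA <- log(hmm$A)
      for (t in seq_len(T_len - 1L)) {
        for (i in seq_len(Ns)) {
          for (j in i:min(Ns, i + 1L)) {
            if (!is.finite(lA[i, j])) next
            v <- fwd$alpha[t, , i] + lA[i, j] + lbs[[j]][t + 1L, ] +
              bwd[t + 1L, , j] - fwd$loglik
            xi[i, j] <- xi[i, j] + sum(exp(v))
          }
        }
      }
    }
    ## ---- M step ----
    newA <- hmm$A
    for (i in seq_len(Ns - 1L)) {
      tot <- xi[i, i] + xi[i, i + 1L]
      if (tot > 1e-12) newA[i, i:(i + 1L)] <- xi[i, i:(i + 1L)] / tot
    }
    if (Ns >= 1) { newA[Ns, ] <- 0; newA[Ns, Ns] <- 1 }
    newW <- hmm$w; newMu <- hmm$mu; newSigma <- hmm$sigma
    for (s in seq_len(Ns)) {
      occ_m <- colSums(matrix(resp[, s, ], ncol = Nm))
      if (sum(occ_m) < 1e-10) next  # starved state: keep parameters
      newW[s, ] <- occ_m / sum(occ_m)
      for (m in seq_len(Nm)) {
        r <- resp[, s, m]
        if (occ_m[m] < 1e-10) next
        mu_sm <- colSums(X * r) / occ_m[m]
        Xc <- sweep(X, 2, mu_sm)
        S <- crossprod(Xc * sqrt(r)) / occ_m[m]
        Sf <- floor_cov(S, cov_floor)
        if (!warned_floor && min(eigen(S, symmetric = TRUE,
                                       only.values = TRUE)$values) < cov_floor) {
          warning("covariance floored during EM")
          warned_floor <- TRUE
        }
        newMu[[s]][[m]] <- mu_sm
        newSigma[[s]][[m]] <- Sf
      }
    }
    prev <- hmm
    hmm$A <- newA; hmm$w <- newW; hmm$mu <- newMu; hmm$sigma <- newSigma
    if (iter > 1) {
      rel <- (trace[iter] - trace[iter - 1L]) /
        max(abs(trace[iter - 1L]), 1e-12)
      if (abs(rel) < tol) {
        hmm <- prev  # parameters that achieved the last evaluated loglik
        hmm$converged <- TRUE
        break
      }
    }
    hmm$converged <- FALSE
  }
  hmm$chol <- NULL
  hmm$loglik_trace <- trace
  hmm$trained <- TRUE
  if (is.null(hmm$converged)) hmm$converged <- FALSE
  hmm
}

#' Restart-selection score
#'
#' The likelihood-distance-weighted training accuracy: with
#' `D(i) = LL_active(i) - LL_rest(i)` per training trial, a trial is
#' assigned `active` when `D > 0` and `rest` otherwise; the score is the
#' summed `|D|` of correctly signed trials over the summed `|D|` of all
#' trials. Zero differences carry no weight; if every difference is zero
#' the score is defined as 0 with a warning.
#'
#' @param D numeric vector of log-likelihood differences.
#' @param labels true labels, `"active"`/`"rest"`.
#' @return the score in \[0, 1\].
#' @export
kappa_score <- function(D, labels) {
  stopifnot(length(D) == length(labels))
  tot <- sum(abs(D))
  if (tot == 0) {
    warning("all log-likelihood differences are zero; score set to 0")
    return(0)
  }
  correct <- (D > 0 & labels == "active") | (D < 0 & labels == "rest")
  sum(abs(D)[correct]) / tot
}

#' Select the best model pair across restarts
#'
#' Evaluates every combination of candidate active and rest models on the
#' training observations and returns the pair maximising the
#' likelihood-weighted training accuracy [kappa_score()].
#'
#' @param candidates_active,candidates_rest lists of trained `nirs_hmm`
#'   models (restarts).
#' @param observations training observation list (entries with `$data`
#'   and `$label`).
#' @return object of class `dual_hmm`: `hmm_active`, `hmm_rest`, `kappa`,
#'   `topology`.
#' @export
select_model_pair <- function(candidates_active, candidates_rest,
                              observations) {
  labels <- vapply(observations, function(o) o$label, character(1))
  lla <- vapply(candidates_active, function(h) log_likelihood(h, observations),
                numeric(length(observations)))
  llr <- vapply(candidates_rest, function(h) log_likelihood(h, observations),
                numeric(length(observations)))
  best <- c(NA_integer_, NA_integer_); best_k <- -Inf
  for (a in seq_along(candidates_active)) {
    for (r in seq_along(candidates_rest)) {
      k <- suppressWarnings(kappa_score(lla[, a] - llr[, r], labels))
      if (k > best_k) { best_k <- k; best <- c(a, r) }
    }
  }
  if (best_k == 0) warning("best model pair has zero selection score")
  structure(list(hmm_active = candidates_active[[best[1]]],
                 hmm_rest = candidates_rest[[best[2]]],
                 kappa = best_k,
                 topology = candidates_active[[best[1]]]$topology),
            class = "dual_hmm")
}

#' Classify an observation with a dual HMM
#'
#' `active` if and only if the active model's log-likelihood strictly
#' exceeds the rest model's; ties resolve to `rest`.
#'
#' @param classifier a `dual_hmm` from [select_model_pair()].
#' @param observations one observation or a list.
#' @return character vector of labels.
#' @export
classify_observation <- function(classifier, observations) {
  lla <- log_likelihood(classifier$hmm_active, observations)
  llr <- log_likelihood(classifier$hmm_rest, observations)
  ifelse(lla > llr, "active", "rest")
}

#' Train candidate models and select a dual classifier
#'
#' Convenience wrapper: per class, runs `n_restarts` seeded
#' initialisations and EM fits, then selects the pair with
#' [select_model_pair()].
#'
#' @param observations training observation list.
#' @param topology an [hmm_topology()].
#' @param n_restarts restarts per class (default 10).
#' @param seed master seed; restart seeds are derived from it.
#' @param max_iter,tol,cov_floor EM settings, see [train_hmm()].
#' @return a `dual_hmm`.
#' @export
fit_dual_hmm <- function(observations, topology, n_restarts = 10L, seed = 1L,
                         max_iter = 100L, tol = 1e-6, cov_floor = 1e-6) {
  labels <- vapply(observations, function(o) o$label, character(1))
  fit_class <- function(lbl, offset) {
    obs <- observations[labels == lbl]
    lapply(seq_len(n_restarts), function(r) {
      ini <- init_hmm(obs, topology, seed = derive_seed(seed, offset, r))
      train_hmm(obs, ini, max_iter = max_iter, tol = tol,
                cov_floor = cov_floor)
    })
  }
  cand_a <- fit_class("active", 101L)
  cand_r <- fit_class("rest", 202L)
  select_model_pair(cand_a, cand_r, observations)
}

#' Sample sequences from a mixture HMM
#'
#' @param hmm a `nirs_hmm`.
#' @param T_len sequence length.
#' @param n number of sequences.
#' @param seed integer seed.
#' @return list of T x d matrices.
#' @export
simulate_hmm <- function(hmm, T_len, n = 1L, seed = 1L) {
  set.seed(derive_seed(seed, 83L))
  Ns <- hmm$topology$n_states; Nm <- hmm$topology$n_mix
  chols <- lapply(hmm$sigma, function(ps) lapply(ps, chol))
  lapply(seq_len(n), function(i) {
    s <- sample.int(Ns, 1, prob = hmm$pi)
    out <- matrix(0, T_len, hmm$d)
    for (t in seq_len(T_len)) {
      m <- sample.int(Nm, 1, prob = hmm$w[s, ])
      z <- rnorm(hmm$d)
      out[t, ] <- hmm$mu[[s]][[m]] + drop(t(chols[[s]][[m]]) %*% z)
      if (t < T_len) s <- sample.int(Ns, 1, prob = hmm$A[s, ])
    }
    out
  })
}

#' Serialise / restore a dual classifier
#'
#' Writes start distribution, transition matrix, mixture parameters,
#' topology and selection score to JSON; numeric values survive a
#' round-trip bit-faithfully (full-precision encoding).
#'
#' @param classifier a `dual_hmm`.
#' @param path output JSON file.
#' @return `path`, invisibly (for `save_dual_hmm`); a `dual_hmm` (for
#'   `load_dual_hmm`).
#' @export
save_dual_hmm <- function(classifier, path) {
  enc <- function(h) list(
    pi = h$pi, A = h$A, w = h$w,
    mu = lapply(h$mu, function(ps) ps),
    sigma = lapply(h$sigma, function(ps) ps),
    n_states = h$topology$n_states, n_mix = h$topology$n_mix, d = h$d)
  obj <- list(hmm_active = enc(classifier$hmm_active),
              hmm_rest = enc(classifier$hmm_rest),
              kappa = classifier$kappa)
  ## 17 significant digits round-trip IEEE doubles exactly
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_dual_hmm
#' @export
load_dual_hmm <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  ## JSON serialises matrices as arrays of rows
  json_matrix <- function(x, nr) {
    matrix(as.numeric(unlist(x)), nrow = nr, byrow = TRUE)
  }
  dec <- function(e) {
    Ns <- as.integer(e$n_states); Nm <- as.integer(e$n_mix)
    d <- as.integer(e$d)
    mu <- lapply(seq_len(Ns), function(s)
      lapply(seq_len(Nm), function(m) as.numeric(unlist(e$mu[[s]][[m]]))))
    sigma <- lapply(seq_len(Ns), function(s)
      lapply(seq_len(Nm), function(m) json_matrix(e$sigma[[s]][[m]], d)))
    structure(list(pi = as.numeric(unlist(e$pi)),
                   A = if (Ns == 1) matrix(as.numeric(unlist(e$A)), 1, 1)
                       else json_matrix(e$A, Ns),
                   w = if (Ns == 1) matrix(as.numeric(unlist(e$w)), 1, Nm)
                       else json_matrix(e$w, Ns),
                   mu = mu, sigma = sigma,
                   topology = hmm_topology(Ns, Nm), d = d,
                   trained = TRUE),
              class = "nirs_hmm")
  }
  ha <- dec(obj$hmm_active)
  structure(list(hmm_active = ha,
                 hmm_rest = dec(obj$hmm_rest),
                 kappa = as.numeric(obj$kappa),
                 topology = ha$topology),
            class = "dual_hmm")
}
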