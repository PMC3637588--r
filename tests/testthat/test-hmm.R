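test_that("initialisation produces a valid left-to-right model", {
  set.seed(1)
  obs <- lapply(1:6, function(i) matrix(rnorm(40 * 2, mean = i / 3), 40, 2))
  # degenerate topology: single Gaussian at the pooled moments
  h1 <- init_hmm(obs, hmm_topology(1, 1), seed = 2)
  X <- do.call(rbind, obs)
  expect_equal(h1$mu[[1]][[1]], colMeans(X), tolerance = 1e-9)
  expect_equal(h1$sigma[[1]][[1]], nirsbci:::floor_cov(cov(X), 1e-6),
               tolerance = 1e-9)
  expect_equal(h1$A, matrix(1, 1, 1))

  # determinism
  hA <- init_hmm(obs, hmm_topology(3, 2), seed = 5)
  hB <- init_hmm(obs, hmm_topology(3, 2), seed = 5)
  expect_identical(hA, hB)

  # left-to-right sparsity holds for every seed
  for (s in 1:20) {
    h <- init_hmm(obs, hmm_topology(4, 1), seed = s)
    expect_equal(h$pi, c(1, 0, 0, 0))
    A <- h$A
    expect_equal(rowSums(A), rep(1, 4), tolerance = 1e-12)
    off <- A
    for (i in 1:4) for (j in i:min(4, i + 1)) off[i, j] <- 0
    expect_true(all(off == 0))
    expect_equal(A[4, 4], 1)
  }
  expect_error(init_hmm(obs[1], hmm_topology(50, 2), seed = 1), "fewer")
})

test_that("forward log-likelihood matches brute-force path enumeration", {
  set.seed(42)
  errs <- replicate(40, {
    Ns <- sample(1:3, 1); Nm <- sample(1:2, 1)
    T_len <- sample(2:5, 1); d <- sample(1:3, 1)
    obs <- lapply(1:4, function(i) matrix(rnorm(8 * d), 8, d))
    h <- init_hmm(obs, hmm_topology(Ns, Nm), seed = sample.int(1e6, 1))
    X <- matrix(rnorm(T_len * d), T_len, d)
    abs(log_likelihood(h, X) - brute_force_loglik(h, X))
  })
  expect_lt(max(errs), 1e-10)

  # closed form for a single state, single mixture
  h <- toy_hmm(0.5, d = 2, var = 1.3)
  X <- matrix(rnorm(12 * 2), 12, 2)
  direct <- sum(vapply(1:12, function(t) {
    z <- X[t, ] - h$mu[[1]][[1]]
    -log(2 * pi) - 0.5 * log(det(h$sigma[[1]][[1]])) -
      0.5 * drop(t(z) %*% solve(h$sigma[[1]][[1]]) %*% z)
  }, numeric(1)))
  expect_equal(log_likelihood(h, X), direct, tolerance = 1e-10)

  expect_error(log_likelihood(h, matrix(0, 5, 3)), "dimension")
})

test_that("EM training is monotone and finds the degenerate fixed point", {
  set.seed(9)
  obs <- lapply(1:8, function(i) matrix(rnorm(30 * 2, mean = (i %% 2) * 2),
                                        30, 2))
  ini <- init_hmm(obs, hmm_topology(1, 1), seed = 1)
  fit <- train_hmm(obs, ini)
  expect_true(all(diff(fit$loglik_trace) > -1e-8))
  X <- do.call(rbind, obs)
  expect_equal(fit$mu[[1]][[1]], colMeans(X), tolerance = 1e-8)
  expect_equal(fit$sigma[[1]][[1]],
               cov(X) * (nrow(X) - 1) / nrow(X), tolerance = 1e-6)

  # monotonicity on richer topologies
  for (topo in list(hmm_topology(2, 1), hmm_topology(3, 2))) {
    ini2 <- init_hmm(obs, topo, seed = 3)
    fit2 <- train_hmm(obs, ini2)
    expect_true(all(diff(fit2$loglik_trace) > -1e-8))
    expect_true(all(vapply(seq_len(topo$n_states), function(s)
      all(eigen(fit2$sigma[[s]][[1]], symmetric = TRUE,
                only.values = TRUE)$values > 0), logical(1))))
    expect_equal(rowSums(fit2$A), rep(1, topo$n_states), tolerance = 1e-12)
  }
})

test_that("EM recovers the parameters of a known two-state model", {
  truth <- structure(list(
    pi = c(1, 0), A = matrix(c(0.9, 0, 0.1, 1), 2, 2),
    w = matrix(1, 2, 1),
    mu = list(list(c(0, 0)), list(c(3, 2))),
    sigma = list(list(diag(2) * 0.5), list(diag(2) * 0.8)),
    topology = hmm_topology(2, 1), d = 2, trained = TRUE),
    class = "nirs_hmm")
  seqs <- simulate_hmm(truth, T_len = 20, n = 200, seed = 9)
  fit <- train_hmm(seqs, init_hmm(seqs, hmm_topology(2, 1), seed = 3))
  expect_true(all(diff(fit$loglik_trace) > -1e-8))
  # state order follows temporal centroids, so state 1 is the early state
  expect_lt(max(abs(fit$mu[[1]][[1]] - c(0, 0))), 0.3 * 1)
  expect_lt(max(abs(fit$mu[[2]][[1]] - c(3, 2))) / 3, 0.1)
  expect_lt(abs(fit$A[1, 1] - 0.9), 0.1)
  expect_lt(abs(fit$A[1, 2] - 0.1), 0.1)
})

test_that("selection score weighs trials by likelihood distance", {
  expect_equal(kappa_score(c(2, -1, 3), c("active", "rest", "active")), 1)
  expect_equal(kappa_score(c(-2, 1), c("active", "rest")), 0)
  # hand evaluation: correct = trial 1 only, kappa = 2 / (2 + 1 + 1)
  expect_equal(kappa_score(c(2, -1, 1), c("active", "active", "rest")), 0.5)
  expect_warning(k0 <- kappa_score(c(0, 0), c("active", "rest")), "zero")
  expect_equal(k0, 0)
})

test_that("model-pair selection maximises the score over all combinations", {
  set.seed(11)
  obs <- labelled_obs(10, mu_active = 2, T_len = 15, seed = 3)
  good_a <- toy_hmm(2); good_r <- toy_hmm(0)
  bad_a <- toy_hmm(-5); bad_r <- toy_hmm(7)
  sel <- select_model_pair(list(bad_a, good_a), list(good_r, bad_r), obs)
  expect_equal(sel$hmm_active$mu[[1]][[1]], c(2, 2))
  expect_equal(sel$hmm_rest$mu[[1]][[1]], c(0, 0))
  expect_gt(sel$kappa, 0.99)
  expect_lte(sel$kappa, 1)
})

test_that("classification compares log-likelihoods with ties to rest", {
  clf <- structure(list(hmm_active = toy_hmm(2), hmm_rest = toy_hmm(0),
                        kappa = 1, topology = hmm_topology(1, 1)),
                   class = "dual_hmm")
  # identical models => equal likelihoods => rest
  clf_tie <- structure(list(hmm_active = toy_hmm(1), hmm_rest = toy_hmm(1),
                            kappa = 0, topology = hmm_topology(1, 1)),
                       class = "dual_hmm")
  X <- matrix(rnorm(20 * 2, mean = 1), 20, 2)
  expect_equal(classify_observation(clf_tie, X), "rest")

  # draws from the active model are labelled active almost always
  draws <- simulate_hmm(toy_hmm(2), T_len = 20, n = 500, seed = 13)
  lab <- classify_observation(clf, draws)
  expect_gte(mean(lab == "active"), 0.95)
  draws_r <- simulate_hmm(toy_hmm(0), T_len = 20, n = 500, seed = 14)
  expect_gte(mean(classify_observation(clf, draws_r) == "rest"), 0.95)
})

test_that("dual-HMM fitting separates well-structured classes", {
  obs <- labelled_obs(12, mu_active = 1.5, T_len = 20, seed = 21)
  clf <- fit_dual_hmm(obs, hmm_topology(2, 1), n_restarts = 3, seed = 4)
  expect_s3_class(clf, "dual_hmm")
  expect_gte(clf$kappa, 0.9)
  test_obs <- labelled_obs(10, mu_active = 1.5, T_len = 20, seed = 22)
  pred <- classify_observation(clf, test_obs)
  truth <- vapply(test_obs, `[[`, character(1), "label")
  expect_gte(mean(pred == truth), 0.9)
})

test_that("classifier serialisation round-trips parameters bit-faithfully", {
  obs <- labelled_obs(8, mu_active = 1.5, T_len = 15, seed = 31)
  clf <- fit_dual_hmm(obs, hmm_topology(2, 1), n_restarts = 2, seed = 6)
  path <- tempfile(fileext = ".json")
  save_dual_hmm(clf, path)
  back <- load_dual_hmm(path)
  expect_identical(back$hmm_active$A, clf$hmm_active$A)
  expect_identical(back$hmm_active$mu, clf$hmm_active$mu)
  expect_identical(back$hmm_rest$sigma, clf$hmm_rest$sigma)
  expect_identical(back$kappa, clf$kappa)
  X <- matrix(rnorm(15 * 2), 15, 2)
  expect_identical(log_likelihood(back$hmm_active, X),
                   log_likelihood(clf$hmm_active, X))
  unlink(path)
})
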