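#' Pairwise k-fold partitioning
#'
#' Randomly splits associated rest-pinching trial pairs (never individual
#' trials) into `k` folds of near-equal size, so every training and test
#' set contains the same number of rest and pinching trials.
#'
#' @param pairs a `trial_pairs` data.frame (flagged pairs should be
#'   removed beforehand).
#' @param k number of folds (default 4).
#' @param seed integer seed.
#' @return list of `k` integer vectors of `pair_id`s (the test fold
#'   memberships); union is all pairs, pairwise disjoint.
#' @export
partition_pairs <- function(pairs, k = 4L, seed = 1L) {
  ids <- pairs$pair_id
  n <- length(ids)
  if (n < k) stop("need at least k pairs to form k folds")
  set.seed(derive_seed(seed, 91L))
  perm <- sample(ids)
  fold_of <- rep(seq_len(k), length.out = n)
  ## contiguous blocks of the permutation -> fold sizes differ by <= 1
  sizes <- tabulate(fold_of, k)
  split(perm, rep(seq_len(k), times = sizes))
}

#' Classification performance metrics
#'
#' Accuracy, sensitivity and specificity from confusion counts. A metric
#' whose denominator is empty is returned as `NA` (undefined), not zero.
#'
#' @param counts named numeric vector or list with `TP`, `TN`, `FP`,
#'   `FN`.
#' @return named numeric vector `c(acc, sens, spec)` in \[0, 1\].
#' @export
compute_metrics <- function(counts) {
  TP <- counts[["TP"]]; TN <- counts[["TN"]]
  FP <- counts[["FP"]]; FN <- counts[["FN"]]
  total <- TP + TN + FP + FN
  if (total <= 0) stop("empty confusion table")
  c(acc = (TP + TN) / total,
    sens = if (TP + FN > 0) TP / (TP + FN) else NA_real_,
    spec = if (TN + FP > 0) TN / (TN + FP) else NA_real_)
}

#' Exact binomial confidence interval for a classification accuracy
#'
#' Clopper-Pearson interval computed from the mean number of successfully
#' classified trials, `x = accuracy * n`. The beta-quantile form is used
#' directly, so a non-integer mean success count is handled without
#' rounding; for integer `x` this is the textbook exact interval.
#'
#' @param mean_accuracy accuracy in \[0, 1\].
#' @param n_trials number of trials.
#' @param level confidence level (default 0.95).
#' @return numeric vector `c(lower, upper)` in percent.
#' @export
binomial_ci <- function(mean_accuracy, n_trials, level = 0.95) {
  if (mean_accuracy < 0 || mean_accuracy > 1) stop("accuracy must be in [0, 1]")
  if (n_trials <= 0) stop("n_trials must be > 0")
  x <- mean_accuracy * n_trials
  a <- (1 - level) / 2
  lower <- if (x <= 0) 0 else qbeta(a, x, n_trials - x + 1)
  upper <- if (x >= n_trials) 1 else qbeta(1 - a, x + 1, n_trials - x)
  c(lower = 100 * lower, upper = 100 * upper)
}

## confusion counts from predicted/true label vectors
confusion_counts <- function(predicted, truth) {
  c(TP = sum(predicted == "active" & truth == "active"),
    TN = sum(predicted == "rest" & truth == "rest"),
    FP = sum(predicted == "active" & truth == "rest"),
    FN = sum(predicted == "rest" & truth == "active"))
}

#' Run the full cross-validated decoding experiment
#'
#' For each decoder mode and each model topology, performs `n_repeats`
#' complete pairwise k-fold cross-validation runs: per partition, spatial
#' feature weights and both class HMMs (with `n_restarts` seeded restarts
#' and likelihood-weighted pair selection) are fitted on the training
#' pairs only and evaluated on the held-out pairs. Fold metrics are
#' averaged into run metrics; run metrics are summarised as mean and SD
#' per topology; the topology with the highest mean accuracy (ties broken
#' toward fewer states, then fewer mixtures) is selected per mode.
#'
#' @param recording a `nirs_recording`.
#' @param modes decoder modes to evaluate (subset of `"fnirs_only"`,
#'   `"combined"`).
#' @param grid list of [hmm_topology()] objects (default the full 10-cell
#'   grid).
#' @param n_repeats complete cross-validation runs per topology
#'   (default 7).
#' @param k folds (default 4).
#' @param n_restarts HMM restarts per class (default 10).
#' @param spec a [segment_spec()].
#' @param seed master seed; every random choice derives from it.
#' @param ma_threshold motion-artifact threshold for preprocessing.
#' @param max_iter,tol EM settings.
#' @return object of class `decoding_report`: per-cell results
#'   (`results` data.frame), per-topology run summaries (`runs`),
#'   selected topology, metrics and binomial CIs per mode (`selected`),
#'   and counts of used/excluded pairs.
#' @export
run_experiment <- function(recording, modes = c("fnirs_only", "combined"),
                           grid = topology_grid(), n_repeats = 7L, k = 4L,
                           n_restarts = 10L, spec = segment_spec(), seed = 1L,
                           ma_threshold = 3, max_iter = 100L, tol = 1e-6) {
  stopifnot(inherits(recording, "nirs_recording"))
  modes <- match.arg(modes, c("fnirs_only", "combined"), several.ok = TRUE)
  processed <- preprocess_fnirs(recording, ma_threshold = ma_threshold)
  ans <- NULL
  if ("combined" %in% modes) {
    ans <- tryCatch(assemble_biosignals(recording), error = function(e) {
      warning("biosignals unavailable (", conditionMessage(e),
              "); dropping combined mode")
      NULL
    })
    if (is.null(ans)) modes <- setdiff(modes, "combined")
  }
  n5 <- vapply(processed$sessions, nrow, integer(1))
  pairs_all <- extract_trial_pairs(recording$timeline, processed$mask, spec,
                                   n_samples = n5)
  pairs <- pairs_all[!pairs_all$ma_affected, , drop = FALSE]
  if (nrow(pairs) < k) stop("fewer unflagged pairs than folds")
  n_trials <- 2L * nrow(pairs)

  cells <- list()
  for (rep_i in seq_len(n_repeats)) {
    folds <- partition_pairs(pairs, k = k, seed = derive_seed(seed, 7L, rep_i))
    for (fold_i in seq_len(k)) {
      test_ids <- folds[[fold_i]]
      train_pairs <- pairs[!pairs$pair_id %in% test_ids, , drop = FALSE]
      test_pairs <- pairs[pairs$pair_id %in% test_ids, , drop = FALSE]
      w_seed <- derive_seed(seed, 13L, rep_i, fold_i)
      weights <- list(
        M1 = fit_weights(train_pairs, processed, "M1", spec, seed = w_seed),
        PMv = fit_weights(train_pairs, processed, "PMv", spec, seed = w_seed))
      feats <- apply_weights(processed, weights)
      for (mode in modes) {
        train_obs <- build_observations(train_pairs, feats, ans, mode, spec)
        test_obs <- build_observations(test_pairs, feats, ans, mode, spec)
        truth <- vapply(test_obs, function(o) o$label, character(1))
        for (g in seq_along(grid)) {
          topo <- grid[[g]]
          clf <- fit_dual_hmm(train_obs, topo, n_restarts = n_restarts,
                              seed = derive_seed(seed, 17L, rep_i, fold_i, g,
                                                 match(mode, c("fnirs_only",
                                                               "combined"))),
                              max_iter = max_iter, tol = tol)
          pred <- classify_observation(clf, test_obs)
          cc <- confusion_counts(pred, truth)
          met <- compute_metrics(cc)
          cells[[length(cells) + 1L]] <- data.frame(
            mode = mode, n_states = topo$n_states, n_mix = topo$n_mix,
            repeat_i = rep_i, fold = fold_i,
            TP = cc[["TP"]], TN = cc[["TN"]], FP = cc[["FP"]], FN = cc[["FN"]],
            acc = met[["acc"]], sens = met[["sens"]], spec = met[["spec"]],
            kappa = clf$kappa)
        }
      }
    }
  }
  results <- do.call(rbind, cells)

  ## run-level: mean over folds; topology-level: mean/sd over runs
  agg_key <- interaction(results$mode, results$n_states, results$n_mix,
                         results$repeat_i, drop = TRUE)
  runs <- do.call(rbind, lapply(split(results, agg_key), function(d) {
    data.frame(mode = d$mode[1], n_states = d$n_states[1], n_mix = d$n_mix[1],
               repeat_i = d$repeat_i[1], acc = mean(d$acc),
               sens = mean(d$sens), spec = mean(d$spec))
  }))
  rownames(runs) <- NULL
  topo_key <- interaction(runs$mode, runs$n_states, runs$n_mix, drop = TRUE)
  summaries <- do.call(rbind, lapply(split(runs, topo_key), function(d) {
    data.frame(mode = d$mode[1], n_states = d$n_states[1], n_mix = d$n_mix[1],
               acc_mean = mean(d$acc), acc_sd = sd(d$acc),
               sens_mean = mean(d$sens), sens_sd = sd(d$sens),
               spec_mean = mean(d$spec), spec_sd = sd(d$spec))
  }))
  rownames(summaries) <- NULL

  selected <- lapply(modes, function(mode) {
    s <- summaries[summaries$mode == mode, , drop = FALSE]
    s <- s[order(-s$acc_mean, s$n_states, s$n_mix), , drop = FALSE]
    top <- s[1, ]
    ci <- binomial_ci(top$acc_mean, n_trials)
    list(mode = mode, n_states = top$n_states, n_mix = top$n_mix,
         acc_mean = top$acc_mean, acc_sd = top$acc_sd,
         sens_mean = top$sens_mean, sens_sd = top$sens_sd,
         spec_mean = top$spec_mean, spec_sd = top$spec_sd,
         ci_lower = ci[["lower"]], ci_upper = ci[["upper"]],
         run_acc = runs$acc[runs$mode == mode &
                              runs$n_states == top$n_states &
                              runs$n_mix == top$n_mix],
         run_sens = runs$sens[runs$mode == mode &
                                runs$n_states == top$n_states &
                                runs$n_mix == top$n_mix],
         run_spec = runs$spec[runs$mode == mode &
                                runs$n_states == top$n_states &
                                runs$n_mix == top$n_mix])
  })
  names(selected) <- modes

  structure(list(results = results, runs = runs, summaries = summaries,
                 selected = selected, n_trials = n_trials,
                 n_pairs_used = nrow(pairs),
                 n_pairs_excluded = sum(pairs_all$ma_affected),
                 modes = modes, seed = seed),
            class = "decoding_report")
}

## paired two-tailed t-test that tolerates identical inputs
paired_t <- function(a, b) {
  if (length(a) != length(b)) stop("unequal run counts")
  d <- b - a
  if (all(abs(d - d[1]) < 1e-15)) {
    if (abs(d[1]) < 1e-15) {
      return(list(t = 0, df = length(d) - 1L, p = 1))
    }
  }
  tt <- t.test(b, a, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = unname(tt$p.value))
}

#' Compare the two decoder modes of a report
#'
#' Per metric: paired two-tailed t-test across the run-level means of the
#' selected topologies, and the relative gain of the combined decoder
#' over the fNIRS-only decoder in percent.
#'
#' @param report a `decoding_report` containing both modes.
#' @return data.frame with one row per metric: fNIRS and combined means,
#'   relative gain (percent), t statistic, degrees of freedom, p-value.
#' @export
compare_decoders <- function(report) {
  if (!all(c("fnirs_only", "combined") %in% report$modes)) {
    stop("both modes must be present to compare decoders")
  }
  f <- report$selected$fnirs_only; c2 <- report$selected$combined
  out <- lapply(c(acc = "acc", sens = "sens", spec = "spec"), function(m) {
    a <- f[[paste0("run_", m)]]; b <- c2[[paste0("run_", m)]]
    tt <- paired_t(a, b)
    data.frame(metric = m, fnirs = mean(a), combined = mean(b),
               gain_pct = 100 * (mean(b) - mean(a)) / mean(a),
               t = tt$t, df = tt$df, p = tt$p)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Group-level summary of per-subject decoder performance
#'
#' Aggregates a per-subject table of mean accuracies, sensitivities and
#' specificities for the two decoder modes: group means per mode
#' (computed over the subjects that have both modes), per-subject
#' relative gains and their group mean, and paired two-tailed t-tests
#' across subjects.
#'
#' @param table data.frame with columns `subject`, `acc_fnirs`,
#'   `sens_fnirs`, `spec_fnirs`, `acc_combined`, `sens_combined`,
#'   `spec_combined` (percent or proportion; returned on the input
#'   scale).
#' @return list with `means` (data.frame metric x mode group means and
#'   SDs), `gains` (per-subject and mean relative gains, percent), and
#'   `tests` (paired t statistics and p-values per metric).
#' @export
summarize_cohort <- function(table) {
  need <- c("subject", "acc_fnirs", "sens_fnirs", "spec_fnirs",
            "acc_combined", "sens_combined", "spec_combined")
  if (!all(need %in% names(table))) {
    stop("missing columns: ", paste(setdiff(need, names(table)), collapse = ", "))
  }
  keep <- stats::complete.cases(table[, need])
  tb <- table[keep, , drop = FALSE]
  metrics <- c("acc", "sens", "spec")
  means <- do.call(rbind, lapply(metrics, function(m) {
    a <- tb[[paste0(m, "_fnirs")]]; b <- tb[[paste0(m, "_combined")]]
    data.frame(metric = m,
               fnirs_mean = mean(a), fnirs_sd = sd(a),
               combined_mean = mean(b), combined_sd = sd(b))
  }))
  gains <- lapply(metrics, function(m) {
    a <- tb[[paste0(m, "_fnirs")]]; b <- tb[[paste0(m, "_combined")]]
    g <- 100 * (b - a) / a
    list(per_subject = stats::setNames(g, tb$subject),
         mean = mean(g), sd = sd(g))
  })
  names(gains) <- metrics
  tests <- do.call(rbind, lapply(metrics, function(m) {
    a <- tb[[paste0(m, "_fnirs")]]; b <- tb[[paste0(m, "_combined")]]
    tt <- paired_t(a, b)
    data.frame(metric = m, t = tt$t, df = tt$df, p = tt$p)
  }))
  list(means = means, gains = gains, tests = tests,
       n_subjects = nrow(tb))
}

#' @export
print.decoding_report <- function(x, ...) {
  cat("Cross-validated decoding report\n")
  cat(sprintf("  pairs used: %d (excluded for motion: %d); trials: %d\n",
              x$n_pairs_used, x$n_pairs_excluded, x$n_trials))
  for (mode in x$modes) {
    s <- x$selected[[mode]]
    cat(sprintf(
      "  %-10s N_s=%d N_m=%d  Acc %.1f%% +- %.1f  Sens %.1f%% +- %.1f  Spec %.1f%% +- %.1f  CI [%.1f, %.1f]\n",
      mode, s$n_states, s$n_mix, 100 * s$acc_mean, 100 * s$acc_sd,
      100 * s$sens_mean, 100 * s$sens_sd, 100 * s$spec_mean, 100 * s$spec_sd,
      s$ci_lower, s$ci_upper))
  }
  invisible(x)
}
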