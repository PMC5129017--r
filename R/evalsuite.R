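#' Balanced classification error
#'
#' `1 - (sensitivity + specificity) / 2`, computed on -1/+1 vectors. A
#' constant predictor scores 0.5 regardless of class imbalance, which is why
#' the cross-validation harness reports this rather than raw accuracy.
#'
#' @param y_true Labels in `{-1, +1}`, both classes present.
#' @param y_pred Predicted labels in `{-1, +1}`.
#' @return Error in `[0, 1]`.
#' @examples
#' balanced_error(c(1, 1, -1, -1), c(1, -1, -1, -1))  # 0.25
#' @export
balanced_error <- function(y_true, y_pred) {
  check_pm1(y_true)
  if (length(y_pred) != length(y_true) || !all(y_pred %in% c(-1, 1))) {
    abort("`y_pred` must be -1/+1 and match `y_true` in length.",
          class = "mediboost_input_error")
  }
  sens <- sum(y_pred == 1 & y_true == 1) / sum(y_true == 1)
  spec <- sum(y_pred == -1 & y_true == -1) / sum(y_true == -1)
  1 - (sens + spec) / 2
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' The probability that a random positive outranks a random negative, with
#' ties counted one half: computed exactly from mid-ranks, equivalent to
#' all-pairs counting.
#'
#' @param y_true Labels in `{-1, +1}`, both classes present.
#' @param scores Real-valued scores (higher = more positive). For trees this
#'   should be the leaf path score `G`, not the hard label.
#' @return AUC in `[0, 1]`.
#' @examples
#' auc_score(c(-1, -1, 1, 1), c(0.1, 0.4, 0.35, 0.8))
#' @export
auc_score <- function(y_true, scores) {
  check_pm1(y_true)
  if (length(scores) != length(y_true) || anyNA(scores)) {
    abort("`scores` must be complete and match `y_true` in length.",
          class = "mediboost_input_error")
  }
  pos <- y_true == 1
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Stratified fold assignment
#'
#' Assigns each instance to one of `folds` folds, separately within each
#' class, so every test fold contains both classes and the balanced error is
#' always defined.
#'
#' @param y Labels in `{-1, +1}`.
#' @param folds Number of folds.
#' @param seed Optional seed; when `NULL` the current RNG stream is used
#'   (this is how [repeated_cv()] derives reproducible trials from one seed).
#' @return Integer vector of fold ids in `1:folds`.
#' @export
stratified_folds <- function(y, folds = 5L, seed = NULL) {
  check_pm1(y)
  draw <- function() {
    id <- integer(length(y))
    for (cls in c(-1, 1)) {
      idx <- which(y == cls)
      if (length(idx) < folds) {
        abort(paste0("class ", cls, " has only ", length(idx),
                     " instances; cannot stratify into ", folds, " folds."),
              class = "mediboost_input_error")
      }
      id[sample(idx)] <- rep_len(seq_len(folds), length(idx))
    }
    id
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Repeated stratified cross-validation
#'
#' The evaluation protocol used throughout the package: `trials` independent
#' stratified `folds`-fold splits (default 5 trials of 5 folds, i.e. 25 fold
#' results), recording the balanced error and the AUC of each held-out fold.
#' The learner is fitted from scratch on each training portion — including
#' any internal preprocessing or nested hyperparameter tuning — so no
#' information leaks from test folds.
#'
#' @param data Data frame with features and the label column.
#' @param label Name of the label column.
#' @param learner A learner specification, e.g. [learner_mediboost()],
#'   [learner_greedy_tree()] or [learner_constant()].
#' @param trials,folds Protocol size (defaults 5 and 5).
#' @param seed Integer seed making fold draws and results reproducible.
#' @param positive Optional positive label value.
#' @return A `mediboost_cv` object; `tidy()` gives the per-fold table,
#'   `glance()` the means and standard deviations.
#' @examples
#' d <- sim_four_region(150, flip_noise = 0.1, seed = 1)
#' cv <- repeated_cv(d, "y", learner_mediboost(depth = 3, gamma = 4),
#'                   trials = 1, seed = 1)
#' glance(cv)
#' @export
repeated_cv <- function(data, label, learner, trials = 5L, folds = 5L,
                        seed = 1L, positive = NULL) {
  if (!label %in% names(data)) {
    abort(paste0("label column '", label, "' not found in `data`."),
          class = "mediboost_input_error")
  }
  check_learner(learner)
  enc <- encode_labels(data[[label]], positive)
  set.seed(seed)
  rows <- list()
  for (tr in seq_len(trials)) {
    fold_id <- stratified_folds(enc$y, folds)
    for (fo in seq_len(folds)) {
      test <- fold_id == fo
      model <- learner$fit(data[!test, , drop = FALSE], label, positive)
      pred <- learner$predict(model, data[test, , drop = FALSE])
      rows[[length(rows) + 1L]] <- tibble::tibble(
        trial = tr, fold = fo,
        balanced_error = balanced_error(enc$y[test], pred$.pred_sign),
        auc = auc_score(enc$y[test], pred$.pred_score),
        depth = attr(model, "tuned_depth") %||% NA_real_,
        gamma = attr(model, "tuned_gamma") %||% NA_real_
      )
    }
  }
  structure(
    list(results = dplyr::bind_rows(rows), learner = learner$name,
         trials = trials, folds = folds, seed = seed),
    class = "mediboost_cv"
  )
}

#' Nested hyperparameter tuning
#'
#' Inner stratified cross-validation over a grid of (depth, gamma) pairs:
#' each grid point is scored by its mean balanced error over the inner
#' folds, and the minimiser is returned, with ties broken towards the
#' smaller depth and then the smaller gamma (preferring the more
#' interpretable model).
#'
#' @inheritParams repeated_cv
#' @param algo `"lmb"` or `"mab"`.
#' @param grid Data frame with columns `depth` and `gamma`.
#' @param inner_folds Number of inner folds (default 5).
#' @param learning_rate,lambda,prune Passed to [mediboost()].
#' @param seed Optional seed; `NULL` (the default) continues the caller's
#'   RNG stream, which is what [learner_mediboost()] relies on inside
#'   [repeated_cv()].
#' @return A `mediboost_tune` object with elements `best` (list with `depth`
#'   and `gamma`) and `trace` (tibble of grid points and their scores).
#' @export
tune_nested <- function(data, label, algo = "lmb", grid,
                        inner_folds = 5L, positive = NULL,
                        learning_rate = 0.1, lambda = 0, prune = TRUE,
                        seed = NULL) {
  if (!is.data.frame(grid) || nrow(grid) == 0L ||
      !all(c("depth", "gamma") %in% names(grid))) {
    abort("`grid` must be a non-empty data frame with columns depth and gamma.",
          class = "mediboost_input_error")
  }
  enc <- encode_labels(data[[label]], positive)
  fold_id <- stratified_folds(enc$y, inner_folds, seed = seed)
  score <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    errs <- numeric(inner_folds)
    for (fo in seq_len(inner_folds)) {
      test <- fold_id == fo
      fit <- mediboost(data[!test, , drop = FALSE], label,
                       positive = positive, algo = algo,
                       depth = grid$depth[g], gamma = grid$gamma[g],
                       learning_rate = learning_rate, lambda = lambda,
                       prune = prune)
      pred <- predict(fit, data[test, , drop = FALSE])
      errs[fo] <- balanced_error(enc$y[test], pred$.pred_sign)
    }
    score[g] <- mean(errs)
  }
  o <- order(score, grid$depth, grid$gamma)[1L]
  structure(
    list(best = list(depth = grid$depth[o], gamma = grid$gamma[o]),
         trace = tibble::tibble(depth = grid$depth, gamma = grid$gamma,
                                mean_balanced_error = score)),
    class = "mediboost_tune"
  )
}

#' Label-permutation test of a cross-validated AUC
#'
#' Permutes the labels `B` times, re-runs the full cross-validation protocol
#' on each permuted copy, and estimates the probability of obtaining an AUC
#' at least as good by chance with the add-one estimator
#' `p = (1 + #{AUC_perm >= AUC_obs}) / (B + 1)` (a valid p-value under the
#' null; the smallest attainable value with `B = 100` is `1/101`).
#'
#' @inheritParams repeated_cv
#' @param B Number of label permutations (default 100).
#' @param trials Trials of the CV protocol per run (default 1; the observed
#'   AUC and every permutation use the same protocol).
#' @return A `mediboost_permutation` object with the observed mean AUC, the
#'   permuted AUCs with their mean and SD, and the p-value.
#' @export
permutation_test <- function(data, label, learner, B = 100L, trials = 1L,
                             folds = 5L, seed = 1L, positive = NULL) {
  if (B < 1L) {
    abort("`B` must be >= 1.", class = "mediboost_input_error")
  }
  set.seed(seed)
  cv_seeds <- sample.int(.Machine$integer.max, B + 1L)
  n <- nrow(data)
  perms <- lapply(seq_len(B), function(i) sample.int(n))
  obs <- repeated_cv(data, label, learner, trials = trials, folds = folds,
                     seed = cv_seeds[1L], positive = positive)
  obs_auc <- mean(obs$results$auc)
  perm_auc <- vapply(seq_len(B), function(i) {
    permuted <- data
    permuted[[label]] <- data[[label]][perms[[i]]]
    cv <- repeated_cv(permuted, label, learner, trials = trials,
                      folds = folds, seed = cv_seeds[i + 1L],
                      positive = positive)
    mean(cv$results$auc)
  }, numeric(1))
  structure(
    list(observed_auc = obs_auc, perm_auc = perm_auc,
         p_value = (1 + sum(perm_auc >= obs_auc)) / (B + 1),
         mean_perm_auc = mean(perm_auc), sd_perm_auc = stats::sd(perm_auc),
         B = B, trials = trials, folds = folds, seed = seed,
         learner = learner$name),
    class = "mediboost_permutation"
  )
}

#' Compare learners across datasets
#'
#' Runs the cross-validation protocol for every learner on every dataset and
#' tallies pairwise wins, losses and ties (differences below `1e-10` count
#' as ties) by mean balanced error (lower wins) and by mean AUC (higher
#' wins), together with a two-sided sign-test p-value on the win/loss
#' counts.
#'
#' @param datasets Named list of data frames.
#' @param label Label column name (shared by all datasets).
#' @param learners Named list of at least two learner specifications.
#' @inheritParams repeated_cv
#' @return A `mediboost_comparison` object with elements `metrics`
#'   (per-dataset per-learner tibble) and `pairwise`.
#' @export
compare_learners <- function(datasets, label, learners, trials = 1L,
                             folds = 5L, seed = 1L, positive = NULL) {
  if (length(learners) < 2L) {
    abort("need at least two learners to compare.",
          class = "mediboost_input_error")
  }
  if (is.null(names(datasets))) {
    names(datasets) <- paste0("dataset", seq_along(datasets))
  }
  rows <- list()
  for (ds in names(datasets)) {
    for (ln in names(learners)) {
      cv <- repeated_cv(datasets[[ds]], label, learners[[ln]],
                        trials = trials, folds = folds, seed = seed,
                        positive = positive)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        dataset = ds, learner = ln,
        balanced_error = mean(cv$results$balanced_error),
        auc = mean(cv$results$auc)
      )
    }
  }
  metrics <- dplyr::bind_rows(rows)
  pair_rows <- list()
  lns <- names(learners)
  for (i in seq_along(lns)) {
    for (j in seq_along(lns)) {
      if (i >= j) next
      a <- metrics[metrics$learner == lns[i], ]
      b <- metrics[metrics$learner == lns[j], ]
      b <- b[match(a$dataset, b$dataset), ]
      for (metric in c("balanced_error", "auc")) {
        diff <- a[[metric]] - b[[metric]]
        if (metric == "balanced_error") diff <- -diff  # lower error wins
        wins <- sum(diff > 1e-10)
        losses <- sum(diff < -1e-10)
        ties <- sum(abs(diff) <= 1e-10)
        p <- if (wins + losses == 0L) NA_real_ else
          stats::binom.test(wins, wins + losses, 0.5)$p.value
        pair_rows[[length(pair_rows) + 1L]] <- tibble::tibble(
          learner_a = lns[i], learner_b = lns[j], metric = metric,
          wins = wins, losses = losses, ties = ties, p_sign_test = p
        )
      }
    }
  }
  structure(list(metrics = metrics, pairwise = dplyr::bind_rows(pair_rows)),
            class = "mediboost_comparison")
}

#' @export
print.mediboost_cv <- function(x, ...) {
  cat(sprintf("<mediboost_cv> %s: %d trial(s) x %d folds (seed %d)\n",
              x$learner, x$trials, x$folds, x$seed))
  cat(sprintf("  balanced error %.4f +/- %.4f, AUC %.4f +/- %.4f\n",
              mean(x$results$balanced_error), stats::sd(x$results$balanced_error),
              mean(x$results$auc), stats::sd(x$results$auc)))
  invisible(x)
}

#' @export
print.mediboost_permutation <- function(x, ...) {
  cat(sprintf("<mediboost_permutation> %s: B = %d\n", x$learner, x$B))
  cat(sprintf("  observed AUC %.4f; permuted %.4f +/- %.4f; p = %.4f\n",
              x$observed_auc, x$mean_perm_auc, x$sd_perm_auc, x$p_value))
  invisible(x)
}

#' @export
print.mediboost_comparison <- function(x, ...) {
  cat("<mediboost_comparison>\n")
  print(x$pairwise)
  invisible(x)
}

#' @export
print.mediboost_tune <- function(x, ...) {
  cat(sprintf("<mediboost_tune> best: depth = %d, gamma = %g\n",
              x$best$depth, x$best$gamma))
  invisible(x)
}
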