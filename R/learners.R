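#' Learner specifications for the evaluation harness
#'
#' A learner specification is a named list with a `fit(data, label,
#' positive)` function returning a fitted model and a `predict(model,
#' new_data)` function returning a tibble with columns `.pred_sign` (-1/+1)
#' and `.pred_score` (real). [repeated_cv()], [permutation_test()] and
#' [compare_learners()] accept any such specification.
#'
#' `learner_mediboost()` wraps [mediboost()]; when `tune_grid` is supplied,
#' each call to `fit()` first runs [tune_nested()] on its training data, so
#' hyperparameter selection is nested inside the outer protocol.
#' `learner_greedy_tree()` is the depth-matched greedy hard-partition
#' baseline: a depth-limited CART tree grown through [rpart::rpart()] with
#' the complexity penalty and minimum node sizes switched off, so the only
#' capacity control is the depth itself. `learner_constant()` always
#' predicts the majority class of its training data (balanced error 0.5 by
#' construction).
#'
#' @param algo,depth,gamma,learning_rate,lambda,prune Passed to
#'   [mediboost()].
#' @param tune_grid Optional data frame with columns `depth` and `gamma`.
#' @param inner_folds Inner folds used when `tune_grid` is given.
#' @return A learner specification list.
#' @name learners
NULL

#' @rdname learners
#' @export
learner_mediboost <- function(algo = "lmb", depth = 4L, gamma = 2,
                              learning_rate = 0.1, lambda = 0, prune = TRUE,
                              tune_grid = NULL, inner_folds = 5L) {
  name <- paste0("mediboost_", algo,
                 if (!is.null(tune_grid)) "_tuned" else "")
  spec <- list(
    name = name,
    fit = function(data, label, positive = NULL) {
      dep <- depth; gam <- gamma
      if (!is.null(tune_grid)) {
        tn <- tune_nested(data, label, algo = algo, grid = tune_grid,
                          inner_folds = inner_folds, positive = positive,
                          learning_rate = learning_rate, lambda = lambda,
                          prune = prune)
        dep <- tn$best$depth; gam <- tn$best$gamma
      }
      fit <- mediboost(data, label, positive = positive, algo = algo,
                       depth = dep, gamma = gam,
                       learning_rate = learning_rate, lambda = lambda,
                       prune = prune)
      attr(fit, "tuned_depth") <- dep
      attr(fit, "tuned_gamma") <- gam
      fit
    },
    predict = function(model, new_data) {
      predict(model, new_data)[c(".pred_sign", ".pred_score")]
    }
  )
  spec
}

#' @rdname learners
#' @export
learner_greedy_tree <- function(depth = 4L) {
  list(
    name = paste0("greedy_tree_d", depth),
    fit = function(data, label, positive = NULL) {
      enc <- encode_labels(data[[label]], positive)
      df <- data[setdiff(names(data), label)]
      df$.y <- factor(enc$y, levels = c(-1, 1))
      rpart::rpart(.y ~ ., data = df, method = "class",
                   control = rpart::rpart.control(
                     maxdepth = depth, cp = 0, minsplit = 2, minbucket = 1,
                     xval = 0))
    },
    predict = function(model, new_data) {
      prob <- stats::predict(model, newdata = new_data, type = "prob")[, "1"]
      tibble::tibble(.pred_sign = ifelse(prob >= 0.5, 1, -1),
                     .pred_score = prob)
    }
  )
}

#' @rdname learners
#' @export
learner_constant <- function() {
  list(
    name = "constant_majority",
    fit = function(data, label, positive = NULL) {
      enc <- encode_labels(data[[label]], positive)
      if (sum(enc$y > 0) * 2 >= length(enc$y)) 1 else -1
    },
    predict = function(model, new_data) {
      n <- nrow(new_data)
      tibble::tibble(.pred_sign = rep(model, n), .pred_score = rep(0, n))
    }
  )
}

check_learner <- function(learner) {
  if (!is.list(learner) || !is.function(learner$fit) ||
      !is.function(learner$predict)) {
    abort("`learner` must be a specification with fit() and predict() (see ?learners).",
          class = "mediboost_input_error")
  }
  invisible(learner)
}
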