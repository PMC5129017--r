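#' Fit an interpretable boosted decision tree
#'
#' Grows a single decision tree whose every root-to-leaf path is a boosting
#' ensemble, using either the exponential-loss engine (`algo = "mab"`) or the
#' binomial log-likelihood gradient-boosting engine (`algo = "lmb"`, the
#' default and usually the more accurate of the two). Features are prepared
#' with [impute_and_flag()] (mean/mode imputation, missingness indicators,
#' one-hot expansion of categoricals) and the preprocessing statistics are
#' stored in the model so that [predict.mediboost()] applies them to new
#' data. By default the fitted tree is simplified with the sign-preserving
#' pruning of [prune_sign()], which never changes a prediction.
#'
#' The two hyperparameters worth tuning (see [tune_nested()]) are `depth`,
#' the number of boosting rounds along each path, and `gamma`, the
#' acceleration parameter: `gamma = 0` keeps every instance in every node
#' (the tree is exactly a rewritten boosting ensemble) while large values
#' approach classical hard recursive partitioning and give smaller trees.
#'
#' @param data A data frame holding the features and the label column.
#' @param label Name of the label column (exactly two distinct values).
#' @param positive Optional value of the positive class; defaults to the
#'   larger label (numerically or alphabetically).
#' @param algo `"lmb"` (likelihood gradient boosting) or `"mab"`
#'   (exponential loss).
#' @param depth,gamma,learning_rate,lambda Convenience shortcuts for the
#'   corresponding [mediboost_control()] fields; ignored when `control` is
#'   supplied.
#' @param prune Apply sign-preserving pruning after growth (default `TRUE`).
#' @param control Optional [mediboost_control()] overriding the shortcuts.
#'
#' @return A `mediboost` model object; see [tidy.mediboost()],
#'   [glance.mediboost()], [predict.mediboost()], [tree_rules()],
#'   [tree_to_dot()], [mediboost_to_json()].
#' @examples
#' d <- sim_four_region(300, flip_noise = 0.05, seed = 7)
#' fit <- mediboost(d, "y", algo = "lmb", depth = 4, gamma = 4)
#' glance(fit)
#' predict(fit, d[1:5, ])
#' @export
mediboost <- function(data, label, positive = NULL,
                      algo = c("lmb", "mab"),
                      depth = 15L, gamma = 2, learning_rate = 0.1,
                      lambda = 0, prune = TRUE, control = NULL) {
  algo <- match.arg(algo)
  if (!is.data.frame(data)) {
    abort("`data` must be a data frame.", class = "mediboost_input_error")
  }
  if (!is.character(label) || length(label) != 1L) {
    abort("`label` must be a single column name.",
          class = "mediboost_input_error")
  }
  if (!label %in% names(data)) {
    abort(paste0("label column '", label, "' not found in `data`."),
          class = "mediboost_input_error")
  }
  if (is.null(control)) {
    control <- mediboost_control(depth = depth, gamma = gamma,
                                 learning_rate = learning_rate,
                                 lambda = lambda)
  }
  enc <- encode_labels(data[[label]], positive)
  features <- data[setdiff(names(data), label)]
  if (ncol(features) == 0L) {
    abort("`data` has no feature columns besides the label.",
          class = "mediboost_input_error")
  }
  proc <- impute_and_flag(features)
  X <- as.matrix(proc)
  fit <- build_engine(X, enc$y, control, algo)
  fit$label_map <- enc$mapping
  fit$preprocess <- attr(proc, "preprocess_stats")
  fit$original_features <- names(features)
  if (prune) fit <- prune_sign(fit)
  fit
}

# apply stored preprocessing (if any) and return the numeric feature matrix
model_matrix <- function(object, new_data) {
  if (!is.null(object$preprocess)) {
    if (!is.data.frame(new_data)) {
      abort("`new_data` must be a data frame.",
            class = "mediboost_input_error")
    }
    proc <- impute_and_flag(new_data, stats = object$preprocess)
    X <- as.matrix(proc)
  } else {
    X <- as.matrix(new_data)
  }
  if (ncol(X) != length(object$feature_names)) {
    abort(paste0("new data yields ", ncol(X), " feature columns; the model ",
                 "was trained with ", length(object$feature_names), "."),
          class = "mediboost_input_error")
  }
  X
}

route_tree <- function(node, X) {
  n <- nrow(X)
  label <- numeric(n)
  score <- numeric(n)
  rec <- function(node, idx) {
    if (length(idx) == 0L) return(invisible(NULL))
    if (isTRUE(node$leaf)) {
      label[idx] <<- node$label
      score[idx] <<- node$G
    } else {
      goes_left <- X[idx, node$stump$feature] <= node$stump$threshold
      rec(node$left, idx[goes_left])
      rec(node$right, idx[!goes_left])
    }
    invisible(NULL)
  }
  rec(node, seq_len(n))
  list(label = label, score = score)
}

#' Predict from a fitted tree
#'
#' Routes each row root-to-leaf with the fixed rule
#' `x[feature] <= threshold` goes left (values exactly at a threshold go
#' left). The predicted class is the leaf label (the sign of the leaf's path
#' score) and the score is the real-valued path score `G`, which is what AUC
#' computations should rank by.
#'
#' @param object A `mediboost` model.
#' @param new_data Data frame (or, for models fitted through
#'   [build_mab()]/[build_lmb()], a numeric matrix) of features.
#' @param type `"tibble"` (default) returns `.pred_class` (original label
#'   values), `.pred_sign` (-1/+1) and `.pred_score`; `"class"` and
#'   `"score"` return bare vectors.
#' @param ... Unused.
#' @return A tibble or vector of predictions.
#' @export
predict.mediboost <- function(object, new_data,
                              type = c("tibble", "class", "score"), ...) {
  type <- match.arg(type)
  X <- model_matrix(object, new_data)
  out <- route_tree(object$root, X)
  cls <- if (is.null(object$label_map)) out$label else
    decode_labels(out$label, object$label_map)
  switch(type,
    tibble = tibble::tibble(.pred_class = cls, .pred_sign = out$label,
                            .pred_score = out$score),
    class = cls,
    score = out$score
  )
}

#' @export
print.mediboost <- function(x, ...) {
  engine <- if (x$algo == "mab") "exponential loss (MAB)"
            else "binomial likelihood (LMB)"
  cat("<mediboost tree>\n")
  cat(sprintf("  engine: %s\n", engine))
  cat(sprintf("  depth limit %d (reached %d), %d leaves%s\n",
              x$control$depth, x$max_depth_reached, x$n_leaves,
              if (x$pruned) " after sign-preserving pruning" else ""))
  cat(sprintf("  gamma = %g, learning_rate = %g, lambda = %g\n",
              x$control$gamma, x$control$learning_rate, x$control$lambda))
  cat(sprintf("  training balanced error: %.4f (n = %d)\n",
              x$train_balanced_error, x$n_train))
  if (!is.null(x$label_map)) {
    cat(sprintf("  positive class: %s\n", as.character(x$label_map$positive)))
  }
  invisible(x)
}
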