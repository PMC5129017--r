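#' Tidy a fitted tree into its node table
#'
#' One row per node in preorder: internal rows carry the split
#' (`feature`, `threshold`), the engine's coefficient (`alpha` for the
#' exponential-loss engine, `c_left`/`c_right` for the likelihood engine)
#' and the cumulative branch scores `G_left`/`G_right`; leaf rows carry the
#' predicted `leaf_label` and path score `G`.
#'
#' @param x A `mediboost` model.
#' @param ... Unused.
#' @return A tibble with one row per node.
#' @method tidy mediboost
#' @export
tidy.mediboost <- function(x, ...) {
  flatten_tree(x)
}

#' One-row summary of a fitted tree
#'
#' @param x A `mediboost` model.
#' @param ... Unused.
#' @return A one-row tibble with the engine, hyperparameters, tree size and
#'   training balanced error.
#' @method glance mediboost
#' @export
glance.mediboost <- function(x, ...) {
  tibble::tibble(
    algo = x$algo, depth = x$control$depth, gamma = x$control$gamma,
    learning_rate = x$control$learning_rate, lambda = x$control$lambda,
    n_leaves = x$n_leaves, max_depth_reached = x$max_depth_reached,
    pruned = x$pruned, n_train = x$n_train,
    train_balanced_error = x$train_balanced_error
  )
}

#' @method tidy mediboost_cv
#' @export
tidy.mediboost_cv <- function(x, ...) x$results

#' @method glance mediboost_cv
#' @export
glance.mediboost_cv <- function(x, ...) {
  tibble::tibble(
    learner = x$learner, trials = x$trials, folds = x$folds,
    n_fold_results = nrow(x$results),
    mean_balanced_error = mean(x$results$balanced_error),
    sd_balanced_error = stats::sd(x$results$balanced_error),
    mean_auc = mean(x$results$auc),
    sd_auc = stats::sd(x$results$auc)
  )
}

#' @method tidy mediboost_tune
#' @export
tidy.mediboost_tune <- function(x, ...) x$trace

#' @method tidy mediboost_permutation
#' @export
tidy.mediboost_permutation <- function(x, ...) {
  tibble::tibble(permutation = seq_along(x$perm_auc), auc = x$perm_auc)
}

#' @method glance mediboost_permutation
#' @export
glance.mediboost_permutation <- function(x, ...) {
  tibble::tibble(
    observed_auc = x$observed_auc, p_value = x$p_value,
    mean_perm_auc = x$mean_perm_auc, sd_perm_auc = x$sd_perm_auc, B = x$B
  )
}

#' @method tidy mediboost_comparison
#' @export
tidy.mediboost_comparison <- function(x, ...) x$metrics

#' @method glance mediboost_comparison
#' @export
glance.mediboost_comparison <- function(x, ...) x$pairwise

# in-order leaf positions for a simple tree drawing
tree_layout <- function(object) {
  nodes <- flatten_tree(object)
  xpos <- numeric(nrow(nodes))
  leaf_x <- 0
  assign_x <- function(id) {
    r <- nodes[nodes$id == id, ]
    if (r$is_leaf) {
      leaf_x <<- leaf_x + 1
      xpos[id] <<- leaf_x
    } else {
      assign_x(r$left_id)
      assign_x(r$right_id)
      xpos[id] <<- (xpos[r$left_id] + xpos[r$right_id]) / 2
    }
  }
  assign_x(1L)
  nodes$x <- xpos
  nodes$y <- -nodes$depth
  nodes
}

#' Plot a fitted tree
#'
#' Draws the tree with internal nodes labelled by their split and leaves by
#' their class and path score.
#'
#' @param object A `mediboost` model.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mediboost
#' @export
autoplot.mediboost <- function(object, ...) {
  nodes <- tree_layout(object)
  internal <- nodes[!nodes$is_leaf, ]
  edges <- dplyr::bind_rows(
    dplyr::left_join(internal, nodes[c("id", "x", "y")],
                     by = c("left_id" = "id"), suffix = c("", "_to")),
    dplyr::left_join(internal, nodes[c("id", "x", "y")],
                     by = c("right_id" = "id"), suffix = c("", "_to"))
  )
  nodes$lab <- ifelse(nodes$is_leaf,
                      sprintf("%+d\nG=%.3g", nodes$leaf_label, nodes$G),
                      sprintf("%s <= %.3g", nodes$feature, nodes$threshold))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y,
                   xend = .data$x_to, yend = .data$y_to),
      colour = "grey50") +
    ggplot2::geom_label(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$lab,
                   fill = .data$is_leaf),
      size = 3, show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#cfe8cf",
                                          `FALSE` = "#e8e8f8")) +
    ggplot2::theme_void()
}

#' Plot cross-validation results
#'
#' Per-fold balanced error and AUC as jittered points with a median line.
#'
#' @param object A `mediboost_cv` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mediboost_cv
#' @export
autoplot.mediboost_cv <- function(object, ...) {
  long <- tidyr::pivot_longer(object$results,
                              cols = c("balanced_error", "auc"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey92") +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.6) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("%s: %d x %d-fold cross-validation",
                                  object$learner, object$trials,
                                  object$folds)) +
    ggplot2::theme_minimal()
}

#' Plot a permutation-test null distribution
#'
#' Histogram of the permuted AUCs with the observed AUC marked.
#'
#' @param object A `mediboost_permutation` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mediboost_permutation
#' @export
autoplot.mediboost_permutation <- function(object, ...) {
  df <- tidy.mediboost_permutation(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$auc)) +
    ggplot2::geom_histogram(bins = 20, fill = "grey80", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed_auc,
                        colour = "firebrick", linewidth = 1) +
    ggplot2::labs(x = "permuted AUC", y = "count",
                  title = sprintf("p = %.3f (B = %d)", object$p_value,
                                  object$B)) +
    ggplot2::theme_minimal()
}

#' Plot a tuning trace
#'
#' Mean inner balanced error over the (depth, gamma) grid.
#'
#' @param object A `mediboost_tune` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mediboost_tune
#' @export
autoplot.mediboost_tune <- function(object, ...) {
  ggplot2::ggplot(object$trace,
                  ggplot2::aes(x = factor(.data$depth),
                               y = factor(.data$gamma),
                               fill = .data$mean_balanced_error)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "balanced error") +
    ggplot2::labs(x = "depth", y = "gamma") +
    ggplot2::theme_minimal()
}
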