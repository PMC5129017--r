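#' Sign-preserving pruning
#'
#' Bottom-up, any internal node whose descendant leaves all carry the same
#' class label is replaced by a single leaf with that label, so branches
#' that never change the sign of their parent's classification disappear.
#' Predictions are unchanged everywhere; the leaf count never increases; the
#' operation is idempotent. The merged leaf keeps the common label and, as
#' its score, the label's sign times the largest `|G|` among the merged
#' leaves, so score-based rankings inside the merged region are preserved.
#'
#' @param object A `mediboost` model.
#' @return The pruned `mediboost` model.
#' @examples
#' d <- sim_four_region(200, flip_noise = 0, seed = 2)
#' fit <- mediboost(d, "y", depth = 5, gamma = 30, prune = FALSE)
#' c(before = leaf_count(fit), after = leaf_count(prune_sign(fit)))
#' @export
prune_sign <- function(object) {
  check_mediboost(object)
  pr <- function(node) {
    if (isTRUE(node$leaf)) return(node)
    node$left <- pr(node$left)
    node$right <- pr(node$right)
    if (isTRUE(node$left$leaf) && isTRUE(node$right$leaf) &&
        node$left$label == node$right$label) {
      label <- node$left$label
      G <- label * max(abs(node$left$G), abs(node$right$G))
      return(list(leaf = TRUE, label = label, G = G, round = node$round,
                  n_train = (node$left$n_train %||% 0) +
                            (node$right$n_train %||% 0)))
    }
    node
  }
  object$root <- pr(object$root)
  object$n_leaves <- leaf_count(object)
  object$pruned <- TRUE
  object
}

#' Number of terminal nodes
#'
#' @param object A `mediboost` model.
#' @return Integer count of leaves (at most `2^depth`).
#' @export
leaf_count <- function(object) {
  check_mediboost(object)
  cnt <- function(node) {
    if (isTRUE(node$leaf)) 1L else cnt(node$left) + cnt(node$right)
  }
  cnt(object$root)
}

check_mediboost <- function(object) {
  if (!inherits(object, "mediboost")) {
    abort("expected a `mediboost` model object.",
          class = "mediboost_input_error")
  }
  invisible(object)
}

# flatten the recursive tree into a node table (preorder ids, root = 1)
flatten_tree <- function(object) {
  rows <- list()
  nid <- 0L
  walk <- function(node) {
    nid <<- nid + 1L
    id <- nid
    if (isTRUE(node$leaf)) {
      rows[[id]] <<- tibble::tibble(
        id = id, is_leaf = TRUE, feature = NA_character_,
        threshold = NA_real_, out_left = NA_real_, out_right = NA_real_,
        alpha = NA_real_, c_left = NA_real_, c_right = NA_real_,
        G_left = NA_real_, G_right = NA_real_,
        left_id = NA_integer_, right_id = NA_integer_,
        leaf_label = node$label, G = node$G, depth = node$round,
        n_train = node$n_train %||% NA_integer_
      )
      return(id)
    }
    rows[[id]] <<- tibble::tibble(
      id = id, is_leaf = FALSE,
      feature = object$feature_names[node$stump$feature],
      threshold = node$stump$threshold,
      out_left = node$stump$out_left, out_right = node$stump$out_right,
      alpha = node$alpha %||% NA_real_,
      c_left = node$c_left %||% NA_real_, c_right = node$c_right %||% NA_real_,
      G_left = node$G_left, G_right = node$G_right,
      left_id = NA_integer_, right_id = NA_integer_,
      leaf_label = NA_real_, G = NA_real_, depth = node$round,
      n_train = NA_integer_
    )
    lid <- walk(node$left)
    rid <- walk(node$right)
    rows[[id]]$left_id <<- lid
    rows[[id]]$right_id <<- rid
    id
  }
  walk(object$root)
  dplyr::bind_rows(rows)
}

#' Plain-text decision rules
#'
#' One `if ... then` rule per leaf, in the conjunction-of-conditions form
#' clinicians read directly off a tree.
#'
#' @param object A `mediboost` model.
#' @return Character vector, one rule per leaf.
#' @examples
#' d <- sim_four_region(200, flip_noise = 0, seed = 3)
#' tree_rules(mediboost(d, "y", depth = 3, gamma = 30))
#' @export
tree_rules <- function(object) {
  check_mediboost(object)
  class_of <- function(sign) {
    if (is.null(object$label_map)) format(sign)
    else as.character(decode_labels(sign, object$label_map))
  }
  out <- character(0)
  walk <- function(node, conds) {
    if (isTRUE(node$leaf)) {
      lhs <- if (length(conds) == 0L) "always"
             else paste("if", paste(conds, collapse = " and "))
      out[[length(out) + 1L]] <<- sprintf("%s then class %s (score %.4g)",
                                          lhs, class_of(node$label), node$G)
      return(invisible(NULL))
    }
    nm <- object$feature_names[node$stump$feature]
    th <- format(node$stump$threshold, digits = 6)
    walk(node$left, c(conds, paste0(nm, " <= ", th)))
    walk(node$right, c(conds, paste0(nm, " > ", th)))
  }
  walk(object$root, character(0))
  out
}

#' Graphviz DOT rendering
#'
#' Writes the tree in DOT format: internal nodes display `name <= threshold`,
#' edges are labelled `left`/`right`, and leaves show the predicted class and
#' the path score `G`. Feature names longer than 20 characters are replaced
#' by `A<index>` with a legend appended to the graph label, mirroring how
#' long attribute names are abbreviated in published trees.
#'
#' @param object A `mediboost` model.
#' @param file Optional path; when given the DOT text is also written there.
#' @return The DOT text, invisibly when `file` is given.
#' @export
tree_to_dot <- function(object, file = NULL) {
  check_mediboost(object)
  nodes <- flatten_tree(object)
  legend <- character(0)
  disp <- function(nm) {
    if (nchar(nm) > 20L) {
      idx <- match(nm, object$feature_names)
      short <- paste0("A", idx)
      legend[[short]] <<- nm
      short
    } else nm
  }
  class_of <- function(sign) {
    if (is.null(object$label_map)) sprintf("%+d", sign)
    else as.character(decode_labels(sign, object$label_map))
  }
  lines <- c("digraph mediboost {", "  node [shape=box];")
  for (i in seq_len(nrow(nodes))) {
    r <- nodes[i, ]
    if (r$is_leaf) {
      lines <- c(lines, sprintf(
        "  n%d [label=\"class %s\\nG=%.4g\", shape=ellipse];",
        r$id, class_of(r$leaf_label), r$G))
    } else {
      lines <- c(lines, sprintf("  n%d [label=\"%s <= %.6g\"];",
                                r$id, disp(r$feature), r$threshold))
    }
  }
  for (i in seq_len(nrow(nodes))) {
    r <- nodes[i, ]
    if (!r$is_leaf) {
      lines <- c(lines,
                 sprintf("  n%d -> n%d [label=\"left\"];", r$id, r$left_id),
                 sprintf("  n%d -> n%d [label=\"right\"];", r$id, r$right_id))
    }
  }
  if (length(legend) > 0L) {
    leg <- paste(sprintf("%s = %s", names(legend), unlist(legend)),
                 collapse = "\\n")
    lines <- c(lines, sprintf("  label=\"%s\";", leg))
  }
  lines <- c(lines, "}")
  txt <- paste(lines, collapse = "\n")
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' Serialise a model to JSON
#'
#' Writes the complete model — engine, hyperparameters, tie label, label
#' mapping, preprocessing statistics and the flattened node table — to a JSON
#' document. [mediboost_from_json()] restores a model that predicts
#' identically.
#'
#' @param object A `mediboost` model.
#' @param file Optional path to write to.
#' @return JSON text (invisibly when `file` is given).
#' @export
mediboost_to_json <- function(object, file = NULL) {
  check_mediboost(object)
  payload <- list(
    format = "mediboost-tree",
    version = 1L,
    algo = object$algo,
    hyperparams = unclass(object$control),
    tie_label = object$tie_label,
    feature_names = as.list(object$feature_names),
    n_leaves = object$n_leaves,
    max_depth_reached = object$max_depth_reached,
    pruned = object$pruned,
    label_map = if (is.null(object$label_map)) NULL else
      list(positive = object$label_map$positive,
           negative = object$label_map$negative),
    original_features = if (is.null(object$original_features)) NULL else
      as.list(object$original_features),
    preprocess = object$preprocess,
    nodes = flatten_tree(object)
  )
  txt <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = I(17),
                          na = "null", null = "null", pretty = TRUE)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(as.character(txt)))
  }
  as.character(txt)
}

schema_abort <- function(...) {
  abort(paste0(...), class = "mediboost_schema_error")
}

#' Restore a model from JSON
#'
#' @param x JSON text, or the path of a file produced by
#'   [mediboost_to_json()].
#' @return A `mediboost` model.
#' @export
mediboost_from_json <- function(x) {
  if (length(x) == 1L && !grepl("^\\s*\\{", x)) {
    if (!file.exists(x)) {
      abort(paste0("model file not found: ", x),
            class = "mediboost_input_error")
    }
    x <- paste(readLines(x, warn = FALSE), collapse = "\n")
  }
  p <- jsonlite::fromJSON(x, simplifyDataFrame = TRUE)
  if (is.null(p$algo) || !p$algo %in% c("mab", "lmb")) {
    schema_abort("field 'algo' must be 'mab' or 'lmb'; got '",
                 p$algo %||% "missing", "'.")
  }
  nodes <- p$nodes
  if (is.null(nodes) || !is.data.frame(nodes) || nrow(nodes) == 0L) {
    schema_abort("field 'nodes' must be a non-empty array of node objects.")
  }
  required <- c("id", "is_leaf", "feature", "threshold", "G_left", "G_right",
                "left_id", "right_id", "leaf_label", "G", "depth")
  miss <- setdiff(required, names(nodes))
  if (length(miss) > 0L) {
    schema_abort("nodes table lacks field(s): ", paste(miss, collapse = ", "))
  }
  if (is.null(p$hyperparams)) schema_abort("field 'hyperparams' is missing.")
  if (is.null(p$tie_label) || !p$tie_label %in% c(-1, 1)) {
    schema_abort("field 'tie_label' must be -1 or 1.")
  }
  feature_names <- unlist(p$feature_names)
  if (is.null(feature_names)) schema_abort("field 'feature_names' is missing.")
  control <- do.call(mediboost_control, p$hyperparams[
    c("depth", "gamma", "learning_rate", "lambda", "eps_min",
      "min_membership")])
  idx <- match(seq_len(nrow(nodes)), nodes$id)
  if (anyNA(idx)) schema_abort("node ids must be 1..n_nodes.")
  build <- function(id) {
    r <- nodes[nodes$id == id, ]
    if (nrow(r) != 1L) schema_abort("node id ", id, " not unique or missing.")
    if (isTRUE(r$is_leaf)) {
      if (is.na(r$leaf_label) || !r$leaf_label %in% c(-1, 1)) {
        schema_abort("leaf node ", id, ": field 'leaf_label' must be -1 or 1.")
      }
      if (is.na(r$G)) schema_abort("leaf node ", id, ": field 'G' is missing.")
      return(list(leaf = TRUE, label = r$leaf_label, G = r$G,
                  round = r$depth,
                  n_train = if ("n_train" %in% names(r)) r$n_train else NA))
    }
    fidx <- match(r$feature, feature_names)
    if (is.na(fidx)) {
      schema_abort("internal node ", id, ": unknown feature '", r$feature, "'.")
    }
    for (f in c("threshold", "G_left", "G_right")) {
      if (is.na(r[[f]])) {
        schema_abort("internal node ", id, ": field '", f, "' is missing.")
      }
    }
    if (p$algo == "mab" && (!"alpha" %in% names(r) || is.na(r$alpha))) {
      schema_abort("internal node ", id, ": field 'alpha' required for mab.")
    }
    if (p$algo == "lmb" &&
        (!all(c("c_left", "c_right") %in% names(r)) ||
         is.na(r$c_left) || is.na(r$c_right))) {
      schema_abort("internal node ", id,
                   ": fields 'c_left'/'c_right' required for lmb.")
    }
    if (is.na(r$left_id) || is.na(r$right_id)) {
      schema_abort("internal node ", id, ": child ids are missing.")
    }
    node <- list(leaf = FALSE,
                 stump = list(feature = fidx, threshold = r$threshold,
                              out_left = r$out_left, out_right = r$out_right),
                 round = r$depth, G_left = r$G_left, G_right = r$G_right,
                 left = build(r$left_id), right = build(r$right_id))
    if (p$algo == "mab") node$alpha <- r$alpha
    else { node$c_left <- r$c_left; node$c_right <- r$c_right }
    node
  }
  root <- build(1L)
  preprocess <- p$preprocess
  if (!is.null(preprocess)) {
    preprocess$columns <- unlist(preprocess$columns)
    preprocess$levels <- lapply(preprocess$levels, unlist)
  }
  structure(
    list(root = root, algo = p$algo, control = control,
         tie_label = p$tie_label, feature_names = feature_names,
         n_leaves = p$n_leaves %||% NA_integer_,
         max_depth_reached = p$max_depth_reached %||% NA_integer_,
         n_train = NA_integer_, fitted = NULL,
         train_balanced_error = NA_real_,
         pruned = isTRUE(p$pruned),
         preprocess = preprocess,
         label_map = if (is.null(p$label_map)) NULL else p$label_map,
         original_features = unlist(p$original_features)),
    class = "mediboost"
  )
}
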