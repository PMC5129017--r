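# a small pool of trained trees of both engines on varied data
trained_pool <- local({
  pool <- list()
  for (seed in 1:10) {
    d <- if (seed %% 2 == 0) {
      sim_four_region(120, flip_noise = 0.15, seed = seed)
    } else {
      sim_additive_logistic(120, d = 4, seed = seed)
    }
    X <- as.matrix(d[setdiff(names(d), "y")])
    ctl <- mediboost_control(depth = 3 + seed %% 3, gamma = c(0, 1, 4, 30)[1 + seed %% 4],
                             learning_rate = if (seed %% 2 == 0) 0.1 else 0.5)
    pool[[2 * seed - 1]] <- build_mab(X, d$y, ctl)
    pool[[2 * seed]] <- build_lmb(X, d$y, ctl)
  }
  pool
})

fresh_rows <- function(d, n = 1000, seed = 999) {
  withr::with_seed(seed, matrix(runif(n * d), n, d))
}

test_that("prediction routes by the fixed tie convention and is pure", {
  d <- sim_four_region(150, flip_noise = 0, seed = 4)
  X <- as.matrix(d[c("x1", "x2")])
  fit <- build_lmb(X, d$y, mediboost_control(depth = 2, gamma = 30))
  # a value exactly at the root threshold goes left
  th <- fit$root$stump$threshold
  f <- fit$root$stump$feature
  probe <- X[1:2, , drop = FALSE]
  probe[1, f] <- th
  p <- predict(fit, probe)
  left_G <- function(node) if (isTRUE(node$leaf)) node$G else left_G(node$left)
  expect_equal(p$.pred_score[1],
               { n <- fit$root$left; while (!isTRUE(n$leaf)) {
                   n <- if (probe[1, n$stump$feature] <= n$stump$threshold)
                     n$left else n$right }; n$G })
  expect_identical(predict(fit, X), predict(fit, X))
  expect_error(predict(fit, X[, 1, drop = FALSE]),
               class = "mediboost_input_error")
})

test_that("a depth-0 tree predicts the tie label with zero score", {
  X <- matrix(runif(40), ncol = 2)
  y <- c(rep(1, 8), rep(-1, 12))
  fit <- build_mab(X, y, mediboost_control(depth = 0))
  p <- predict(fit, X)
  expect_true(all(p$.pred_sign == -1))  # majority class
  expect_true(all(p$.pred_score == 0))
  expect_equal(leaf_count(fit), 1L)
})

test_that("sign-preserving pruning never changes a prediction", {
  for (fit in trained_pool) {
    Xf <- fresh_rows(length(fit$feature_names))
    colnames(Xf) <- fit$feature_names
    pruned <- prune_sign(fit)
    expect_lte(pruned$n_leaves, fit$n_leaves)
    expect_identical(predict(pruned, Xf)$.pred_sign,
                     predict(fit, Xf)$.pred_sign)
    # idempotence
    again <- prune_sign(pruned)
    expect_equal(again$n_leaves, pruned$n_leaves)
    expect_identical(tidy(again)[c("feature", "threshold", "leaf_label")],
                     tidy(pruned)[c("feature", "threshold", "leaf_label")])
  }
})

test_that("a tree whose leaves all agree collapses to one leaf", {
  X <- matrix(runif(60), ncol = 2)
  fit <- build_lmb(X, rep(1, 30), mediboost_control(depth = 3, gamma = 2))
  pruned <- prune_sign(fit)
  expect_equal(pruned$n_leaves, 1L)
  expect_true(isTRUE(pruned$root$leaf))
})

test_that("structure bounds hold: leaves <= 2^depth, thresholds feasible", {
  for (fit in trained_pool) {
    expect_lte(leaf_count(fit), 2^fit$control$depth)
    expect_lte(fit$max_depth_reached, fit$control$depth)
    # every internal threshold strictly inside its path's feasible interval
    check <- function(node, lo, hi) {
      if (isTRUE(node$leaf)) return(invisible(NULL))
      j <- node$stump$feature; th <- node$stump$threshold
      expect_gt(th, lo[j]); expect_lt(th, hi[j])
      hi_l <- hi; hi_l[j] <- th
      lo_r <- lo; lo_r[j] <- th
      check(node$left, lo, hi_l)
      check(node$right, lo_r, hi)
    }
    ddim <- length(fit$feature_names)
    check(fit$root, rep(-Inf, ddim), rep(Inf, ddim))
  }
})

test_that("rule extraction yields one rule per leaf", {
  for (fit in trained_pool[1:4]) {
    expect_length(tree_rules(fit), leaf_count(fit))
  }
  d0 <- build_mab(matrix(runif(20), ncol = 2), rep(c(-1, 1), 5),
                  mediboost_control(depth = 0))
  expect_match(tree_rules(d0), "^always")
})

test_that("DOT export contains one node statement per tree node", {
  for (fit in trained_pool[1:6]) {
    lines <- strsplit(tree_to_dot(fit), "\n")[[1]]
    nodes <- tidy(fit)
    expect_equal(sum(grepl("^  n[0-9]+ \\[label", lines)), nrow(nodes))
    expect_equal(sum(grepl("->", lines, fixed = TRUE)),
                 sum(!nodes$is_leaf) * 2)
  }
  d0 <- build_mab(matrix(runif(20), ncol = 2), rep(c(-1, 1), 5),
                  mediboost_control(depth = 0))
  lines0 <- strsplit(tree_to_dot(d0), "\n")[[1]]
  expect_equal(sum(grepl("^  n[0-9]+ \\[label", lines0)), 1L)
  expect_false(any(grepl("->", lines0, fixed = TRUE)))
})

test_that("long feature names are abbreviated with a legend", {
  nm <- c("an_extremely_long_clinical_attribute_name", "x2")
  X <- matrix(runif(100), ncol = 2, dimnames = list(NULL, nm))
  y <- ifelse(X[, 1] > 0.5, 1, -1)
  fit <- build_lmb(X, y, mediboost_control(depth = 2, gamma = 30))
  dot <- tree_to_dot(fit)
  expect_match(dot, "A1 <=")
  expect_match(dot, "A1 = an_extremely_long_clinical_attribute_name")
})

test_that("JSON round-trips preserve predictions exactly", {
  for (fit in trained_pool[c(1, 4, 7, 10, 13, 16)]) {
    Xf <- fresh_rows(length(fit$feature_names), n = 500, seed = 31)
    colnames(Xf) <- fit$feature_names
    back <- mediboost_from_json(mediboost_to_json(fit))
    expect_identical(predict(back, Xf), predict(fit, Xf))
    expect_equal(back$algo, fit$algo)
    expect_equal(back$control, fit$control)
  }
})

test_that("a full model with preprocessing round-trips through a file", {
  df <- data.frame(
    age = c(55, 61, NA, 47, 70, 52, 66, 58, NA, 49, 63, 71),
    stage = c("i", "ii", "ii", NA, "i", "ii", "i", "i", "ii", "i", NA, "ii"),
    outcome = rep(c("good", "poor"), 6)
  )
  fit <- mediboost(df, "outcome", depth = 3, gamma = 2)
  path <- withr::local_tempfile(fileext = ".json")
  mediboost_to_json(fit, file = path)
  back <- mediboost_from_json(path)
  expect_identical(predict(back, df), predict(fit, df))
  expect_equal(back$label_map$positive, "poor")
})

test_that("malformed JSON models are rejected field-by-field", {
  fit <- trained_pool[[1]]
  txt <- mediboost_to_json(fit)
  p <- jsonlite::fromJSON(txt, simplifyDataFrame = TRUE)

  bad <- p; bad$algo <- "boosted_forest"
  expect_error(mediboost_from_json(jsonlite::toJSON(bad, auto_unbox = TRUE, na = "null")),
               "algo", class = "mediboost_schema_error")
  bad <- p; bad$nodes <- bad$nodes[0, ]
  expect_error(mediboost_from_json(jsonlite::toJSON(bad, auto_unbox = TRUE, na = "null")),
               "nodes", class = "mediboost_schema_error")
  bad <- p; bad$nodes$threshold <- NULL
  expect_error(mediboost_from_json(jsonlite::toJSON(bad, auto_unbox = TRUE, na = "null")),
               "threshold", class = "mediboost_schema_error")
  bad <- p; bad$tie_label <- 3
  expect_error(mediboost_from_json(jsonlite::toJSON(bad, auto_unbox = TRUE, na = "null")),
               "tie_label", class = "mediboost_schema_error")
})
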