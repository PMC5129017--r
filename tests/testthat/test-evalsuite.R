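test_that("balanced error matches its closed forms and symmetries", {
  expect_equal(balanced_error(c(1, 1, -1, -1), c(1, 1, -1, -1)), 0)
  # all-positive predictions on mixed truth: 1 - (1 + 0)/2
  expect_equal(balanced_error(c(1, -1, -1, 1), rep(1, 4)), 0.5)
  # TP=3, FN=1, TN=2, FP=2 -> 1 - (0.75 + 0.5)/2
  y <- c(rep(1, 4), rep(-1, 4))
  p <- c(1, 1, 1, -1, 1, 1, -1, -1)
  expect_equal(balanced_error(y, p), 0.375)
  # invariant under simultaneous class relabelling
  expect_equal(balanced_error(-y, -p), balanced_error(y, p))
  expect_error(balanced_error(rep(1, 4), rep(1, 4)),
               class = "mediboost_input_error")
})

test_that("AUC equals brute-force pair counting, including ties", {
  expect_equal(auc_score(c(-1, -1, 1, 1), c(0.1, 0.2, 0.7, 0.9)), 1)
  expect_equal(auc_score(c(-1, 1, -1, 1), rep(0.5, 4)), 0.5)
  for (i in 1:100) {
    withr::with_seed(i, {
      y <- c(-1, 1, sample(c(-1, 1), 18, replace = TRUE))
      s <- sample(seq(0, 1, by = 0.25), 20, replace = TRUE)  # force ties
    })
    expect_equal(auc_score(y, s), auc_pairs(y, s), tolerance = 1e-12)
  }
  # complement symmetry for tie-free scores
  withr::with_seed(7, {
    y <- c(rep(1, 10), rep(-1, 10))
    s <- rnorm(20)
  })
  expect_equal(auc_score(y, s) + auc_score(y, -s), 1)
})

test_that("stratified folds cover both classes and respect the seed", {
  y <- c(rep(1, 30), rep(-1, 20))
  f1 <- stratified_folds(y, 5, seed = 3)
  f2 <- stratified_folds(y, 5, seed = 3)
  expect_identical(f1, f2)
  for (k in 1:5) {
    expect_true(all(table(y[f1 == k]) > 0))
  }
  expect_equal(unname(table(f1[y == 1])), rep(6L, 5), ignore_attr = TRUE)
  expect_error(stratified_folds(c(rep(1, 3), rep(-1, 30)), 5),
               class = "mediboost_input_error")
})

test_that("the repeated protocol yields trials x folds results, deterministically", {
  d <- sim_four_region(100, flip_noise = 0.1, seed = 6)
  cv1 <- repeated_cv(d, "y", learner_mediboost(depth = 2, gamma = 4),
                     trials = 5, folds = 5, seed = 11)
  expect_equal(nrow(cv1$results), 25L)
  cv2 <- repeated_cv(d, "y", learner_mediboost(depth = 2, gamma = 4),
                     trials = 5, folds = 5, seed = 11)
  expect_identical(cv1$results, cv2$results)
  g <- glance(cv1)
  expect_equal(g$n_fold_results, 25L)
  expect_lt(g$mean_balanced_error, 0.5)
})

test_that("a constant learner scores balanced error one half on stratified folds", {
  d <- sim_four_region(120, flip_noise = 0.1, seed = 8)
  cv <- repeated_cv(d, "y", learner_constant(), trials = 2, folds = 5,
                    seed = 2)
  expect_true(all(cv$results$balanced_error == 0.5))
  expect_true(all(cv$results$auc == 0.5))
})

test_that("nested tuning selects a depth that recovers the generator", {
  d <- sim_four_region(250, flip_noise = 0, seed = 12)
  grid <- expand.grid(depth = c(2, 3, 6), gamma = c(4, 30))
  tn <- tune_nested(d, "y", algo = "lmb", grid = grid, seed = 5)
  expect_equal(nrow(tn$trace), nrow(grid))
  # depth 2 cannot express the interaction greedily; deeper grids can
  expect_gte(tn$best$depth, 3)
  expect_lte(min(tn$trace$mean_balanced_error), 0.05)
  # singleton grid is returned unchanged
  tn1 <- tune_nested(d, "y", grid = data.frame(depth = 2, gamma = 4), seed = 5)
  expect_equal(tn1$best, list(depth = 2, gamma = 4))
  # ties break towards the smaller depth, then smaller gamma
  tied <- tune_nested(d, "y", grid = data.frame(depth = c(3, 2, 2),
                                                gamma = c(30, 30, 4)),
                      seed = 7)
  expect_lte(tied$best$depth, 3)
})

test_that("permutation p-values separate signal from noise", {
  strong <- sim_four_region(120, flip_noise = 0.05, seed = 13)
  pt <- permutation_test(strong, "y", learner_mediboost(depth = 3, gamma = 4),
                         B = 30, seed = 3)
  expect_gte(pt$p_value, 1 / 31)
  expect_lte(pt$p_value, 2 / 31)
  expect_equal(length(pt$perm_auc), 30L)
  expect_lt(pt$mean_perm_auc, pt$observed_auc)

  # B = 1 admits only the two add-one outcomes
  tiny <- sim_four_region(60, flip_noise = 0.1, seed = 14)
  p1 <- permutation_test(tiny, "y", learner_mediboost(depth = 1, gamma = 4),
                         B = 1, seed = 4)
  expect_true(p1$p_value %in% c(0.5, 1))
})

test_that("the comparison harness tallies wins, losses, ties and the sign test", {
  datasets <- lapply(1:3, function(s) sim_four_region(90, 0.1, seed = s + 40))
  cmp <- compare_learners(datasets, "y",
                          list(lmb = learner_mediboost(depth = 2, gamma = 4),
                               lmb_again = learner_mediboost(depth = 2, gamma = 4),
                               cart = learner_greedy_tree(depth = 2)),
                          trials = 1, folds = 3, seed = 9)
  expect_equal(nrow(cmp$metrics), 9L)
  pw <- cmp$pairwise
  # a learner against its identical twin ties everywhere
  self <- pw[pw$learner_a == "lmb" & pw$learner_b == "lmb_again", ]
  expect_true(all(self$ties == 3))
  expect_true(all(self$wins == 0))
  # counts always partition the datasets
  expect_true(all(pw$wins + pw$losses + pw$ties == 3))
  # the sign-test closed form: 10 wins, 0 losses
  expect_equal(stats::binom.test(10, 10, 0.5)$p.value, 2 * 0.5^10)
})

test_that("learners that overfit hard do not beat consistent ones on separable data", {
  d <- sim_four_region(150, flip_noise = 0, seed = 44)
  cv_good <- repeated_cv(d, "y", learner_mediboost(depth = 3, gamma = 30),
                         trials = 1, folds = 5, seed = 5)
  cv_const <- repeated_cv(d, "y", learner_constant(), trials = 1, folds = 5,
                          seed = 5)
  expect_lt(mean(cv_good$results$balanced_error),
            mean(cv_const$results$balanced_error))
})
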