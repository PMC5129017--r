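test_that("pseudo-residuals follow the closed form and never overflow", {
  expect_equal(pseudo_residuals(c(1, -1), c(0, 0)), c(1, -1))
  expect_equal(pseudo_residuals(1, 0.5), 2 / (1 + exp(1)))
  expect_equal(pseudo_residuals(1, 40), 2 * plogis(-80))
  expect_true(is.finite(pseudo_residuals(1, 1e4)))
  expect_true(all(abs(pseudo_residuals(c(-1, 1), c(-50, -50))) <= 2))
})

test_that("Newton coefficients match the closed form and a numeric oracle", {
  expect_equal(newton_coefficient(1, 1), 1)          # y=+1, F=0, lambda=0
  expect_equal(newton_coefficient(1, 1, lambda = 1), 0.5)
  expect_equal(newton_coefficient(numeric(0), numeric(0)), 0)
  expect_equal(newton_coefficient(c(0, 0), c(1, 1)), 0)  # zero denominator

  # one Newton step on the pooled binomial loss, second derivative by
  # central finite differences
  withr::with_seed(8, {
    y <- sample(c(-1, 1), 12, replace = TRUE)
    fs <- rnorm(12, sd = 0.7)
    m <- runif(12)
  })
  r <- pseudo_residuals(y, fs)
  loss <- function(delta) sum(m * log(1 + exp(-2 * y * (fs + delta))))
  h <- 1e-5
  grad <- (loss(h) - loss(-h)) / (2 * h)
  hess <- (loss(h) - 2 * loss(0) + loss(-h)) / h^2
  expect_equal(newton_coefficient(r, m), -grad / hess, tolerance = 1e-5)
})

test_that("with gamma = 0 growth equals stump gradient boosting exactly", {
  for (seed in 1:10) {
    d <- sim_additive_logistic(150, d = 5, seed = seed + 30)
    X <- as.matrix(d[paste0("x", 1:5)])
    for (rounds in c(3, 5)) {
      fit <- build_lmb(X, d$y, mediboost_control(depth = rounds, gamma = 0,
                                                 learning_rate = 0.1))
      ora <- gradboost_oracle(X, d$y, rounds, nu = 0.1)
      expect_equal(fit$fitted$.working_score, ora$score, tolerance = 1e-8)
      expect_identical(fit$fitted$.pred_sign,
                       ifelse(ora$score > 0, 1,
                              ifelse(ora$score < 0, -1, fit$tie_label)))
    }
  }
})

test_that("pure-node input drives the score positive in one step", {
  X <- matrix(runif(20), ncol = 2)
  y <- rep(1, 10)
  fit <- build_lmb(X, y, mediboost_control(depth = 3, gamma = 0))
  expect_true(all(fit$fitted$.pred_sign == 1))
  expect_true(all(fit$fitted$.working_score > 0))
})

test_that("depth 0 yields a single leaf predicting the tie label", {
  d <- sim_four_region(50, flip_noise = 0.2, seed = 9)
  X <- as.matrix(d[c("x1", "x2")])
  fit <- build_lmb(X, d$y, mediboost_control(depth = 0))
  expect_equal(fit$n_leaves, 1L)
  expect_true(all(predict(fit, X)$.pred_sign == fit$tie_label))
  expect_true(all(predict(fit, X)$.pred_score == 0))
})

test_that("training binomial loss is non-increasing in depth at gamma 0", {
  d <- sim_additive_logistic(200, d = 4, seed = 17)
  X <- as.matrix(d[paste0("x", 1:4)])
  loss <- vapply(1:5, function(rounds) {
    fit <- build_lmb(X, d$y, mediboost_control(depth = rounds, gamma = 0,
                                               learning_rate = 0.1))
    sum(log(1 + exp(-2 * d$y * fit$fitted$.working_score)))
  }, numeric(1))
  expect_true(all(diff(loss) <= 1e-8))
})

test_that("an overwhelming ridge penalty collapses the tree to the tie label", {
  d <- sim_four_region(100, flip_noise = 0.1, seed = 21)
  X <- as.matrix(d[c("x1", "x2")])
  fit <- build_lmb(X, d$y, mediboost_control(depth = 4, gamma = 2,
                                             lambda = 1e12))
  expect_true(all(predict(fit, X)$.pred_sign == fit$tie_label))
  expect_equal(prune_sign(fit)$n_leaves, 1L)
})

test_that("the gamma = 30 tree equals hard recursive partitioning", {
  for (seed in 1:4) {
    d <- sim_four_region(200, flip_noise = 0.1, seed = seed)
    X <- as.matrix(d[c("x1", "x2")])
    for (algo in c("mab", "lmb")) {
      ctl <- mediboost_control(depth = 3, gamma = 30)
      fit <- if (algo == "mab") build_mab(X, d$y, ctl) else build_lmb(X, d$y, ctl)
      ref <- hard_partition_tree(X, d$y, ctl, algo)
      sig_fit <- tree_signature(fit$root)
      sig_ref <- tree_signature(ref)
      expect_equal(length(sig_fit), length(sig_ref))
      for (i in seq_along(sig_fit)) {
        expect_equal(sig_fit[[i]]$kind, sig_ref[[i]]$kind)
        if (sig_fit[[i]]$kind == "split") {
          expect_equal(sig_fit[[i]]$feature, sig_ref[[i]]$feature)
          expect_equal(sig_fit[[i]]$threshold, sig_ref[[i]]$threshold)
        } else {
          expect_equal(sig_fit[[i]]$label, sig_ref[[i]]$label)
          expect_equal(sig_fit[[i]]$G, sig_ref[[i]]$G, tolerance = 1e-8)
        }
      }
    }
  }
})

test_that("training balanced error is non-increasing in gamma for LMB too", {
  gammas <- c(0, 1, 2, 4)
  errs <- matrix(NA_real_, 10, length(gammas))
  for (s in 1:10) {
    d <- sim_additive_logistic(200, d = 5, seed = s + 90)
    X <- as.matrix(d[paste0("x", 1:5)])
    for (g in seq_along(gammas)) {
      fit <- build_lmb(X, d$y, mediboost_control(depth = 4, gamma = gammas[g]))
      errs[s, g] <- fit$train_balanced_error
    }
  }
  avg <- colMeans(errs)
  expect_true(all(diff(avg) <= 0.01))
})
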