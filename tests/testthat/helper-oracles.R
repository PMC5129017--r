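# Independent oracles used across the suite. These deliberately recompute
# everything by direct enumeration / direct summation rather than calling the
# package's fitters, sharing only the public conventions: thresholds at
# midpoints of consecutive distinct values among instances with weight
# > max(w) * 1e-9, routing x <= threshold left, and ties resolved to the
# first candidate (feature asc, threshold asc, negative-left polarity first)
# within a relative tolerance of 1e-10.

oracle_candidates <- function(x, keep) {
  ux <- sort(unique(x[keep]))
  if (length(ux) < 2) return(numeric(0))
  (ux[-1] + ux[-length(ux)]) / 2
}

# exhaustive weighted-error stump search
brute_stump_error <- function(X, y, w) {
  keep <- w > max(w) * 1e-9
  W <- sum(w)
  cands <- list()
  for (j in seq_len(ncol(X))) {
    for (th in oracle_candidates(X[, j], keep)) {
      left <- X[, j] <= th
      for (pol in c(-1, 1)) {
        pred <- ifelse(left, pol, -pol)
        err <- sum(w[pred != y]) / W
        cands[[length(cands) + 1]] <- list(feature = j, threshold = th,
                                           out_left = pol, error = err)
      }
    }
  }
  if (length(cands) == 0) return(NULL)
  errs <- vapply(cands, `[[`, numeric(1), "error")
  best <- min(errs)
  pick <- cands[[which(errs <= best + 1e-10 * (1 + abs(best)))[1]]]
  pick$out_right <- -pick$out_left
  pick
}

# exhaustive weighted least-squares stump search
brute_stump_ls <- function(X, r, m) {
  keep <- m > max(m) * 1e-9
  cands <- list()
  for (j in seq_len(ncol(X))) {
    for (th in oracle_candidates(X[, j], keep)) {
      left <- X[, j] <= th
      cl <- sum(m[left] * r[left]) / sum(m[left])
      cr <- sum(m[!left] * r[!left]) / sum(m[!left])
      sse <- sum(m[left] * (r[left] - cl)^2) +
        sum(m[!left] * (r[!left] - cr)^2)
      cands[[length(cands) + 1]] <- list(feature = j, threshold = th,
                                         out_left = cl, out_right = cr,
                                         sse = sse)
    }
  }
  if (length(cands) == 0) return(NULL)
  sses <- vapply(cands, `[[`, numeric(1), "sse")
  best <- min(sses)
  cands[[which(sses <= best + 1e-10 * (1 + abs(best)))[1]]]
}

# discrete AdaBoost on stumps, coded directly from the additive-logistic
# recipe: weights exp(-yF), alpha = log((1-e)/e)/2 with clipping
adaboost_oracle <- function(X, y, rounds, nu = 1, eps_min = 1e-6) {
  n <- nrow(X)
  fs <- numeric(n)
  stumps <- list()
  alphas <- numeric(0)
  for (t in seq_len(rounds)) {
    w <- exp(-y * fs)
    w <- w / sum(w)
    st <- brute_stump_error(X, y, w)
    if (is.null(st)) break
    e <- min(max(st$error, eps_min), 1 - eps_min)
    alpha <- 0.5 * log((1 - e) / e)
    if (alpha <= 0) break
    h <- ifelse(X[, st$feature] <= st$threshold, st$out_left, st$out_right)
    fs <- fs + nu * alpha * h
    stumps[[t]] <- st
    alphas[t] <- alpha
  }
  tie <- if (sum(y > 0) * 2 >= n) 1 else -1
  score_fun <- function(Xn) {
    s <- numeric(nrow(Xn))
    for (t in seq_along(stumps)) {
      st <- stumps[[t]]
      s <- s + nu * alphas[t] *
        ifelse(Xn[, st$feature] <= st$threshold, st$out_left, st$out_right)
    }
    s
  }
  list(stumps = stumps, alphas = alphas, score = score_fun,
       label = function(Xn) {
         s <- score_fun(Xn)
         ifelse(s > 0, 1, ifelse(s < 0, -1, tie))
       })
}

# gradient boosting of regression stumps on the binomial log-likelihood with
# Newton side coefficients (same residual / split / coefficient formulas)
gradboost_oracle <- function(X, y, rounds, nu = 0.1, lambda = 0) {
  n <- nrow(X)
  fs <- numeric(n)
  stumps <- list()
  for (t in seq_len(rounds)) {
    r <- 2 * y / (1 + exp(2 * y * fs))
    st <- brute_stump_ls(X, r, rep(1, n))
    if (is.null(st)) break
    left <- X[, st$feature] <= st$threshold
    cl <- sum(r[left]) / (sum(abs(r[left]) * (2 - abs(r[left]))) + lambda)
    cr <- sum(r[!left]) / (sum(abs(r[!left]) * (2 - abs(r[!left]))) + lambda)
    if (abs(cl) < 1e-12 && abs(cr) < 1e-12) break
    fs <- fs + nu * ifelse(left, cl, cr)
    stumps[[t]] <- c(st, list(c_left = cl, c_right = cr))
  }
  list(stumps = stumps, score = fs)
}

# all-pairs AUC with ties counted one half
auc_pairs <- function(y, s) {
  sp <- s[y == 1]
  sn <- s[y == -1]
  tot <- 0
  for (a in sp) tot <- tot + sum(a > sn) + 0.5 * sum(a == sn)
  tot / (length(sp) * length(sn))
}

# hard recursive partitioning variant: same stump fitters and bookkeeping,
# but memberships below exp(-gamma/2) are zeroed, i.e. off-branch instances
# are dropped outright
hard_partition_tree <- function(X, y, control, algo) {
  n <- nrow(X)
  tie <- if (sum(y > 0) * 2 >= n) 1 else -1
  cutoff <- exp(-control$gamma / 2)
  rec <- function(m, fs, G, round) {
    leaf <- function() list(leaf = TRUE,
                            label = if (G > 0) 1 else if (G < 0) -1 else tie,
                            G = G)
    if (round >= control$depth || sum(m) / n < control$min_membership) {
      return(leaf())
    }
    if (algo == "mab") {
      w <- m * exp(-y * fs)
      if (sum(w) == 0) return(leaf())
      fit <- fit_stump_error(X, y, w / sum(w))
      if (is.null(fit)) return(leaf())
      alpha <- alpha_from_error(fit$error, control$eps_min)
      if (alpha <= 0) return(leaf())
      st <- fit$stump
      h <- ifelse(X[, st$feature] <= st$threshold, st$out_left, st$out_right)
      fs2 <- fs + control$learning_rate * alpha * h
      gl <- G + control$learning_rate * alpha * st$out_left
      gr <- G + control$learning_rate * alpha * st$out_right
    } else {
      r <- pseudo_residuals(y, fs)
      fit <- fit_stump_ls(X, r, m)
      if (is.null(fit)) return(leaf())
      st <- fit$stump
      left <- X[, st$feature] <= st$threshold
      cl <- newton_coefficient(r[left], m[left], control$lambda)
      cr <- newton_coefficient(r[!left], m[!left], control$lambda)
      if (abs(cl) < 1e-12 && abs(cr) < 1e-12) return(leaf())
      fs2 <- fs + control$learning_rate * ifelse(left, cl, cr)
      gl <- G + control$learning_rate * cl
      gr <- G + control$learning_rate * cr
    }
    drop0 <- function(v) { v[v < cutoff] <- 0; v }
    ml <- drop0(membership_update(m, st, X, "left", control$gamma))
    mr <- drop0(membership_update(m, st, X, "right", control$gamma))
    list(leaf = FALSE, feature = st$feature, threshold = st$threshold,
         left = rec(ml, fs2, gl, round + 1L),
         right = rec(mr, fs2, gr, round + 1L))
  }
  rec(rep(1, n), numeric(n), 0, 0L)
}

# flatten any tree-shaped structure (package node or helper node) into a
# comparable record of splits and leaf labels/scores
tree_signature <- function(node) {
  if (isTRUE(node$leaf)) {
    return(list(list(kind = "leaf", label = node$label, G = node$G)))
  }
  feature <- if (!is.null(node$stump)) node$stump$feature else node$feature
  threshold <- if (!is.null(node$stump)) node$stump$threshold else node$threshold
  c(list(list(kind = "split", feature = feature, threshold = threshold)),
    tree_signature(node$left), tree_signature(node$right))
}

random_xy <- function(n, d, seed) {
  withr::with_seed(seed, {
    X <- matrix(runif(n * d), n, d)
    y <- sample(c(-1, 1), n, replace = TRUE)
  })
  list(X = X, y = y)
}
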