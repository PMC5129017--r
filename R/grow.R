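#' Stump coefficient from a weighted error
#'
#' The additive-logistic-regression coefficient
#' `alpha = log((1 - e)/e) / 2`, with the error clipped to
#' `[eps_min, 1 - eps_min]` so degenerate (perfect or hopeless) stumps give a
#' finite coefficient.
#'
#' @param error Weighted classification error in `[0, 1]`.
#' @param eps_min Clipping floor (default `1e-6`).
#' @return The coefficient `alpha` (non-positive when `error >= 0.5`).
#' @examples
#' alpha_from_error(0.25)  # log(3)/2
#' @export
alpha_from_error <- function(error, eps_min = 1e-6) {
  e <- pmin(pmax(error, eps_min), 1 - eps_min)
  0.5 * log((1 - e) / e)
}

#' Boosting weights under a membership function
#'
#' The exponential-loss weight of each instance, damped by its degree of
#' belonging to the current node: `w_i` proportional to
#' `m_i * exp(-y_i * F_i)`, normalised to sum to one. Computed on the log
#' scale so that large working scores do not overflow.
#'
#' @param membership Non-negative membership values `m`.
#' @param score Working scores `F` accumulated so far.
#' @param y Labels in `{-1, +1}`.
#' @return Weights summing to one.
#' @examples
#' boost_weights(rep(1, 4), rep(0, 4), c(-1, 1, 1, -1))  # uniform
#' @export
boost_weights <- function(membership, score, y) {
  if (any(membership < 0)) {
    abort("membership must be non-negative.", class = "mediboost_input_error")
  }
  logw <- log(membership) - y * score
  mx <- max(logw)
  if (!is.finite(mx)) {
    abort("total boosting weight underflowed to zero; use a smaller gamma or tree depth.",
          class = "mediboost_numeric_error")
  }
  w <- exp(logw - mx)
  w / sum(w)
}

#' Membership decay along a branch
#'
#' Instances routed by the stump to the branch being grown keep their
#' membership; instances routed the other way are damped by `exp(-gamma)`.
#' With `gamma = 0` membership never changes (pure boosting: all observations
#' contribute to all nodes); as `gamma` grows the recursion approaches hard
#' recursive partitioning.
#'
#' @param membership Current membership values.
#' @param stump A stump as returned by [fit_stump_error()]/[fit_stump_ls()].
#' @param X Training feature matrix.
#' @param branch `"left"` or `"right"`: the branch being descended.
#' @param gamma Acceleration parameter (>= 0).
#' @return Updated membership vector.
#' @export
membership_update <- function(membership, stump, X, branch = c("left", "right"),
                              gamma) {
  branch <- match.arg(branch)
  if (gamma < 0) abort("`gamma` must be >= 0.", class = "mediboost_input_error")
  goes_left <- X[, stump$feature] <= stump$threshold
  on_branch <- if (branch == "left") goes_left else !goes_left
  membership * ifelse(on_branch, 1, exp(-gamma))
}

#' Pseudo-residuals of the binomial log-likelihood
#'
#' The negative gradient of `log(1 + exp(-2 y F))` with respect to the score
#' `F`: `r = 2 y / (1 + exp(2 y F))`, always in `(-2, 2)` and evaluated
#' through `plogis()` so large scores cannot overflow.
#'
#' @param y Labels in `{-1, +1}`.
#' @param score Working scores `F`.
#' @return Residual vector in `(-2, 2)`.
#' @examples
#' pseudo_residuals(c(1, -1), c(0, 0))  # equals y at F = 0
#' @export
pseudo_residuals <- function(y, score) {
  2 * y * stats::plogis(-2 * y * score)
}

#' Newton leaf coefficient with ridge regularisation
#'
#' One Newton-Raphson step for the pooled binomial loss of a stump side:
#' `c = sum(m r) / (sum(m |r| (2 - |r|)) + lambda)`. The denominator is the
#' membership-weighted second derivative of the loss (`|r|(2-|r|) = 4p(1-p)`);
#' `lambda` adds a ridge penalty. A zero denominator (with `lambda = 0`)
#' returns 0.
#'
#' @param residuals Pseudo-residuals of the instances on one side.
#' @param membership Their membership values.
#' @param lambda Ridge penalty (>= 0).
#' @return The coefficient `c` (0 for an empty side).
#' @examples
#' newton_coefficient(1, 1)            # 1
#' newton_coefficient(1, 1, lambda = 1)  # 1/2
#' @export
newton_coefficient <- function(residuals, membership, lambda = 0) {
  if (length(residuals) == 0L) return(0)
  num <- sum(membership * residuals)
  den <- sum(membership * abs(residuals) * (2 - abs(residuals))) + lambda
  if (den <= 0) return(0)
  num / den
}

# ---------------------------------------------------------------------------
# Shared recursive grower.
#
# State carried down the recursion: membership m, working score fs (per
# instance), path constant G, feasible intervals (lo, hi], boosting round
# `round`, and the mask of training instances hard-routed to this node.
#
# Impossible-path elimination: the split search is weight-driven and
# unconstrained; if the chosen threshold falls outside the open feasible
# interval of its feature, one branch would have an empty region, so that
# branch is never created and the stump's contribution on the surviving
# branch is folded into the path constants without recording an internal
# node (a "collapsed" round). Recorded thresholds therefore always lie
# strictly inside their path's feasible intervals, and with gamma = 0 every
# path exactly replays the boosting ensemble.
# ---------------------------------------------------------------------------
grow_tree <- function(X, y, control, algo) {
  n <- nrow(X)
  d <- ncol(X)
  TT <- control$depth
  nu <- control$learning_rate
  gamma <- control$gamma
  tau <- control$min_membership
  ord <- lapply(seq_len(d), function(j) order(X[, j]))

  npos <- sum(y > 0)
  tie_label <- if (npos * 2 >= n) 1 else -1

  acc <- new.env(parent = emptyenv())
  acc$n_leaves <- 0L
  acc$max_depth <- 0L
  acc$fitted_score <- numeric(n)   # working score F at the instance's leaf
  acc$fitted_G <- numeric(n)
  acc$fitted_label <- numeric(n)
  unbounded <- list(lo = rep(-Inf, d), hi = rep(Inf, d))

  make_leaf <- function(G, round, fs, mask) {
    # |G| below the numeric floor counts as a zero path score -> tie label
    label <- if (G > G_ZERO_TOL) 1 else if (G < -G_ZERO_TOL) -1 else tie_label
    acc$n_leaves <- acc$n_leaves + 1L
    acc$max_depth <- max(acc$max_depth, round)
    acc$fitted_score[mask] <- fs[mask]
    acc$fitted_G[mask] <- G
    acc$fitted_label[mask] <- label
    list(leaf = TRUE, label = label, G = G, round = round,
         n_train = sum(mask))
  }

  recurse <- function(m, fs, G, lo, hi, round, mask) {
    if (round >= TT || sum(m) / n < tau) {
      return(make_leaf(G, round, fs, mask))
    }
    active <- m > max(m) * ACTIVE_TOL

    if (algo == "mab") {
      w <- boost_weights(m, fs, y)
      fit <- stump_search_error(X, y, w, ord, active, unbounded$lo, unbounded$hi)
      if (is.null(fit)) return(make_leaf(G, round, fs, mask))
      alpha <- alpha_from_error(fit$error, control$eps_min)
      if (alpha <= 0) return(make_leaf(G, round, fs, mask))
      st <- fit$stump
      h <- ifelse(X[, st$feature] <= st$threshold, st$out_left, st$out_right)
      fs2 <- fs + nu * alpha * h
      contrib_l <- nu * alpha * st$out_left
      contrib_r <- nu * alpha * st$out_right
      coef <- list(alpha = alpha)
    } else {
      r <- pseudo_residuals(y, fs)
      fit <- stump_search_ls(X, r, m, ord, active, unbounded$lo, unbounded$hi)
      if (is.null(fit)) return(make_leaf(G, round, fs, mask))
      st <- fit$stump
      goes_left <- X[, st$feature] <= st$threshold
      c_l <- newton_coefficient(r[goes_left], m[goes_left], control$lambda)
      c_r <- newton_coefficient(r[!goes_left], m[!goes_left], control$lambda)
      if (abs(c_l) < 1e-12 && abs(c_r) < 1e-12) {
        return(make_leaf(G, round, fs, mask))
      }
      fs2 <- fs + nu * ifelse(goes_left, c_l, c_r)
      contrib_l <- nu * c_l
      contrib_r <- nu * c_r
      coef <- list(c_left = c_l, c_right = c_r)
    }

    j <- st$feature
    th <- st$threshold
    if (th <= lo[j]) {
      # left branch infeasible: fold this round into the path and continue
      m2 <- membership_update(m, st, X, "right", gamma)
      return(recurse(m2, fs2, G + contrib_r, lo, hi, round + 1L, mask))
    }
    if (th >= hi[j]) {
      m2 <- membership_update(m, st, X, "left", gamma)
      return(recurse(m2, fs2, G + contrib_l, lo, hi, round + 1L, mask))
    }

    goes_left <- X[, j] <= th
    hi_l <- hi; hi_l[j] <- th
    lo_r <- lo; lo_r[j] <- th
    left <- recurse(membership_update(m, st, X, "left", gamma), fs2,
                    G + contrib_l, lo, hi_l, round + 1L, mask & goes_left)
    right <- recurse(membership_update(m, st, X, "right", gamma), fs2,
                     G + contrib_r, lo_r, hi, round + 1L, mask & !goes_left)
    c(list(leaf = FALSE, stump = st, round = round,
           G_left = G + contrib_l, G_right = G + contrib_r,
           left = left, right = right),
      coef)
  }

  root <- recurse(rep(1, n), numeric(n), 0, rep(-Inf, d), rep(Inf, d), 0L,
                  rep(TRUE, n))
  list(root = root, tie_label = tie_label, n_leaves = acc$n_leaves,
       max_depth_reached = acc$max_depth,
       fitted = tibble::tibble(
         .working_score = acc$fitted_score,
         .pred_score = acc$fitted_G,
         .pred_sign = acc$fitted_label
       ))
}

validate_xy <- function(X, y) {
  X <- as.matrix(X)
  if (!is.numeric(X) || any(!is.finite(X))) {
    abort("`X` must be a numeric matrix with finite entries (preprocess first).",
          class = "mediboost_input_error")
  }
  check_pm1(y, require_both = FALSE)
  if (nrow(X) != length(y)) {
    abort("`X` and `y` have inconsistent sizes.",
          class = "mediboost_input_error")
  }
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  X
}

build_engine <- function(X, y, control, algo) {
  X <- validate_xy(X, y)
  grown <- grow_tree(X, y, control, algo)
  fitted <- grown$fitted
  structure(
    list(root = grown$root, algo = algo, control = control,
         tie_label = grown$tie_label, feature_names = colnames(X),
         n_leaves = grown$n_leaves,
         max_depth_reached = grown$max_depth_reached,
         n_train = nrow(X), fitted = fitted,
         train_balanced_error = if (length(unique(y)) == 2L)
           balanced_error(y, fitted$.pred_sign) else NA_real_,
         pruned = FALSE, preprocess = NULL, label_map = NULL,
         original_features = NULL),
    class = "mediboost"
  )
}

#' Grow a tree with the exponential-loss (AdaBoost-style) engine
#'
#' Low-level matrix interface to the exponential-loss grower. At every node
#' the boosting weights `m * exp(-y F)` are formed, a classification stump is
#' fitted by weighted error, its coefficient `alpha` computed, and both
#' branches are descended with the off-branch membership damped by
#' `exp(-gamma)`. Branch constants accumulate into the path score `G`, whose
#' sign labels each terminal node. With `gamma = 0` the tree's predictions
#' coincide exactly with the underlying stump ensemble.
#'
#' Most users should call [mediboost()], which adds preprocessing and label
#' handling on top of this engine.
#'
#' @param X Numeric feature matrix with finite entries.
#' @param y Labels in `{-1, +1}`, both classes present.
#' @param control A [mediboost_control()] object.
#' @return A `mediboost` model object.
#' @examples
#' d <- sim_four_region(100, flip_noise = 0, seed = 1)
#' fit <- build_mab(as.matrix(d[c("x1", "x2")]), d$y,
#'                  mediboost_control(depth = 3, gamma = 30))
#' leaf_count(fit)
#' @export
build_mab <- function(X, y, control = mediboost_control()) {
  build_engine(X, y, control, "mab")
}

#' Grow a tree with the binomial log-likelihood gradient-boosting engine
#'
#' Low-level matrix interface to the likelihood grower. At every node the
#' pseudo-residuals of the binomial log-likelihood are computed, a regression
#' stump is fitted to them by membership-weighted least squares, and each
#' side receives a ridge-regularised Newton coefficient. Otherwise the
#' recursion (membership decay, path scores, impossible-path elimination)
#' matches [build_mab()].
#'
#' @inheritParams build_mab
#' @return A `mediboost` model object.
#' @examples
#' d <- sim_four_region(100, flip_noise = 0, seed = 1)
#' fit <- build_lmb(as.matrix(d[c("x1", "x2")]), d$y,
#'                  mediboost_control(depth = 3, gamma = 30))
#' leaf_count(fit)
#' @export
build_lmb <- function(X, y, control = mediboost_control()) {
  build_engine(X, y, control, "lmb")
}
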