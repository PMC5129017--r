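#' Hyperparameters for tree growth
#'
#' Bundles the tunable parameters of the boosting-based tree growers and
#' validates their ranges. The two parameters that matter most in practice
#' (and the two that are tuned by [tune_nested()]) are the tree depth and the
#' acceleration parameter.
#'
#' @param depth Maximum number of boosting rounds along any root-to-leaf path
#'   (the depth `T` of the unpruned tree). Non-negative integer; `0` yields a
#'   single-leaf tree predicting the majority class. The default of 15 grows a
#'   deep tree intended to be simplified afterwards by [prune_sign()]; note
#'   that an unpruned tree can hold up to `2^depth` leaves, so large depths
#'   are expensive.
#' @param gamma Acceleration parameter (>= 0) controlling the exponential
#'   decay `exp(-gamma)` applied to the membership of instances routed against
#'   a branch. `gamma = 0` keeps every instance fully in every node, so the
#'   tree is exactly a rewritten boosting ensemble; large `gamma`
#'   (e.g. 30) reproduces hard recursive partitioning.
#' @param learning_rate Shrinkage `nu` in `(0, 1]` applied to every additive
#'   update (default 0.1).
#' @param lambda Ridge penalty (>= 0) added to the Newton denominator of the
#'   likelihood engine's leaf coefficients; default 0 (no regularisation
#'   beyond tree size).
#' @param eps_min Clipping floor for weighted classification errors before the
#'   stump coefficient `alpha = log((1 - e)/e)/2` is formed (default `1e-6`).
#' @param min_membership Growth along a branch stops when the mean membership
#'   `sum(m)/n` falls below this fraction (default `1e-4`); with large
#'   `gamma` this is what terminates branches that no training instance
#'   follows.
#'
#' @return An object of class `mediboost_control` (a validated list).
#' @seealso [mediboost()], [build_mab()], [build_lmb()]
#' @examples
#' mediboost_control(depth = 4, gamma = 2)
#' @export
mediboost_control <- function(depth = 15L, gamma = 2, learning_rate = 0.1,
                              lambda = 0, eps_min = 1e-6,
                              min_membership = 1e-4) {
  depth <- check_scalar(depth, "depth")
  if (depth < 0 || depth != floor(depth)) {
    abort("`depth` must be a non-negative integer.",
          class = "mediboost_input_error")
  }
  gamma <- check_scalar(gamma, "gamma")
  if (gamma < 0) {
    abort("`gamma` must be >= 0.", class = "mediboost_input_error")
  }
  learning_rate <- check_scalar(learning_rate, "learning_rate")
  if (learning_rate <= 0 || learning_rate > 1) {
    abort("`learning_rate` must lie in (0, 1].",
          class = "mediboost_input_error")
  }
  lambda <- check_scalar(lambda, "lambda")
  if (lambda < 0) {
    abort("`lambda` must be >= 0.", class = "mediboost_input_error")
  }
  eps_min <- check_scalar(eps_min, "eps_min")
  if (eps_min <= 0 || eps_min >= 0.5) {
    abort("`eps_min` must lie in (0, 0.5).", class = "mediboost_input_error")
  }
  min_membership <- check_scalar(min_membership, "min_membership")
  if (min_membership < 0 || min_membership >= 1) {
    abort("`min_membership` must lie in [0, 1).",
          class = "mediboost_input_error")
  }
  structure(
    list(depth = as.integer(depth), gamma = gamma,
         learning_rate = learning_rate, lambda = lambda,
         eps_min = eps_min, min_membership = min_membership),
    class = "mediboost_control"
  )
}

check_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(paste0("`", name, "` must be a single finite number."),
          class = "mediboost_input_error")
  }
  as.numeric(x)
}

#' @export
print.mediboost_control <- function(x, ...) {
  cat("<mediboost_control>\n")
  cat(sprintf("  depth = %d, gamma = %g, learning_rate = %g, lambda = %g\n",
              x$depth, x$gamma, x$learning_rate, x$lambda))
  cat(sprintf("  eps_min = %g, min_membership = %g\n",
              x$eps_min, x$min_membership))
  invisible(x)
}
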