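#' Two-dimensional four-region toy data
#'
#' Points uniform on the unit square, labelled by a fixed depth-2
#' axis-aligned tree — three decision nodes partitioning the square into four
#' subregions with alternating labels — and then flipped independently with
#' probability `flip_noise`. The generating tree splits `x1` at 0.5, then
#' `x2` at 0.3 (left) and 0.7 (right): left of 0.5 the positive region is
#' `x2 <= 0.3`, right of 0.5 it is `x2 > 0.7`, so neither marginal alone
#' separates the classes and a depth-2 tree reproduces the Bayes rule
#' exactly.
#'
#' @param n Number of points.
#' @param flip_noise Label-flip probability in `[0, 0.5)`.
#' @param seed Integer seed; the generator is a pure function of
#'   `(n, flip_noise, seed)`.
#' @return A tibble with columns `x1`, `x2` and `y` (-1/+1). The noiseless
#'   labels are attached as attribute `"true_label"`.
#' @examples
#' d <- sim_four_region(500, flip_noise = 0.1, seed = 1)
#' table(d$y)
#' @export
sim_four_region <- function(n, flip_noise = 0.1, seed = 1L) {
  if (flip_noise < 0 || flip_noise >= 0.5) {
    abort("`flip_noise` must lie in [0, 0.5).",
          class = "mediboost_input_error")
  }
  withr::with_seed(seed, {
    x1 <- stats::runif(n)
    x2 <- stats::runif(n)
    base <- ifelse(x1 <= 0.5,
                   ifelse(x2 <= 0.3, 1, -1),
                   ifelse(x2 <= 0.7, -1, 1))
    flip <- stats::runif(n) < flip_noise
    y <- base * ifelse(flip, -1, 1)
  })
  out <- tibble::tibble(x1 = x1, x2 = x2, y = y)
  attr(out, "true_label") <- base
  out
}

#' Additive-logistic data where stump ensembles are the correct model
#'
#' Features uniform on `[0, 1]^d`; the log-odds of the positive class are an
#' additive combination of step functions,
#' `P(y = +1 | x) = plogis(sum_j beta_j * sign(x_j - t_j))`, so the Bayes
#' rule is itself an additive ensemble of decision stumps. The exact Bayes
#' error (enumerated over the `2^d` sign patterns) is attached as attribute
#' `"bayes_error"`.
#'
#' The default coefficients `beta_j = 2 * 0.75^(j-1)` give a handful of
#' informative features of decreasing strength at thresholds of 0.5, a
#' regime in which a few boosting rounds capture most of the signal. With
#' `beta = 0` the labels are pure noise, which is the null configuration
#' used to calibrate the permutation test.
#'
#' @param n Number of points.
#' @param d Number of features.
#' @param beta Coefficient vector of length `d` (recycled if scalar).
#' @param thresholds Step locations `t_j` in `(0, 1)` (default all 0.5).
#' @param seed Integer seed.
#' @return A tibble with columns `x1..xd` and `y` (-1/+1), with attributes
#'   `"bayes_error"`, `"beta"` and `"thresholds"`.
#' @examples
#' d <- sim_additive_logistic(1000, d = 5, seed = 2)
#' attr(d, "bayes_error")
#' @export
sim_additive_logistic <- function(n, d = 5L, beta = NULL, thresholds = NULL,
                                  seed = 1L) {
  if (d < 1L) abort("`d` must be >= 1.", class = "mediboost_input_error")
  beta <- beta %||% (2 * 0.75^(seq_len(d) - 1))
  beta <- rep_len(beta, d)
  thresholds <- rep_len(thresholds %||% 0.5, d)
  if (any(thresholds <= 0 | thresholds >= 1)) {
    abort("`thresholds` must lie strictly inside (0, 1).",
          class = "mediboost_input_error")
  }
  withr::with_seed(seed, {
    X <- matrix(stats::runif(n * d), n, d)
    z <- as.vector(sign(sweep(X, 2, thresholds)) %*% beta)
    p <- stats::plogis(z)
    y <- ifelse(stats::runif(n) < p, 1, -1)
  })
  out <- tibble::as_tibble(as.data.frame(X))
  names(out) <- paste0("x", seq_len(d))
  out$y <- y
  attr(out, "bayes_error") <- if (d <= 16L) additive_bayes_error(beta, thresholds) else NA_real_
  attr(out, "beta") <- beta
  attr(out, "thresholds") <- thresholds
  out
}

# exact Bayes error by enumeration over the 2^d sign patterns
additive_bayes_error <- function(beta, thresholds) {
  d <- length(beta)
  err <- 0
  for (k in 0:(2^d - 1)) {
    s <- 2 * as.integer(intToBits(k)[seq_len(d)]) - 1
    prob <- prod(ifelse(s > 0, 1 - thresholds, thresholds))
    p <- stats::plogis(sum(beta * s))
    err <- err + prob * min(p, 1 - p)
  }
  err
}
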