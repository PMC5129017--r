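#' Candidate split thresholds for one feature
#'
#' Candidate thresholds are the midpoints between consecutive distinct
#' observed values, restricted to those lying strictly inside the feasible
#' interval `(lo, hi)` of the current path. A midpoint at or outside the
#' interval cannot separate the feasible region and is dropped; a constant
#' column yields no candidates.
#'
#' @param x Numeric vector of observed feature values.
#' @param lo,hi Feasible interval bounds (may be infinite).
#' @return Sorted numeric vector of thresholds (possibly empty).
#' @examples
#' candidate_thresholds(c(1, 2, 3))            # 1.5 2.5
#' candidate_thresholds(c(1, 2, 3), hi = 1.2)  # none feasible
#' @export
candidate_thresholds <- function(x, lo = -Inf, hi = Inf) {
  ux <- sort(unique(x[!is.na(x)]))
  if (length(ux) < 2L) return(numeric(0))
  mids <- (ux[-1L] + ux[-length(ux)]) / 2
  mids[mids > lo & mids < hi]
}

# Relative weight below which an instance no longer proposes candidate
# thresholds (it still contributes to split scores). Makes the hard-partition
# limit of large acceleration exact.
ACTIVE_TOL <- 1e-9

# Path scores with |G| at or below this floor are treated as exactly zero
# when a leaf is labelled (the tie label applies).
G_ZERO_TOL <- 1e-10

# Relative tolerance inside which competing splits are treated as tied and
# the canonical order (feature asc, threshold asc, negative-left polarity
# first) decides.
TIE_TOL <- 1e-10

region_bounds <- function(region, d) {
  if (is.null(region)) {
    list(lo = rep(-Inf, d), hi = rep(Inf, d))
  } else {
    region <- as.matrix(region)
    if (nrow(region) != d || ncol(region) != 2L) {
      abort("`region` must be a d x 2 matrix of (lo, hi] bounds.",
            class = "mediboost_input_error")
    }
    if (any(region[, 1L] >= region[, 2L])) {
      abort("every feasible interval must satisfy lo < hi.",
            class = "mediboost_input_error")
    }
    list(lo = region[, 1L], hi = region[, 2L])
  }
}

#' Fit a classification stump by weighted 0/1 error
#'
#' Searches all features, feasible midpoint thresholds and both sign
#' polarities for the stump minimising the normalised weighted
#' misclassification error `sum(w * (h(x) != y)) / sum(w)`. The routing rule
#' is fixed throughout the package: `x[feature] <= threshold` goes left.
#' Ties (within a relative tolerance of `1e-10`) are broken towards the lower
#' feature index, then the lower threshold, then `out_left = -1`.
#'
#' Candidate thresholds are generated from instances whose weight exceeds
#' `max(w) * 1e-9`; all instances contribute to the error. Both conventions
#' are shared with [fit_stump_ls()].
#'
#' @param X Numeric matrix (n x d).
#' @param y Labels in `{-1, +1}`.
#' @param w Non-negative instance weights with `sum(w) > 0`.
#' @param region Optional `d x 2` matrix of feasible `(lo, hi]` intervals
#'   restricting the thresholds.
#' @return `NULL` when no feasible split exists; otherwise a list with
#'   `stump` (fields `feature`, `threshold`, `out_left`, `out_right`) and
#'   `error` (the achieved weighted error in `[0, 1]`).
#' @examples
#' X <- matrix(1:4, ncol = 1)
#' fit_stump_error(X, c(-1, -1, 1, 1), rep(1, 4))
#' @export
fit_stump_error <- function(X, y, w, region = NULL) {
  X <- as.matrix(X)
  check_pm1(y, require_both = FALSE)
  if (any(w < 0) || sum(w) <= 0) {
    abort("weights must be non-negative with positive sum.",
          class = "mediboost_input_error")
  }
  b <- region_bounds(region, ncol(X))
  ord <- lapply(seq_len(ncol(X)), function(j) order(X[, j]))
  active <- w > max(w) * ACTIVE_TOL
  stump_search_error(X, y, w, ord, active, b$lo, b$hi)
}

#' Fit a regression stump by membership-weighted least squares
#'
#' Finds the stump minimising `sum(m * (r - c[side])^2)` where `c[side]` is
#' the membership-weighted mean of the working response `r` on each side of
#' the split; equivalently, the split maximising the explained weighted sum
#' of squares, computed in a single sorted pass per feature. This is the weak
#' learner of the likelihood engine, with `r` the pseudo-residuals of the
#' binomial log-likelihood. Candidate generation and tie-breaking follow
#' [fit_stump_error()].
#'
#' @param X Numeric matrix (n x d).
#' @param residuals Numeric working response `r`.
#' @param membership Non-negative weights with positive sum.
#' @inheritParams fit_stump_error
#' @return `NULL` when no feasible split exists; otherwise a list with
#'   `stump` (whose `out_left`/`out_right` are the weighted side means) and
#'   `sse` (the achieved weighted sum of squared errors).
#' @examples
#' X <- matrix(1:4, ncol = 1)
#' fit_stump_ls(X, c(-1, -1, 1, 1), rep(1, 4))
#' @export
fit_stump_ls <- function(X, residuals, membership, region = NULL) {
  X <- as.matrix(X)
  if (any(membership < 0) || sum(membership) <= 0) {
    abort("membership must be non-negative with positive sum.",
          class = "mediboost_input_error")
  }
  b <- region_bounds(region, ncol(X))
  ord <- lapply(seq_len(ncol(X)), function(j) order(X[, j]))
  active <- membership > max(membership) * ACTIVE_TOL
  stump_search_ls(X, residuals, membership, ord, active, b$lo, b$hi)
}

# shared candidate machinery: midpoints of consecutive distinct active values
# inside (lo, hi), plus the index k of the last sorted observation <= each
feature_candidates <- function(xs, act, lo, hi) {
  xa <- xs[act]
  if (length(xa) < 2L) return(NULL)
  du <- xa[!duplicated(xa)]          # xa is sorted, so du is sorted distinct
  if (length(du) < 2L) return(NULL)
  mids <- (du[-1L] + du[-length(du)]) / 2
  keep <- mids > lo & mids < hi
  if (!any(keep)) return(NULL)
  mids <- mids[keep]
  list(mids = mids, k = findInterval(mids, xs))
}

stump_search_error <- function(X, y, w, ord, active, lo, hi) {
  d <- ncol(X)
  n <- nrow(X)
  per <- vector("list", d)
  gmin <- Inf
  for (j in seq_len(d)) {
    oj <- ord[[j]]
    xs <- X[oj, j]
    cand <- feature_candidates(xs, active[oj], lo[j], hi[j])
    if (is.null(cand)) next
    wp <- w[oj] * (y[oj] > 0)
    wn <- w[oj] - wp
    cp <- cumsum(wp)
    cn <- cumsum(wn)
    W <- cp[n] + cn[n]
    k <- cand$k
    errA <- (cp[k] + (cn[n] - cn[k])) / W   # out_left = -1
    errB <- (cp[n] - cp[k] + cn[k]) / W     # out_left = +1
    # interleave so canonical order is threshold asc, polarity -1 first
    errs <- as.vector(rbind(errA, errB))
    per[[j]] <- list(mids = cand$mids, errs = errs)
    gmin <- min(gmin, errs)
  }
  if (!is.finite(gmin)) return(NULL)
  tol <- TIE_TOL * (1 + abs(gmin))
  for (j in seq_len(d)) {
    if (is.null(per[[j]])) next
    hit <- which(per[[j]]$errs <= gmin + tol)
    if (length(hit) == 0L) next
    hit <- hit[1L]
    ki <- (hit + 1L) %/% 2L
    pol <- if (hit %% 2L == 1L) -1 else 1
    return(list(
      stump = list(feature = j, threshold = per[[j]]$mids[ki],
                   out_left = pol, out_right = -pol),
      error = per[[j]]$errs[hit]
    ))
  }
  NULL
}

stump_search_ls <- function(X, r, m, ord, active, lo, hi) {
  d <- ncol(X)
  S <- sum(m * r)
  M <- sum(m)
  base <- sum(m * r * r)
  per <- vector("list", d)
  gmax <- -Inf
  for (j in seq_len(d)) {
    oj <- ord[[j]]
    xs <- X[oj, j]
    cand <- feature_candidates(xs, active[oj], lo[j], hi[j])
    if (is.null(cand)) next
    ca <- cumsum((m * r)[oj])
    cb <- cumsum(m[oj])
    k <- cand$k
    Sl <- ca[k]; Ml <- cb[k]
    gains <- Sl^2 / Ml + (S - Sl)^2 / (M - Ml)
    per[[j]] <- list(mids = cand$mids, gains = gains, Sl = Sl, Ml = Ml)
    gmax <- max(gmax, gains)
  }
  if (!is.finite(gmax)) return(NULL)
  tol <- TIE_TOL * (1 + abs(gmax))
  for (j in seq_len(d)) {
    if (is.null(per[[j]])) next
    hit <- which(per[[j]]$gains >= gmax - tol)
    if (length(hit) == 0L) next
    hit <- hit[1L]
    Sl <- per[[j]]$Sl[hit]; Ml <- per[[j]]$Ml[hit]
    return(list(
      stump = list(feature = j, threshold = per[[j]]$mids[hit],
                   out_left = Sl / Ml, out_right = (S - Sl) / (M - Ml)),
      sse = base - per[[j]]$gains[hit]
    ))
  }
  NULL
}
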