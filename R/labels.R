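#' Encode a two-class label vector as -1/+1
#'
#' All growers work internally with labels in `{-1, +1}`. The positive class
#' is the user-supplied `positive` value, or by default the larger of the two
#' observed values (numerically for numeric labels, alphabetically otherwise).
#'
#' @param labels A vector with exactly two distinct non-missing values
#'   (character, factor, logical or numeric).
#' @param positive Optional value naming the class mapped to `+1`.
#'
#' @return A list with `y` (numeric vector of -1/+1) and `mapping` (list with
#'   elements `positive` and `negative` holding the original values).
#' @examples
#' encode_labels(c("yes", "no", "yes"), positive = "yes")$y
#' encode_labels(c(0, 1, 1, 0))$y   # larger value is positive
#' @export
encode_labels <- function(labels, positive = NULL) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (anyNA(labels)) {
    abort("labels contain missing values.", class = "mediboost_input_error")
  }
  vals <- unique(labels)
  if (length(vals) != 2L) {
    abort(
      paste0("labels must have exactly 2 distinct values; observed ",
             length(vals), ": ",
             paste(utils::head(as.character(vals), 10L), collapse = ", ")),
      class = "mediboost_input_error"
    )
  }
  if (is.null(positive)) {
    positive <- if (is.numeric(vals)) max(vals) else sort(as.character(vals))[2L]
  }
  if (!positive %in% vals) {
    abort(paste0("positive label '", positive,
                 "' not among the observed values: ",
                 paste(as.character(vals), collapse = ", ")),
          class = "mediboost_input_error")
  }
  negative <- vals[vals != positive]
  list(
    y = ifelse(labels == positive, 1, -1),
    mapping = list(positive = positive, negative = negative)
  )
}

#' Map -1/+1 predictions back to original labels
#'
#' Inverse of [encode_labels()]: applies the stored mapping so that
#' `decode_labels(encode_labels(x)$y, encode_labels(x)$mapping)` returns `x`.
#'
#' @param y Numeric vector of -1/+1.
#' @param mapping The `mapping` element returned by [encode_labels()].
#' @return Vector of original label values.
#' @export
decode_labels <- function(y, mapping) {
  if (!all(y %in% c(-1, 1))) {
    abort("`y` must contain only -1 and +1.", class = "mediboost_input_error")
  }
  out <- c(mapping$negative, mapping$positive)[(y + 3) / 2]
  out
}

# validate an internal -1/+1 label vector
check_pm1 <- function(y, require_both = TRUE) {
  if (!is.numeric(y) || !all(y %in% c(-1, 1))) {
    abort("labels must be a numeric vector of -1/+1 (see encode_labels()).",
          class = "mediboost_input_error")
  }
  if (require_both && length(unique(y)) < 2L) {
    abort("both classes must be present.", class = "mediboost_input_error")
  }
  invisible(y)
}
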