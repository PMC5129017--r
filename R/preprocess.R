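#' Impute missing cells and append missingness indicators
#'
#' Prepares a raw feature table for tree growth the way the original
#' evaluation protocol does: continuous columns are imputed with the mean of
#' their observed values, categorical columns with the mode, and one binary
#' indicator column per *original* feature is appended recording which cells
#' were missing. Categorical columns are then expanded to one-hot 0/1 columns
#' so that the stump search only ever deals with numeric thresholds.
#'
#' When `stats` is supplied (the `"preprocess_stats"` attribute of a previous
#' call), the stored means, modes and level sets are applied instead of being
#' re-estimated. Cross-validation harnesses use this to fit the imputation on
#' training folds only. Levels unseen at fit time map to all-zero dummy rows.
#'
#' @param data A data frame of features (no label column). Empty cells must
#'   already be `NA`.
#' @param kinds Optional named character vector overriding the per-column
#'   kind, entries `"continuous"` or `"categorical"`. By default numeric
#'   columns are continuous and everything else categorical.
#' @param stats Optional statistics from a previous call, to apply rather
#'   than estimate.
#'
#' @return A tibble of numeric columns: imputed continuous columns, one-hot
#'   expansions of categorical columns (named `<col>_<level>`), then one
#'   `<col>_missing` 0/1 indicator per original column. The estimation
#'   statistics are attached as attribute `"preprocess_stats"`.
#' @examples
#' df <- data.frame(age = c(1, NA, 3), sex = c("m", "f", NA))
#' impute_and_flag(df)
#' @export
impute_and_flag <- function(data, kinds = NULL, stats = NULL) {
  if (!is.data.frame(data) || ncol(data) == 0L) {
    abort("`data` must be a data frame with at least one column.",
          class = "mediboost_input_error")
  }
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  if (is.null(stats)) {
    stats <- preprocess_fit(data, kinds)
  } else {
    missing_cols <- setdiff(stats$columns, names(data))
    if (length(missing_cols) > 0L) {
      abort(paste0("new data lacks feature column(s): ",
                   paste(missing_cols, collapse = ", ")),
            class = "mediboost_input_error")
    }
    data <- data[stats$columns]
  }
  out <- list()
  for (col in stats$columns) {
    x <- data[[col]]
    if (is.factor(x)) x <- as.character(x)
    if (is.logical(x) && all(is.na(x))) x <- as.numeric(x)  # all-NA column
    miss <- is.na(x)
    if (stats$kinds[[col]] == "continuous") {
      if (!is.numeric(x)) {
        abort(paste0("column '", col, "' is declared continuous but is not numeric."),
              class = "mediboost_input_error")
      }
      x[miss] <- stats$means[[col]]
      out[[col]] <- as.numeric(x)
    } else {
      x <- as.character(x)
      x[miss] <- stats$modes[[col]]
      for (lvl in stats$levels[[col]]) {
        out[[paste0(col, "_", lvl)]] <- as.numeric(x == lvl)
      }
    }
  }
  # one indicator per original column; names are de-duplicated in case a
  # feature literally named "<col>_missing" already exists
  ind <- lapply(stats$columns, function(col) as.numeric(is.na(data[[col]])))
  nms <- make.unique(c(names(out), paste0(stats$columns, "_missing")),
                     sep = "_")
  out <- c(out, ind)
  names(out) <- nms
  res <- tibble::as_tibble(out)
  attr(res, "preprocess_stats") <- stats
  res
}

preprocess_fit <- function(data, kinds = NULL) {
  cols <- names(data)
  kind_of <- vapply(data, function(x) {
    if (is.numeric(x)) "continuous" else "categorical"
  }, character(1))
  if (!is.null(kinds)) {
    bad <- setdiff(names(kinds), cols)
    if (length(bad) > 0L) {
      abort(paste0("`kinds` names unknown column(s): ",
                   paste(bad, collapse = ", ")),
            class = "mediboost_input_error")
    }
    if (!all(kinds %in% c("continuous", "categorical"))) {
      abort("`kinds` entries must be 'continuous' or 'categorical'.",
            class = "mediboost_input_error")
    }
    kind_of[names(kinds)] <- kinds
  }
  means <- list(); modes <- list(); levels <- list()
  for (col in cols) {
    x <- data[[col]]
    if (is.factor(x)) x <- as.character(x)
    obs <- x[!is.na(x)]
    if (length(obs) == 0L) {
      abort(paste0("column '", col, "' has no observed values; cannot impute."),
            class = "mediboost_input_error")
    }
    if (kind_of[[col]] == "continuous") {
      means[[col]] <- mean(obs)
    } else {
      obs <- as.character(obs)
      tab <- table(obs)
      # mode; ties broken towards the alphabetically first level
      modes[[col]] <- sort(names(tab)[tab == max(tab)])[1L]
      levels[[col]] <- sort(unique(obs))
    }
  }
  list(columns = cols, kinds = as.list(kind_of), means = means,
       modes = modes, levels = levels)
}

#' Mask cells completely at random
#'
#' Sets each cell of the selected columns to `NA` independently with
#' probability `rate` (missing completely at random), reproducibly under the
#' given seed. Used to exercise the imputation pipeline on data with known
#' missingness.
#'
#' @param data A data frame.
#' @param rate Probability in `[0, 1)` that any one cell is masked.
#' @param seed Integer seed.
#' @param cols Columns to mask (default all).
#' @return A tibble with the same shape as `data` and masked cells set to `NA`.
#' @examples
#' inject_missingness(data.frame(a = 1:5, b = 6:10), rate = 0.4, seed = 1)
#' @export
inject_missingness <- function(data, rate, seed = 1L, cols = names(data)) {
  if (!is.numeric(rate) || length(rate) != 1L || rate < 0 || rate >= 1) {
    abort("`rate` must be a probability in [0, 1).",
          class = "mediboost_input_error")
  }
  data <- tibble::as_tibble(data)
  bad <- setdiff(cols, names(data))
  if (length(bad) > 0L) {
    abort(paste0("unknown column(s): ", paste(bad, collapse = ", ")),
          class = "mediboost_input_error")
  }
  if (rate == 0) return(data)
  withr::with_seed(seed, {
    for (col in cols) {
      mask <- stats::runif(nrow(data)) < rate
      data[[col]][mask] <- NA
    }
  })
  data
}
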