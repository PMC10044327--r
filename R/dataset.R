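#' Chronological half split of a feature frame
#'
#' First half (floor on the training side for odd lengths) is the training
#' segment, second half the test segment; no shuffling, so overlapping
#' temporal context never leaks across the boundary.
#'
#' @param df Tibble ordered in time.
#' @param split_fraction Fraction assigned to training (default 0.5).
#' @return List with `train` and `test` tibbles.
#' @export
split_half <- function(df, split_fraction = 0.5) {
  n <- nrow(df)
  if (n < 2) abort("Need at least 2 frames to split.")
  if (split_fraction <= 0 || split_fraction >= 1) {
    abort("split_fraction must lie in (0, 1).")
  }
  n_train <- floor(n * split_fraction)
  list(train = df[seq_len(n_train), , drop = FALSE],
       test = df[(n_train + 1):n, , drop = FALSE])
}

#' Standardize feature columns using training statistics
#'
#' Per-channel z-scoring with mean and standard deviation computed on the
#' training segment only, applied to both segments. Target (wrench)
#' columns are left in physical units. A zero-variance channel keeps scale
#' 1 and triggers a warning.
#'
#' @param train,test Tibbles from [split_half()].
#' @param cols Character vector of feature columns to standardize;
#'   defaults to all non-time, non-wrench columns of `train`.
#' @return List with standardized `train`, `test` and a `stats` tibble
#'   (`column`, `mean`, `sd`).
#' @export
standardize <- function(train, test, cols = NULL) {
  if (is.null(cols)) {
    cols <- setdiff(names(train), c("time", wrench_channels()))
  }
  stats_tbl <- tibble::tibble(
    column = cols,
    mean = vapply(train[cols], mean, numeric(1)),
    sd = vapply(train[cols], sd, numeric(1))
  )
  zero_var <- stats_tbl$sd == 0 | !is.finite(stats_tbl$sd)
  if (any(zero_var)) {
    warn(sprintf("Zero-variance channel(s) %s: scale set to 1.",
                 paste(stats_tbl$column[zero_var], collapse = ", ")))
    stats_tbl$sd[zero_var] <- 1
  }
  scale_df <- function(df) {
    for (i in seq_along(cols)) {
      df[[cols[i]]] <- (df[[cols[i]]] - stats_tbl$mean[i]) / stats_tbl$sd[i]
    }
    df
  }
  list(train = scale_df(train), test = scale_df(test), stats = stats_tbl)
}

#' Non-overlapping training windows
#'
#' Splits `n` frames into contiguous non-overlapping windows of
#' `window_length` frames for truncated backpropagation through time; the
#' last partial window is kept. Concatenating the windows reproduces the
#' original frame order exactly.
#'
#' @param n Number of frames.
#' @param window_length Frames per window (>= 1).
#' @return List of integer index vectors.
#' @export
make_windows <- function(n, window_length) {
  if (window_length < 1) abort("window_length must be >= 1.")
  starts <- seq(1L, n, by = as.integer(window_length))
  lapply(starts, function(s) seq.int(s, min(s + window_length - 1L, n)))
}

#' Assemble a model-ready dataset for one input pattern
#'
#' Restricts the feature frame to the pattern's channels, splits it
#' chronologically, and standardizes the inputs with training-half
#' statistics. Targets stay in physical units.
#'
#' @param features Feature tibble from [preprocess_session()] (must
#'   include the wrench target columns).
#' @param pattern_id Input pattern 1--6 (see [input_patterns()]).
#' @param split_fraction Training fraction (default 0.5).
#' @param window_length Frames per truncated-BPTT window (default 128).
#' @return A `grf_dataset`: list with standardized `train` / `test`
#'   tibbles, `input_cols`, `target_cols`, `stats`, `pattern_id`,
#'   `window_length`.
#' @export
build_dataset <- function(features, pattern_id, split_fraction = 0.5,
                          window_length = 128) {
  missing_targets <- setdiff(wrench_channels(), names(features))
  if (length(missing_targets) > 0) {
    abort(sprintf("Feature frame lacks target column(s) %s.",
                  paste(missing_targets, collapse = ", ")))
  }
  restricted <- select_pattern(features, pattern_id)
  input_cols <- pattern_columns(pattern_id)
  halves <- split_half(restricted, split_fraction)
  std <- standardize(halves$train, halves$test, cols = input_cols)
  structure(
    list(train = std$train, test = std$test, stats = std$stats,
         input_cols = input_cols, target_cols = wrench_channels(),
         pattern_id = pattern_id, window_length = window_length),
    class = "grf_dataset"
  )
}

#' @export
print.grf_dataset <- function(x, ...) {
  cat(sprintf(
    "<grf_dataset> pattern %d: d = %d inputs, %d train + %d test frames (window %d)\n",
    x$pattern_id, length(x$input_cols), nrow(x$train), nrow(x$test),
    x$window_length
  ))
  invisible(x)
}
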