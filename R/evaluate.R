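#' Percent RMSE between an estimated and a measured channel
#'
#' Root-mean-square error expressed as a percentage of a reference scale
#' of the measured channel. The default reference is the measured range
#' (max - min) over the evaluation segment, the common normalized-RMSE
#' convention for signals oscillating around a varying baseline;
#' `"peak"` (max absolute value) and `"std"` (standard deviation) are
#' available to match other conventions.
#'
#' @param estimated,measured Numeric vectors of equal length (>= 2).
#' @param normalization `"range"`, `"peak"` or `"std"`.
#' @return Percentage (scalar).
#' @examples
#' percent_rmse(c(0, 0), c(0, 10))  # sqrt(50) / 10 * 100 = 70.71
#' @export
percent_rmse <- function(estimated, measured,
                         normalization = c("range", "peak", "std")) {
  normalization <- match.arg(normalization)
  if (length(estimated) != length(measured)) {
    abort("estimated and measured must have equal length.")
  }
  if (length(measured) < 2) abort("Need at least 2 samples.")
  denom <- switch(normalization,
    range = diff(range(measured)),
    peak = max(abs(measured)),
    std = sd(measured)
  )
  if (!is.finite(denom) || denom == 0) {
    abort("Measured channel is constant: percent RMSE normalization undefined.")
  }
  100 * sqrt(mean((estimated - measured)^2)) / denom
}

#' Aggregate three per-axis percentages into mean and standard error
#'
#' The mean +/- SE aggregation used for a force (Fx, Fy, Fz) or moment
#' (Mx, My, Mz) group: arithmetic mean and sample (n - 1) standard
#' deviation divided by sqrt(3).
#'
#' @param values Numeric vector of exactly three per-axis percentages.
#' @return Named numeric vector `c(mean = , se = )` at full precision.
#' @examples
#' aggregate_group(c(8.00, 10.0, 6.67))  # 8.22 +/- 0.97
#' @export
aggregate_group <- function(values) {
  if (length(values) != 3) {
    abort("A force or moment group has exactly three axis values.")
  }
  c(mean = mean(values), se = sd(values) / sqrt(3))
}

#' Accuracy from a mean percent RMSE
#'
#' @param grf_mean_pct Mean percent RMSE over the three force axes, in
#'   \[0, 100\].
#' @return `100 - grf_mean_pct`.
#' @examples
#' accuracy_from_rmse(7.83)  # 92.17
#' @export
accuracy_from_rmse <- function(grf_mean_pct) {
  if (any(grf_mean_pct < 0 | grf_mean_pct > 100)) {
    abort("Mean percent RMSE must lie in [0, 100].")
  }
  100 - grf_mean_pct
}

#' Evaluate an estimated wrench against the measured wrench
#'
#' Computes the six per-axis percent RMSE values, the force and moment
#' group means with standard errors, and the accuracy (100 minus the
#' force-group mean).
#'
#' @param estimated,measured Tibbles with the six wrench columns
#'   (`Fx` .. `Mz`), equal length.
#' @param pattern_id Optional input pattern id carried into the report.
#' @param motion_type Optional motion label (`"pcm"` / `"sm"`).
#' @param normalization Passed to [percent_rmse()].
#' @return A `grf_eval` object.
#' @export
evaluate_wrench <- function(estimated, measured, pattern_id = NA_integer_,
                            motion_type = NA_character_,
                            normalization = "range") {
  axes <- wrench_channels()
  missing <- setdiff(axes, intersect(names(estimated), names(measured)))
  if (length(missing) > 0) {
    abort(sprintf("Wrench column(s) %s missing.",
                  paste(missing, collapse = ", ")))
  }
  if (nrow(estimated) != nrow(measured)) {
    abort("Estimated and measured wrench must have equal length.")
  }
  per_axis <- vapply(axes, function(ch) {
    percent_rmse(estimated[[ch]], measured[[ch]],
                 normalization = normalization)
  }, numeric(1))
  grf <- aggregate_group(per_axis[c("Fx", "Fy", "Fz")])
  grm <- aggregate_group(per_axis[c("Mx", "My", "Mz")])
  structure(
    list(
      per_axis_pct_rmse = per_axis,
      grf_mean = unname(grf["mean"]), grf_se = unname(grf["se"]),
      grm_mean = unname(grm["mean"]), grm_se = unname(grm["se"]),
      accuracy_pct = accuracy_from_rmse(unname(grf["mean"])),
      pattern_id = pattern_id, motion_type = motion_type,
      normalization = normalization, n = nrow(measured)
    ),
    class = "grf_eval"
  )
}

#' @export
print.grf_eval <- function(x, ...) {
  cat(sprintf(
    "<grf_eval> pattern %s (%s): GRF %.2f%% +/- %.2f%% | GRM %.2f%% +/- %.2f%% | accuracy %.2f%%\n",
    x$pattern_id, x$motion_type, x$grf_mean, x$grf_se, x$grm_mean,
    x$grm_se, x$accuracy_pct
  ))
  print(round(x$per_axis_pct_rmse, 2))
  invisible(x)
}

#' @describeIn evaluate_wrench Per-axis percent RMSE as a tibble.
#' @param x A `grf_eval`.
#' @param ... Unused.
#' @export
tidy.grf_eval <- function(x, ...) {
  tibble::tibble(
    axis = names(x$per_axis_pct_rmse),
    group = rep(c("GRF", "GRM"), each = 3),
    pct_rmse = unname(x$per_axis_pct_rmse),
    pattern_id = x$pattern_id,
    motion_type = x$motion_type
  )
}

#' @describeIn evaluate_wrench One-row summary (group means, SEs,
#'   accuracy).
#' @export
glance.grf_eval <- function(x, ...) {
  tibble::tibble(
    pattern_id = x$pattern_id, motion_type = x$motion_type,
    grf_mean = x$grf_mean, grf_se = x$grf_se,
    grm_mean = x$grm_mean, grm_se = x$grm_se,
    accuracy_pct = x$accuracy_pct, n = x$n
  )
}

#' Compare two evaluation reports
#'
#' Signed differences (`a - b`) of the group means and of each axis, used
#' for inter-pattern comparisons such as the Mx gap between IMU-only and
#' EMG + IMU configurations.
#'
#' @param a,b `grf_eval` reports from the same motion type.
#' @return Tibble with `quantity` and `delta` columns.
#' @export
compare_patterns <- function(a, b) {
  stopifnot(inherits(a, "grf_eval"), inherits(b, "grf_eval"))
  if (!is.na(a$motion_type) && !is.na(b$motion_type) &&
        a$motion_type != b$motion_type) {
    abort("Cannot compare reports from different motion types.")
  }
  tibble::tibble(
    quantity = c("grf_mean", "grm_mean", names(a$per_axis_pct_rmse)),
    delta = c(a$grf_mean - b$grf_mean, a$grm_mean - b$grm_mean,
              unname(a$per_axis_pct_rmse - b$per_axis_pct_rmse))
  )
}

signif3 <- function(x) signif(x, 3)

#' Render a results table for a set of pattern reports
#'
#' Mirrors the row/column layout of the study's result tables: one row
#' per input pattern, per-axis percent RMSE for forces and moments, and
#' the group "Average +/- SE" columns. Per-axis cells are rounded to 3
#' significant figures and group averages to 2 decimals for display
#' (full precision is retained in the underlying reports).
#'
#' @param reports List of `grf_eval` objects (typically patterns 1--6 in
#'   order).
#' @param file Optional path; when given the numeric table is also
#'   written as CSV.
#' @return A tibble with one row per report; the formatted text table is
#'   attached as attribute `"text"` and printed by `cat(attr(x, "text"))`.
#' @export
render_table <- function(reports, file = NULL) {
  rows <- purrr::map_dfr(reports, function(r) {
    pa <- r$per_axis_pct_rmse
    tibble::tibble(
      pattern_id = r$pattern_id,
      Fx = signif3(pa[["Fx"]]), Fy = signif3(pa[["Fy"]]),
      Fz = signif3(pa[["Fz"]]),
      grf_mean = round(r$grf_mean, 2), grf_se = round(r$grf_se, 2),
      Mx = signif3(pa[["Mx"]]), My = signif3(pa[["My"]]),
      Mz = signif3(pa[["Mz"]]),
      grm_mean = round(r$grm_mean, 2), grm_se = round(r$grm_se, 2)
    )
  })
  fmt_row <- function(r) {
    sprintf(
      "%-7s %-7.4g %-7.4g %-7.4g %-16s %-7.4g %-7.4g %-7.4g %-16s",
      r$pattern_id, r$Fx, r$Fy, r$Fz,
      sprintf("%.4g%% ± %.4g%%", r$grf_mean, r$grf_se),
      r$Mx, r$My, r$Mz,
      sprintf("%.4g%% ± %.4g%%", r$grm_mean, r$grm_se)
    )
  }
  header <- sprintf(
    "%-7s %-7s %-7s %-7s %-16s %-7s %-7s %-7s %-16s",
    "Input", "Fx [N]", "Fy [N]", "Fz [N]", "Average ± SE [N]",
    "Mx [Nm]", "My [Nm]", "Mz [Nm]", "Average ± SE [Nm]"
  )
  text <- paste(c(header, vapply(seq_len(nrow(rows)), function(i) {
    fmt_row(rows[i, ])
  }, character(1))), collapse = "\n")
  if (!is.null(file)) readr::write_csv(rows, file)
  attr(rows, "text") <- paste0(text, "\n")
  rows
}
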