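# Published per-axis %RMSE cells and their printed "Average +/- SE"
# columns for the two motion conditions, kept as printed strings so each
# check can use the precision of the printed value.
printed_results <- function() {
  pcm <- tibble::tribble(
    ~pattern, ~Fx, ~Fy, ~Fz, ~grf_mean, ~grf_se, ~Mx, ~My, ~Mz, ~grm_mean, ~grm_se,
    1L, "11.2", "11.3", "7.33", "9.94", "1.31", "13.2", "16.3", "11.3", "13.6", "1.46",
    2L, "7.83", "9.00", "6.67", "7.83", "0.67", "9.50", "7.33", "9.83", "8.89", "0.78",
    3L, "7.67", "9.17", "6.83", "7.89", "0.68", "7.83", "7.17", "9.33", "8.11", "0.64",
    4L, "11.0", "11.8", "7.33", "10.04", "1.38", "13.5", "18.2", "11.3", "14.33", "2.03",
    5L, "8.17", "11.3", "6.67", "8.71", "1.36", "16.8", "7.83", "10.0", "11.54", "2.70",
    6L, "8.00", "10.0", "6.67", "8.22", "0.97", "10.7", "7.67", "9.67", "9.35", "0.89"
  )
  sm <- tibble::tribble(
    ~pattern, ~Fx, ~Fy, ~Fz, ~grf_mean, ~grf_se, ~Mx, ~My, ~Mz, ~grm_mean, ~grm_se,
    1L, "11.0", "11.5", "16.5", "13", "1.76", "12.8", "14.7", "10.3", "12.6", "1.27",
    2L, "7.3", "11.3", "15.7", "11.43", "2.43", "12.0", "8.83", "9.33", "10.05", "1.20",
    3L, "7.17", "9.17", "15.2", "10.51", "2.41", "11.0", "8.83", "8.83", "9.55", "0.72",
    4L, "11.0", "11.7", "17.0", "13.23", "1.89", "13.3", "15.0", "10.3", "12.87", "1.37",
    5L, "8.50", "11.3", "16.0", "11.93", "2.19", "16.0", "10.3", "10.0", "12.1", "1.95",
    6L, "8.00", "10.2", "15.3", "11.17", "2.16", "12.3", "10.2", "9.50", "10.67", "1.05"
  )
  list(pcm = pcm, sm = sm)
}

# Two printed SM moment-group SE cells are inconsistent with their own
# printed per-axis values under the convention that reproduces the other
# 22 cells exactly (sample sd over the three axes / sqrt(3)); they are
# treated as typos in the published table and checked separately.
printed_se_discrepancies <- function() {
  tibble::tibble(
    motion = c("sm", "sm"),
    pattern = c(2L, 6L),
    group = c("grm", "grm"),
    printed = c("1.20", "1.05"),
    consistent_value = c(sd(c(12.0, 8.83, 9.33)) / sqrt(3),
                         sd(c(12.3, 10.2, 9.50)) / sqrt(3))
  )
}

# half a unit in the last printed decimal place
printed_tol <- function(s) {
  dec <- if (grepl("\\.", s)) nchar(sub("^[^.]*\\.", "", s)) else 0
  0.5 * 10^(-dec)
}

expect_matches_printed <- function(value, printed_string) {
  expect_lte(abs(value - as.numeric(printed_string)),
             printed_tol(printed_string) + 1e-12)
}
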