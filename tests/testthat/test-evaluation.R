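test_that("percent RMSE matches hand-computed values and its invariances", {
  expect_equal(percent_rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  # est = (0,0), meas = (0,10): RMSE sqrt(50), range 10 -> 70.71%
  expect_equal(percent_rmse(c(0, 0), c(0, 10)), 100 * sqrt(50) / 10,
               tolerance = 1e-12)
  withr::with_seed(1, {
    est <- rnorm(200)
    meas <- rnorm(200)
  })
  r0 <- percent_rmse(est, meas)
  expect_equal(percent_rmse(3 * est, 3 * meas), r0, tolerance = 1e-12)
  expect_equal(percent_rmse(est + 11, meas + 11), r0, tolerance = 1e-12)
  expect_error(percent_rmse(c(1, 2), c(5, 5)), "constant")
  expect_error(percent_rmse(1:3, 1:4), "equal length")
  # alternative normalizations are exposed
  expect_equal(percent_rmse(est, meas, "std"),
               100 * sqrt(mean((est - meas)^2)) / sd(meas))
})

test_that("group aggregation reproduces printed mean and standard error cells", {
  # the (n-1) standard deviation over the three axes divided by sqrt(3)
  g <- aggregate_group(c(11.2, 11.3, 7.33))
  expect_matches_printed(g[["mean"]], "9.94")
  expect_matches_printed(g[["se"]], "1.31")
  g2 <- aggregate_group(c(8.00, 10.0, 6.67))
  expect_matches_printed(g2[["mean"]], "8.22")
  expect_matches_printed(g2[["se"]], "0.97")
  expect_equal(aggregate_group(c(5, 5, 5)), c(mean = 5, se = 0))
  expect_error(aggregate_group(c(1, 2)), "three")
})

test_that("accuracy is the complement of the force-group mean RMSE", {
  expect_equal(accuracy_from_rmse(7.83), 92.17)
  expect_equal(accuracy_from_rmse(13.23), 86.77)
  expect_equal(accuracy_from_rmse(0), 100)
  expect_error(accuracy_from_rmse(101), "0, 100")
})

test_that("evaluate_wrench assembles a coherent report", {
  withr::with_seed(2, {
    meas <- tibble::as_tibble(stats::setNames(
      lapply(1:6, function(i) sin(seq(0, 20, by = 0.05) + i) * 10 * i),
      wrench_channels()
    ))
    est <- meas + 0.5
  })
  r <- evaluate_wrench(est, meas, pattern_id = 3, motion_type = "pcm")
  expect_s3_class(r, "grf_eval")
  expect_true(all(r$per_axis_pct_rmse >= 0))
  expect_equal(r$accuracy_pct, 100 - r$grf_mean, tolerance = 1e-9)
  expect_equal(unname(aggregate_group(r$per_axis_pct_rmse[4:6])["se"]),
               r$grm_se)
  td <- tidy(r)
  expect_equal(nrow(td), 6)
  expect_equal(td$group, rep(c("GRF", "GRM"), each = 3))
  gl <- glance(r)
  expect_equal(gl$pattern_id, 3)
})

test_that("pattern comparison is signed, antisymmetric and guarded", {
  mk <- function(vals, motion = "pcm", id = 1L) {
    structure(list(
      per_axis_pct_rmse = stats::setNames(vals, wrench_channels()),
      grf_mean = mean(vals[1:3]), grf_se = sd(vals[1:3]) / sqrt(3),
      grm_mean = mean(vals[4:6]), grm_se = sd(vals[4:6]) / sqrt(3),
      accuracy_pct = 100 - mean(vals[1:3]), pattern_id = id,
      motion_type = motion, normalization = "range", n = 100L
    ), class = "grf_eval")
  }
  a <- mk(c(11.2, 11.3, 7.33, 13.2, 16.3, 11.3), id = 1L)
  b <- mk(c(7.83, 9.00, 6.67, 9.50, 7.33, 9.83), id = 2L)
  d <- compare_patterns(a, b)
  expect_matches_printed(d$delta[d$quantity == "grf_mean"], "2.11")
  d_ba <- compare_patterns(b, a)
  expect_equal(d$delta, -d_ba$delta)
  expect_equal(compare_patterns(a, a)$delta, rep(0, 8))
  # the published Mx gap between shank-IMU-only and EMG+IMU patterns
  p5 <- mk(c(8.17, 11.3, 6.67, 16.8, 7.83, 10.0), id = 5L)
  p6 <- mk(c(8.00, 10.0, 6.67, 10.7, 7.67, 9.67), id = 6L)
  expect_matches_printed(
    compare_patterns(p5, p6)$delta[d$quantity == "Mx"], "6.1"
  )
  sm <- mk(c(1, 1, 1, 1, 1, 1), motion = "sm")
  expect_error(compare_patterns(a, sm), "motion")
})

test_that("rendered tables mirror the published layout and round-trip", {
  tabs <- printed_results()$pcm
  reports <- lapply(seq_len(nrow(tabs)), function(i) {
    vals <- as.numeric(unlist(tabs[i, c("Fx", "Fy", "Fz", "Mx", "My", "Mz")]))
    structure(list(
      per_axis_pct_rmse = stats::setNames(vals, wrench_channels()),
      grf_mean = mean(vals[1:3]), grf_se = sd(vals[1:3]) / sqrt(3),
      grm_mean = mean(vals[4:6]), grm_se = sd(vals[4:6]) / sqrt(3),
      accuracy_pct = 100 - mean(vals[1:3]), pattern_id = tabs$pattern[i],
      motion_type = "pcm", normalization = "range", n = 100L
    ), class = "grf_eval")
  })
  f <- withr::local_tempfile(fileext = ".csv")
  tab <- render_table(reports, file = f)
  expect_equal(nrow(tab), 6)
  expect_equal(tab$pattern_id, 1:6)
  # the averages column reproduces the printed values
  for (i in 1:6) {
    expect_matches_printed(tab$grf_mean[i], tabs$grf_mean[i])
  }
  back <- readr::read_csv(f, show_col_types = FALSE)
  expect_equal(as.data.frame(back), as.data.frame(tab),
               ignore_attr = TRUE)
  expect_match(attr(tab, "text"), "Average")
})
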