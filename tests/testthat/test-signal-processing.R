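test_that("filter designs meet their frequency-domain contract", {
  lp <- design_filter("lowpass", 3, fs = 148.148)
  expect_s3_class(lp, "grf_filter")
  expect_equal(lp$order, 4)
  # DC gain exactly 1
  expect_lt(abs(sum(lp$b) / sum(lp$a) - 1), 1e-9)

  bp <- design_filter("bandpass", c(20, 450), fs = 1111.11)
  resp <- filter_response(bp, c(1e-3, 100, 555), zero_phase = FALSE)
  expect_lt(resp$gain_db[1], -40)           # DC
  expect_lt(resp$gain_db[3], -40)           # near Nyquist
  expect_lt(abs(resp$gain[2] - 1), 0.05)    # passband

  expect_error(design_filter("lowpass", 80, fs = 148.148), "Nyquist")
  expect_error(design_filter("bandpass", c(450, 20), fs = 1111.11),
               "increasing")
})

test_that("EMG band-pass removes sub-20 Hz artifact and preserves the passband", {
  fs <- 1111.11
  t <- (0:(10 * fs)) / fs
  emg5 <- tibble::tibble(time = t, ch = sin(2 * pi * 5 * t))
  emg100 <- tibble::tibble(time = t, ch = sin(2 * pi * 100 * t))
  y5 <- bandpass_emg(emg5, fs = fs)$ch
  y100 <- bandpass_emg(emg100, fs = fs)$ch
  rms <- function(x) sqrt(mean(x^2))
  expect_lt(rms(y5) / rms(emg5$ch), 0.03)
  expect_lt(abs(rms(y100) / rms(emg100$ch) - 1), 0.05)
  # zero input -> zero output
  z <- tibble::tibble(time = t, ch = rep(0, length(t)))
  expect_equal(max(abs(bandpass_emg(z, fs = fs)$ch)), 0)
})

test_that("linear envelope tracks an amplitude modulator and rejects the carrier", {
  fs <- 1111.11
  t <- (0:(20 * fs)) / fs
  modu <- 1 + 0.8 * sin(2 * pi * 0.5 * t)
  withr::with_seed(5, carrier <- rnorm(length(t)))
  bp <- design_filter("bandpass", c(20, 450), fs = fs)
  carrier <- apply_filter(carrier, bp)
  carrier <- carrier / sd(carrier)
  raw <- tibble::tibble(time = t, ch = modu * carrier)
  env <- envelope(bandpass_emg(raw, fs = fs), fs = fs)$ch
  keep <- t > 1 & t < max(t) - 1
  expect_gt(cor(env[keep], modu[keep]), 0.95)
  # constant-amplitude carrier -> envelope settles near a constant.
  # A 3 Hz smoother on a 430 Hz-wide rectified carrier leaves ~6%
  # residual fluctuation, so "near-constant" means CV below 8%.
  raw2 <- tibble::tibble(time = t, ch = carrier)
  env2 <- envelope(bandpass_emg(raw2, fs = fs), fs = fs)$ch
  expect_lt(sd(env2[keep]) / mean(env2[keep]), 0.08)
  expect_true(all(env2[keep] > 0))
})

test_that("3 Hz low-pass preserves DC and sway, attenuates 30 Hz", {
  fs <- 148.148
  t <- (0:(30 * fs)) / fs
  dc <- tibble::tibble(time = t, ch = rep(4.2, length(t)))
  expect_lt(max(abs(lowpass_aux(dc, fs = fs)$ch - 4.2)) / 4.2, 1e-6)
  sway <- tibble::tibble(time = t, ch = sin(2 * pi * 0.25 * t))
  ys <- lowpass_aux(sway, fs = fs)$ch
  keep <- t > 4 & t < max(t) - 4
  expect_lt(abs(max(abs(ys[keep])) - 1), 0.02)
  hi <- tibble::tibble(time = t, ch = sin(2 * pi * 30 * t))
  yh <- lowpass_aux(hi, fs = fs)$ch
  atten_db <- 20 * log10(sqrt(mean(yh[keep]^2)) / sqrt(0.5))
  expect_lt(atten_db, -40)
})

test_that("filter chain is linear before rectification", {
  fs <- 1111.11
  withr::with_seed(3, x <- rnorm(5000))
  df1 <- tibble::tibble(time = seq_along(x) / fs, ch = x)
  df3 <- tibble::tibble(time = seq_along(x) / fs, ch = 3 * x)
  expect_equal(bandpass_emg(df3, fs = fs)$ch,
               3 * bandpass_emg(df1, fs = fs)$ch, tolerance = 1e-10)
})

test_that("decimation lands exactly on the 74.074 Hz timebase", {
  fs <- 1111.11
  n <- round(120 * fs)
  t <- (0:(n - 1)) / fs
  df <- tibble::tibble(time = t, ch = sin(2 * pi * 0.5 * t))
  out <- decimate_stream(df, fs = fs)
  expect_lt(abs(nrow(out) - floor(120 * 74.074)), 2)
  # decimated samples match the analytic signal at the output times
  expect_lt(max(abs(out$ch - sin(2 * pi * 0.5 * out$time))), 1e-3)
  # constant input -> identical constant output
  dfc <- tibble::tibble(time = t, ch = rep(7, n))
  expect_equal(unique(decimate_stream(dfc, fs = fs)$ch), 7)
  # non-integer factor rejected
  expect_error(decimate_stream(df, fs = 1000), "Non-integer")
})

test_that("downsampling after the 3 Hz low-pass leaves no power above 3 Hz", {
  withr::with_seed(8, x <- rnorm(30 * 148, sd = 1))
  fs <- 148.148
  df <- tibble::tibble(time = seq_along(x) / fs, ch = x)
  out <- decimate_stream(lowpass_aux(df, fs = fs), fs = fs)
  frac_above <- 1 - band_power_fraction(out$ch, 74.074, 0, 3.5)
  expect_lt(frac_above, 0.01)
})
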