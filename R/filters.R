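#' Design a Butterworth filter for the processing chain
#'
#' Builds the filter coefficients used throughout the pipeline: a 4th-order
#' band-pass with a 20--450 Hz pass band for raw EMG, and a 4th-order
#' low-pass with a 3 Hz cutoff for envelopes, IMU and wrench streams.
#'
#' @param kind `"bandpass"` or `"lowpass"`.
#' @param cutoffs_hz One cutoff (lowpass) or two strictly increasing cutoffs
#'   (bandpass), in Hz. Must lie below the Nyquist frequency `fs / 2`.
#' @param fs Sampling rate of the stream the filter will be applied to (Hz).
#' @param order Filter order parameter (default 4, the design used for both
#'   stages of the chain).
#'
#' @return An object of class `grf_filter`: a list with `b`, `a` coefficient
#'   vectors and the design metadata.
#' @examples
#' lp <- design_filter("lowpass", 3, fs = 148.148)
#' bp <- design_filter("bandpass", c(20, 450), fs = 1111.11)
#' @export
design_filter <- function(kind = c("bandpass", "lowpass"), cutoffs_hz, fs,
                          order = 4) {
  kind <- match.arg(kind)
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) {
    abort("`fs` must be a single positive sampling rate in Hz.")
  }
  nyq <- fs / 2
  if (any(cutoffs_hz <= 0) || any(cutoffs_hz >= nyq)) {
    abort(sprintf(
      "Filter cutoffs must lie strictly between 0 and the Nyquist frequency (%.3f Hz).",
      nyq
    ))
  }
  if (kind == "bandpass") {
    if (length(cutoffs_hz) != 2 || diff(cutoffs_hz) <= 0) {
      abort("A bandpass design needs two strictly increasing cutoffs.")
    }
    flt <- signal::butter(order, cutoffs_hz / nyq, type = "pass")
  } else {
    if (length(cutoffs_hz) != 1) {
      abort("A lowpass design needs exactly one cutoff.")
    }
    flt <- signal::butter(order, cutoffs_hz / nyq, type = "low")
  }
  structure(
    list(b = as.numeric(flt$b), a = as.numeric(flt$a),
         kind = kind, cutoffs_hz = cutoffs_hz, fs = fs, order = order),
    class = "grf_filter"
  )
}

#' Frequency response magnitude of a designed filter
#'
#' @param filter A `grf_filter` from [design_filter()].
#' @param freqs_hz Frequencies at which to evaluate the magnitude response.
#' @param zero_phase If `TRUE` (default) return the forward-backward
#'   (squared-magnitude) response, matching how filters are applied offline.
#' @return A tibble with `freq_hz`, `gain` and `gain_db`.
#' @export
filter_response <- function(filter, freqs_hz, zero_phase = TRUE) {
  stopifnot(inherits(filter, "grf_filter"))
  z <- exp(1i * 2 * pi * freqs_hz / filter$fs)
  h <- vapply(z, function(zz) {
    abs(sum(filter$b * zz^-(seq_along(filter$b) - 1)) /
          sum(filter$a * zz^-(seq_along(filter$a) - 1)))
  }, numeric(1))
  if (zero_phase) h <- h^2
  tibble::tibble(freq_hz = freqs_hz, gain = h, gain_db = 20 * log10(h))
}

# Linear filter with direct-form-I state seeded at the constant-input
# equilibrium for x0, so a DC input passes through with no start-up
# transient.
lfilter_ss <- function(b, a, x, x0) {
  g <- sum(b) / sum(a)
  as.numeric(signal::filter(
    b, a, x,
    init.x = rep(x0, length(b) - 1),
    init = rep(g * x0, length(a) - 1)
  ))
}

#' Apply a filter to a numeric vector
#'
#' Default is zero-phase (forward-backward) application with odd reflective
#' padding of three filter lengths at both ends and equilibrium initial
#' conditions, so offline processing introduces no phase lag -- important
#' because EMG-to-force timing carries the predictive information. A causal
#' single-pass mode is available for streaming-style use.
#'
#' @param x Numeric vector (one channel).
#' @param filter A `grf_filter`.
#' @param zero_phase Apply forward and backward (default `TRUE`).
#' @return Filtered numeric vector, same length as `x`.
#' @export
apply_filter <- function(x, filter, zero_phase = TRUE) {
  stopifnot(inherits(filter, "grf_filter"))
  b <- filter$b
  a <- filter$a
  if (!zero_phase) {
    return(lfilter_ss(b, a, x, x[1]))
  }
  n <- length(x)
  p <- 3L * max(length(a), length(b))
  if (n <= p + 1) {
    abort(sprintf("Signal too short to filter: %d samples, need > %d.", n, p + 1))
  }
  ext <- c(2 * x[1] - rev(x[2:(p + 1)]), x, 2 * x[n] - rev(x[(n - p):(n - 1)]))
  y <- lfilter_ss(b, a, ext, ext[1])
  y <- rev(lfilter_ss(b, a, rev(y), y[length(y)]))
  y[(p + 1):(p + n)]
}

# Apply a filter to every non-time column of a wide tibble.
filter_frame <- function(df, filter, zero_phase = TRUE) {
  chans <- setdiff(names(df), "time")
  df[chans] <- lapply(df[chans], apply_filter, filter = filter,
                      zero_phase = zero_phase)
  df
}

#' Band-pass filter raw EMG
#'
#' Removes sub-20 Hz motion artifact and baseline drift plus components
#' above 450 Hz (no muscle-contraction content) with the 4th-order
#' Butterworth band-pass, applied per channel.
#'
#' @param emg Tibble with a `time` column and one column per EMG channel,
#'   sampled at `fs`.
#' @param fs EMG sampling rate in Hz (default 1111.11).
#' @param zero_phase Forward-backward filtering (default).
#' @return Tibble of the same shape, filtered.
#' @export
bandpass_emg <- function(emg, fs = FS_EMG, zero_phase = TRUE) {
  bp <- design_filter("bandpass", c(20, 450), fs = fs)
  filter_frame(emg, bp, zero_phase = zero_phase)
}

#' Linear envelope of band-passed EMG
#'
#' Full-wave rectification followed by the 3 Hz 4th-order Butterworth
#' low-pass: the standard linear-envelope construction, yielding a slowly
#' varying proxy for muscle activation.
#'
#' @inheritParams bandpass_emg
#' @param emg Tibble of already band-passed EMG.
#' @return Tibble of envelopes on the same timebase.
#' @export
envelope <- function(emg, fs = FS_EMG, zero_phase = TRUE) {
  chans <- setdiff(names(emg), "time")
  emg[chans] <- lapply(emg[chans], abs)
  lp <- design_filter("lowpass", 3, fs = fs)
  filter_frame(emg, lp, zero_phase = zero_phase)
}

#' Low-pass auxiliary streams
#'
#' Applies the same 3 Hz 4th-order Butterworth low-pass used for the EMG
#' envelope to IMU and wrench streams, removing measurement noise while
#' preserving the sub-3 Hz motion band.
#'
#' @param df Tibble with `time` plus channel columns.
#' @param fs Sampling rate of the stream (Hz).
#' @param zero_phase Forward-backward filtering (default).
#' @return Filtered tibble.
#' @export
lowpass_aux <- function(df, fs, zero_phase = TRUE) {
  lp <- design_filter("lowpass", 3, fs = fs)
  filter_frame(df, lp, zero_phase = zero_phase)
}

#' Decimate filtered streams onto the common 74.074 Hz timebase
#'
#' The EMG envelope (1111.11 Hz) is decimated by the integer factor 15 and
#' the IMU / wrench streams (148.148 Hz) by 2; both land exactly on the
#' 74.074 Hz feature timebase. The preceding 3 Hz low-pass is the
#' anti-aliasing stage, so plain sample picking is exact here.
#'
#' @param df Tibble with `time` plus channels, already low-pass filtered.
#' @param fs Input sampling rate (Hz).
#' @param fs_out Output rate, default 74.074 Hz.
#' @return Tibble on the decimated timebase.
#' @export
decimate_stream <- function(df, fs, fs_out = FS_FEAT) {
  k <- fs / fs_out
  if (abs(k - round(k)) > 1e-6) {
    abort(sprintf(
      "Non-integer decimation factor %.4f from %s Hz to %s Hz.", k, fs, fs_out
    ))
  }
  k <- as.integer(round(k))
  df[seq(1, nrow(df), by = k), , drop = FALSE]
}

#' Build the synchronized feature frame for a session
#'
#' Runs the full preprocessing chain: EMG band-pass + linear envelope, IMU
#' and wrench 3 Hz low-pass, then integer decimation of every stream to the
#' common 74.074 Hz timebase. Columns are the 10 EMG envelopes
#' (`emg_01`..`emg_10`), 6 channels per IMU sensor
#' (`imu1_acc_x` .. `imu9_gyro_z`) and the 6 wrench targets
#' (`Fx`..`Mz`).
#'
#' @param session A `grf_session` (see [generate_session()] /
#'   [read_session()]).
#' @param zero_phase Forward-backward filtering (default).
#' @return A tibble: `time` plus feature and target columns, uniform at
#'   74.074 Hz.
#' @export
preprocess_session <- function(session, zero_phase = TRUE) {
  stopifnot(inherits(session, "grf_session"))
  env <- session$emg |>
    bandpass_emg(fs = session$rates$emg, zero_phase = zero_phase) |>
    envelope(fs = session$rates$emg, zero_phase = zero_phase) |>
    decimate_stream(fs = session$rates$emg)
  imu <- session$imu |>
    lowpass_aux(fs = session$rates$imu, zero_phase = zero_phase) |>
    decimate_stream(fs = session$rates$imu)
  wr <- session$wrench |>
    lowpass_aux(fs = session$rates$wrench, zero_phase = zero_phase) |>
    decimate_stream(fs = session$rates$wrench)
  n <- min(nrow(env), nrow(imu), nrow(wr))
  dplyr::bind_cols(
    env[seq_len(n), , drop = FALSE],
    imu[seq_len(n), setdiff(names(imu), "time"), drop = FALSE],
    wr[seq_len(n), setdiff(names(wr), "time"), drop = FALSE]
  )
}
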